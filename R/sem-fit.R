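# Multi-group ML estimation for the one-factor model family.
#
# The discrepancy minimized is the standard multi-group ML fit function
#   F = sum_g (n_g/N) [ log|Sigma_g| + tr(S_g Sigma_g^-1) - log|S_g| - p
#                       + (xbar_g - mu_g)' Sigma_g^-1 (xbar_g - mu_g) ]
# with S_g the biased (divisor n_g) sample covariance and T = N * F the model
# chi-square. Because all intercepts are group-specific and the latent mean is
# fixed at 0, the implied means are saturated: mu_hat_g = xbar_g exactly, the
# mean term vanishes at the optimum, and the intercepts can be profiled out of
# the numerical search (they still count as free parameters in the df). At the
# optimum the observed information is block-diagonal between means and
# covariance-structure parameters, so profiling does not change the standard
# errors of the structural parameters.
#
# Free covariance-structure parameters, in optimizer order (variances on the
# log scale so the implied covariance matrix is positive definite for every
# iterate): shared loadings, non-reference latent variances, indicator residual
# variances (by group), regression slope(s), outcome residual variances.

sem_group_stats <- function(data, spec) {
  data <- as.data.frame(data)
  vars <- spec_variables(spec)
  if (!spec$group_col %in% names(data)) stop("data lacks grouping column '", spec$group_col, "'")
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0) stop("data lacks variable(s): ", paste(missing_vars, collapse = ", "))
  g <- as.character(data[[spec$group_col]])
  if (!all(spec$groups %in% g)) {
    stop("group(s) absent from data: ", paste(setdiff(spec$groups, unique(g)), collapse = ", "))
  }
  x <- as.matrix(data[vars])
  if (anyNA(x)) stop("missing values in model variables; complete cases are required")
  out <- lapply(spec$groups, function(gr) {
    xg <- x[g == gr, , drop = FALSE]
    n <- nrow(xg)
    if (n < length(vars) + 1) stop("group ", gr, " has too few subjects (", n, ")")
    list(n = n, mean = colMeans(xg), cov = stats::cov(xg) * (n - 1) / n)
  })
  names(out) <- spec$groups
  validate_group_stats(out, spec)
}

validate_group_stats <- function(stats, spec) {
  p <- length(spec_variables(spec))
  for (g in spec$groups) {
    st <- stats[[g]]
    R <- tryCatch(chol(st$cov), error = function(e) NULL)
    if (is.null(R)) stop("sample covariance of group ", g, " is not positive definite")
    stats[[g]]$logdet <- 2 * sum(log(diag(R)))
    stats[[g]]$p <- p
  }
  stats
}

.par_layout <- function(spec) {
  m <- length(spec$indicators)
  G <- length(spec$groups)
  ref_i <- match(spec$reference, spec$groups)
  nonref_i <- setdiff(seq_len(G), ref_i)
  has_out <- !is.null(spec$outcome)
  nb <- if (!has_out) 0L else if (spec$beta == "free") G else 1L
  k <- m + (G - 1) + m * G + nb + if (has_out) G else 0L
  list(m = m, G = G, ref_i = ref_i, nonref_i = nonref_i,
       nonref = spec$groups[nonref_i], has_out = has_out, nb = nb, k = k)
}

# positionally indexed parameter values; names are attached only at the end of
# a fit (.unpack_named) to keep the optimizer hot path cheap
.unpack <- function(par, lay) {
  m <- lay$m; G <- lay$G
  lambda <- par[seq_len(m)]
  psi <- rep(1, G)
  psi[lay$nonref_i] <- exp(par[m + seq_len(G - 1)])
  theta <- matrix(exp(par[m + (G - 1) + seq_len(m * G)]), m, G)
  beta <- zeta <- NULL
  if (lay$has_out) {
    i <- m + (G - 1) + m * G
    b <- par[i + seq_len(lay$nb)]
    beta <- if (lay$nb == 1) rep(b, G) else b
    zeta <- exp(par[i + lay$nb + seq_len(G)])
  }
  list(lambda = lambda, psi = psi, theta = theta, beta = beta, zeta = zeta)
}

.unpack_named <- function(par, spec, lay) {
  pp <- .unpack(par, lay)
  names(pp$lambda) <- spec$indicators
  names(pp$psi) <- spec$groups
  dimnames(pp$theta) <- list(spec$indicators, spec$groups)
  if (lay$has_out) {
    names(pp$beta) <- spec$groups
    names(pp$zeta) <- spec$groups
  }
  pp
}

# objective and analytic gradient on the transformed scale; returns list(f, grad)
.sem_fg <- function(par, spec, gstats, lay, want_grad = TRUE) {
  pp <- .unpack(par, lay)
  m <- lay$m; G <- lay$G
  ns <- vapply(gstats, `[[`, numeric(1), "n")
  N <- sum(ns)
  f <- 0
  g_lambda <- numeric(m)
  g_lpsi <- numeric(G - 1)
  g_ltheta <- matrix(0, m, G)
  g_beta <- numeric(if (lay$has_out) lay$nb else 0)
  g_lzeta <- numeric(if (lay$has_out) G else 0)
  jj <- seq_len(m)
  for (gi in seq_len(G)) {
    st <- gstats[[gi]]
    w <- ns[gi] / N
    if (lay$has_out) {
      L <- c(pp$lambda, pp$beta[gi])
      dv <- c(pp$theta[, gi], pp$zeta[gi])
    } else {
      L <- pp$lambda
      dv <- pp$theta[, gi]
    }
    Sigma <- tcrossprod(L) * pp$psi[gi] + diag(dv, st$p)
    R <- chol(Sigma)
    Sinv <- chol2inv(R)
    f <- f + w * (2 * sum(log(diag(R))) + sum(Sinv * st$cov) - st$logdet - st$p)
    if (want_grad) {
      W <- Sinv - Sinv %*% st$cov %*% Sinv
      WL <- as.numeric(W %*% L)
      g_lambda <- g_lambda + (w * 2 * pp$psi[gi]) * WL[jj]
      pos <- match(gi, lay$nonref_i)
      if (!is.na(pos)) {
        g_lpsi[pos] <- w * sum(L * WL) * pp$psi[gi]          # chain rule: d/dlog psi
      }
      g_ltheta[, gi] <- w * diag(W)[jj] * pp$theta[, gi]
      if (lay$has_out) {
        gb <- w * 2 * pp$psi[gi] * WL[st$p]
        if (lay$nb == 1) g_beta[1] <- g_beta[1] + gb else g_beta[gi] <- gb
        g_lzeta[gi] <- w * W[st$p, st$p] * pp$zeta[gi]
      }
    }
  }
  grad <- if (want_grad) c(g_lambda, g_lpsi, as.numeric(g_ltheta), g_beta, g_lzeta) else NULL
  list(f = f, grad = grad)
}

.polish_newton <- function(par, fn, gr, tol, max_iter = 10) {
  k <- length(par)
  f0 <- fn(par)
  for (it in seq_len(max_iter)) {
    g <- gr(par)
    if (max(abs(g)) < tol) break
    H <- matrix(0, k, k)
    h <- pmax(abs(par), 1) * 1e-6
    for (j in seq_len(k)) {
      pp <- par; pp[j] <- par[j] + h[j]
      pm <- par; pm[j] <- par[j] - h[j]
      H[, j] <- (gr(pp) - gr(pm)) / (2 * h[j])
    }
    H <- (H + t(H)) / 2
    step <- tryCatch(-solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      step <- tryCatch(-solve(H + diag(1e-6 * max(abs(diag(H)), 1), k), g),
                       error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
    }
    alpha <- 1
    repeat {
      f1 <- fn(par + alpha * step)
      if (is.finite(f1) && f1 <= f0 + 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-8) break
    }
    if (alpha < 1e-8) break
    par <- par + alpha * step
    f0 <- fn(par)
  }
  par
}

.start_values <- function(spec, gstats, lay) {
  N <- sum(vapply(gstats, `[[`, numeric(1), "n"))
  Spool <- Reduce(`+`, lapply(gstats, function(st) st$cov * st$n / N))
  m <- lay$m
  sjj <- diag(Spool)[seq_len(m)]
  lam0 <- sqrt(pmax(sjj, 1e-3) / 2)
  par <- c(lam0, rep(0, lay$G - 1), rep(log(pmax(sjj, 1e-3) / 2), lay$G))
  if (lay$has_out) {
    spp <- diag(Spool)[m + 1]
    b0 <- Spool[m + 1, 1] / lam0[1]
    par <- c(par, rep(b0, lay$nb), rep(log(pmax(spp, 1e-3) / 2), lay$G))
  }
  par
}

#' Fit a multi-group one-factor SEM by maximum likelihood
#'
#' Minimizes the multi-group ML discrepancy over the free covariance-structure
#' parameters (quasi-Newton with analytic gradient on an unconstrained
#' log-variance parameterization); intercepts are profiled analytically. The
#' model chi-square is `T = N * F` with `N` the total sample size.
#'
#' @param data Data frame with the grouping column and all model variables.
#' @param spec A [sem_model_spec()].
#' @param se Compute standard errors from the observed information? Default
#'   `TRUE` (skipping them speeds up large simulation scans).
#' @param start Optional start vector on the optimizer scale (expert use).
#' @param grad_tol Convergence requirement: max-abs gradient below this after
#'   polishing restarts. Default `1e-6`.
#' @param max_restart Number of quasi-Newton restarts allowed while polishing.
#' @return Object of class `"edsem_fit"`; see [tidy.edsem_fit()],
#'   [glance.edsem_fit()], [standardized_solution()], [fit_indices()].
#' @export
sem_fit_ml <- function(data, spec, se = TRUE, start = NULL,
                       grad_tol = 1e-6, max_restart = 5) {
  gstats <- sem_group_stats(data, spec)
  sem_fit_moments(spec, gstats, se = se, start = start,
                  grad_tol = grad_tol, max_restart = max_restart)
}

#' Fit from group-level sufficient statistics
#'
#' Same engine as [sem_fit_ml()] but starting from per-group sample sizes,
#' mean vectors and (divisor-n) covariance matrices. Feeding exact
#' model-implied moments recovers the generating parameters with `T = 0`
#' (the zero-discrepancy fixed point).
#'
#' @param spec A [sem_model_spec()].
#' @param group_stats Named list (one element per group) of
#'   `list(n, mean, cov)`.
#' @inheritParams sem_fit_ml
#' @return Object of class `"edsem_fit"`.
#' @export
sem_fit_moments <- function(spec, group_stats, se = TRUE, start = NULL,
                            grad_tol = 1e-6, max_restart = 5) {
  if (!all(spec$groups %in% names(group_stats))) {
    stop("group_stats must be named by group")
  }
  group_stats <- group_stats[spec$groups]
  if (is.null(group_stats[[1]]$logdet)) {
    group_stats <- validate_group_stats(group_stats, spec)
  }
  lay <- .par_layout(spec)
  df <- count_df(spec)
  N <- sum(vapply(group_stats, `[[`, numeric(1), "n"))

  # optimize in a unit-variance metric (each observed variable divided by its
  # pooled SD) and map the solution back exactly; the ML solution is
  # equivariant under this linear rescaling and the optimizer stays
  # well-conditioned regardless of raw variable scales
  s <- sqrt(Reduce(`+`, lapply(group_stats, function(st) (st$n / N) * diag(st$cov))))
  gs_scaled <- lapply(group_stats, function(st) {
    list(n = st$n, mean = unname(st$mean) / s, cov = st$cov / tcrossprod(s),
         logdet = st$logdet - 2 * sum(log(s)), p = st$p)
  })
  par <- start %||% .start_values(spec, gs_scaled, lay)

  fn <- function(p) .sem_fg(p, spec, gs_scaled, lay, want_grad = FALSE)$f
  gr <- function(p) .sem_fg(p, spec, gs_scaled, lay)$grad

  converged <- FALSE
  for (attempt in seq_len(max_restart + 1)) {
    opt <- stats::optim(par, fn, gr, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-10))
    par <- opt$par
    if (max(abs(gr(par))) < grad_tol) { converged <- TRUE; break }
    # quasi-Newton stalled above the gradient tolerance: finish with damped
    # Newton steps (Hessian by central differences of the analytic gradient)
    par <- .polish_newton(par, fn, gr, grad_tol)
    if (max(abs(gr(par))) < grad_tol) { converged <- TRUE; break }
  }
  # sign convention: loadings sum positive (the global sign flip of the latent
  # leaves the likelihood unchanged)
  if (sum(par[seq_len(lay$m)] * s[seq_len(lay$m)]) < 0) {
    par[seq_len(lay$m)] <- -par[seq_len(lay$m)]
    if (lay$has_out) {
      bidx <- lay$m + (lay$G - 1) + lay$m * lay$G + seq_len(lay$nb)
      par[bidx] <- -par[bidx]
    }
  }
  fg <- .sem_fg(par, spec, gs_scaled, lay, want_grad = FALSE)
  params <- .unpack_named(par, spec, lay)
  # map the unit-metric solution back to the raw variable metric
  params$lambda <- params$lambda * s[seq_len(lay$m)]
  params$theta <- params$theta * s[seq_len(lay$m)]^2
  if (lay$has_out) {
    params$beta <- params$beta * s[lay$m + 1]
    params$zeta <- params$zeta * s[lay$m + 1]^2
  }
  params$nu <- vapply(spec$groups, function(g)
    group_stats[[g]]$mean[seq_len(lay$m)], numeric(lay$m))
  if (!is.matrix(params$nu)) params$nu <- matrix(params$nu, nrow = lay$m)
  dimnames(params$nu) <- list(spec$indicators, spec$groups)
  if (lay$has_out) {
    params$iota <- stats::setNames(vapply(spec$groups, function(g)
      unname(group_stats[[g]]$mean[lay$m + 1]), numeric(1)), spec$groups)
  }

  implied <- model_implied_moments(spec, params)
  Tstat <- max(N * as.numeric(fg$f), 0)
  heywood <- c(params$theta[params$theta < 1e-6],
               if (lay$has_out) params$zeta[params$zeta < 1e-6])

  fit <- structure(
    list(spec = spec, params = params, group_stats = group_stats,
         group_stats_scaled = gs_scaled, scale = s,
         implied = implied, discrepancy = as.numeric(fg$f), statistic = Tstat, df = df,
         p_value = if (df > 0) stats::pchisq(Tstat, df, lower.tail = FALSE) else NA_real_,
         n_total = N, n_groups = vapply(group_stats, `[[`, numeric(1), "n"),
         converged = converged, heywood = heywood,
         par_internal = par, layout = lay),
    class = "edsem_fit"
  )
  fit$vcov <- if (se) try(.sem_vcov(fit), silent = TRUE) else NULL
  fit$estimates <- .estimates_table(fit)
  fit$indices <- fit_indices(fit)
  fit
}

# observed information: numeric central differences of the analytic gradient
# with respect to the *natural* free parameters (variances untransformed),
# evaluated at the optimum; I = (N/2) * Hessian of F. Computed in the scaled
# (unit-variance) metric and mapped back via the exact linear reparameterization.
.nat_par <- function(fit) {
  pp <- fit$params; lay <- fit$layout; spec <- fit$spec
  c(pp$lambda, pp$psi[lay$nonref], as.numeric(pp$theta),
    if (lay$has_out) c(if (lay$nb == 1) pp$beta[1] else pp$beta, pp$zeta))
}

# per-parameter scale factors mapping unit-metric estimates to the raw metric
.nat_scale <- function(fit) {
  lay <- fit$layout
  s <- fit$scale
  sj <- s[seq_len(lay$m)]
  c(sj, rep(1, lay$G - 1), rep(sj^2, lay$G),
    if (lay$has_out) c(rep(s[lay$m + 1], lay$nb), rep(s[lay$m + 1]^2, lay$G)))
}

.nat_names <- function(fit) {
  lay <- fit$layout; spec <- fit$spec
  nm <- c(paste0("lambda[", spec$indicators, "]"),
          if (lay$G > 1) paste0("psi[", lay$nonref, "]"),
          paste0("theta[", outer(spec$indicators, spec$groups, paste, sep = ","), "]"))
  if (lay$has_out) {
    nm <- c(nm,
            if (lay$nb == 1) "beta" else paste0("beta[", spec$groups, "]"),
            paste0("zeta[", spec$groups, "]"))
  }
  nm
}

.grad_nat <- function(x, fit) {
  lay <- fit$layout
  m <- lay$m; G <- lay$G
  # natural -> transformed
  i <- m
  tpar <- x
  if (G > 1) tpar[i + seq_len(G - 1)] <- log(x[i + seq_len(G - 1)])
  i <- i + (G - 1)
  tpar[i + seq_len(m * G)] <- log(x[i + seq_len(m * G)])
  i <- i + m * G
  if (lay$has_out) {
    i <- i + lay$nb
    tpar[i + seq_len(G)] <- log(x[i + seq_len(G)])
  }
  g <- .sem_fg(tpar, fit$spec, fit$group_stats_scaled, lay)$grad
  # transformed gradient -> natural gradient (divide log-scale entries by value)
  i <- m
  if (G > 1) g[i + seq_len(G - 1)] <- g[i + seq_len(G - 1)] / x[i + seq_len(G - 1)]
  i <- i + (G - 1)
  g[i + seq_len(m * G)] <- g[i + seq_len(m * G)] / x[i + seq_len(m * G)]
  i <- i + m * G
  if (lay$has_out) {
    i <- i + lay$nb
    g[i + seq_len(G)] <- g[i + seq_len(G)] / x[i + seq_len(G)]
  }
  g
}

.sem_vcov <- function(fit) {
  J <- .nat_scale(fit)
  x0 <- .nat_par(fit) / J        # unit-metric natural parameters
  k <- length(x0)
  H <- matrix(0, k, k)
  h <- pmax(abs(x0), 1e-2) * 1e-5
  # variance parameters must stay positive under perturbation
  lay <- fit$layout
  var_idx <- c(lay$m + seq_len(lay$G - 1),
               lay$m + (lay$G - 1) + seq_len(lay$m * lay$G),
               if (lay$has_out) lay$m + (lay$G - 1) + lay$m * lay$G + lay$nb + seq_len(lay$G))
  h[var_idx] <- pmin(h[var_idx], x0[var_idx] * 0.49)
  for (j in seq_len(k)) {
    xp <- x0; xp[j] <- x0[j] + h[j]
    xm <- x0; xm[j] <- x0[j] - h[j]
    H[, j] <- (.grad_nat(xp, fit) - .grad_nat(xm, fit)) / (2 * h[j])
  }
  H <- (H + t(H)) / 2
  info <- (fit$n_total / 2) * H
  V <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) < 0)) {
    bad <- if (!is.null(V)) .nat_names(fit)[!is.finite(diag(V)) | diag(V) < 0]
           else .nat_names(fit)
    stop("singular observed information; offending parameter(s): ",
         paste(bad, collapse = ", "))
  }
  V <- V * tcrossprod(J)          # back to the raw metric
  dimnames(V) <- list(.nat_names(fit), .nat_names(fit))
  V
}

.estimates_table <- function(fit) {
  spec <- fit$spec; pp <- fit$params; lay <- fit$layout
  V <- fit$vcov
  se_of <- function(nm) {
    if (is.null(V) || inherits(V, "try-error") || !nm %in% rownames(V)) return(NA_real_)
    sqrt(V[nm, nm])
  }
  rows <- list()
  add <- function(parameter, group, estimate, se, free = TRUE) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      parameter = parameter, group = group, estimate = estimate, se = se, free = free)
  }
  for (j in spec$indicators) {
    add(paste0("lambda[", j, "]"), NA_character_, unname(pp$lambda[j]),
        se_of(paste0("lambda[", j, "]")))
  }
  for (g in spec$groups) {
    add("psi", g, unname(pp$psi[g]),
        if (g == spec$reference) NA_real_ else se_of(paste0("psi[", g, "]")),
        free = g != spec$reference)
  }
  for (g in spec$groups) for (j in spec$indicators) {
    add(paste0("theta[", j, "]"), g, unname(pp$theta[j, g]),
        se_of(paste0("theta[", j, ",", g, "]")))
  }
  if (lay$has_out) {
    for (g in spec$groups) {
      add("beta", g, unname(pp$beta[g]),
          if (lay$nb == 1) se_of("beta") else se_of(paste0("beta[", g, "]")))
      add("zeta", g, unname(pp$zeta[g]), se_of(paste0("zeta[", g, "]")))
    }
  }
  for (g in spec$groups) {
    sdg <- sqrt(diag(fit$implied[[g]]$sigma))
    ng <- fit$n_groups[[g]]
    for (j in spec$indicators) {
      add(paste0("nu[", j, "]"), g, unname(pp$nu[j, g]), unname(sdg[j]) / sqrt(ng))
    }
    if (lay$has_out) add("iota", g, unname(pp$iota[g]), unname(sdg[length(sdg)]) / sqrt(ng))
  }
  out <- dplyr::bind_rows(rows)
  out$z <- out$estimate / out$se
  out$p.value <- 2 * stats::pnorm(-abs(out$z))
  out
}

#' Standard errors, z statistics and p-values of a fitted model
#'
#' Standard errors come from the inverse observed information of the
#' log-likelihood; `z` is estimate/SE and p-values are two-sided normal.
#'
#' @param fit An `"edsem_fit"`.
#' @return Tibble with columns `parameter`, `group`, `estimate`, `se`, `z`,
#'   `p.value`.
#' @export
standard_errors <- function(fit) {
  if (is.null(fit$vcov) || inherits(fit$vcov, "try-error")) {
    fit$vcov <- .sem_vcov(fit)
    fit$estimates <- .estimates_table(fit)
  }
  fit$estimates[c("parameter", "group", "estimate", "se", "z", "p.value")]
}

#' Completely standardized solution
#'
#' Rescales loadings and regression slopes by the implied standard deviations
#' of the latent and observed variables, separately per group, so that all
#' variables have unit variance.
#'
#' @param fit An `"edsem_fit"`.
#' @return Tibble with columns `parameter`, `group`, `std_estimate`.
#' @export
standardized_solution <- function(fit) {
  spec <- fit$spec; pp <- fit$params
  rows <- purrr::map_dfr(spec$groups, function(g) {
    sdg <- sqrt(diag(fit$implied[[g]]$sigma))
    if (any(sdg == 0)) stop("zero implied variance in group ", g)
    sp <- sqrt(pp$psi[g])
    out <- tibble::tibble(
      parameter = paste0("lambda[", spec$indicators, "]"),
      group = g,
      std_estimate = unname(pp$lambda * sp / sdg[seq_along(spec$indicators)])
    )
    if (!is.null(spec$outcome)) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        parameter = "beta", group = g,
        std_estimate = unname(pp$beta[g] * sp / sdg[length(sdg)])
      ))
    }
    out
  })
  rows
}

#' Goodness-of-fit indices
#'
#' CFI against the per-group independence baseline (free variances and means),
#' RMSEA with the multi-group `sqrt(G)` scaling, and SRMR as the average over
#' groups of the root-mean-square standardized residual moments (covariances
#' and means).
#'
#' @param fit An `"edsem_fit"`.
#' @return List with `cfi`, `srmr`, `rmsea`, and the baseline statistic and df.
#' @export
fit_indices <- function(fit) {
  G <- length(fit$spec$groups)
  N <- fit$n_total
  p <- fit$group_stats[[1]]$p
  # independence baseline: diagonal Sigma = diag(S_g), saturated means
  Fb <- 0
  for (g in fit$spec$groups) {
    st <- fit$group_stats[[g]]
    Fb <- Fb + (st$n / N) * (sum(log(diag(st$cov))) - st$logdet)
  }
  Tb <- N * Fb
  dfb <- G * (p * (p + 1) / 2 + p) - 2 * p * G
  Tt <- fit$statistic; df <- fit$df
  cfi <- 1 - max(Tt - df, 0) / max(Tb - dfb, Tt - df, 0)
  rmsea <- if (df > 0) sqrt(G) * sqrt(max(Tt - df, 0) / (df * N)) else NA_real_
  srmr_g <- vapply(fit$spec$groups, function(g) {
    S <- fit$group_stats[[g]]$cov
    Sig <- fit$implied[[g]]$sigma
    sd <- sqrt(diag(S))
    Dres <- (S - Sig) / tcrossprod(sd)
    mres <- (fit$group_stats[[g]]$mean - fit$implied[[g]]$mu) / sd
    vals <- c(Dres[upper.tri(Dres, diag = TRUE)], mres)
    sqrt(mean(vals^2))
  }, numeric(1))
  list(cfi = cfi, srmr = mean(srmr_g), rmsea = rmsea,
       baseline_statistic = Tb, baseline_df = dfb)
}

#' Chi-square difference test between nested model fits
#'
#' Likelihood-ratio comparison of a constrained (shared regression slope)
#' model against the free model on the same data.
#'
#' @param fit_free,fit_constrained `"edsem_fit"` objects on identical data;
#'   the constrained spec must nest in the free spec.
#' @return Tibble with `statistic` (delta chi-square), `df` (delta df) and
#'   `p.value`.
#' @export
chi_square_difference <- function(fit_free, fit_constrained) {
  sf <- fit_free$spec; sc <- fit_constrained$spec
  same <- identical(sf$indicators, sc$indicators) &&
    identical(sf$outcome, sc$outcome) &&
    identical(sf$groups, sc$groups) &&
    identical(sf$reference, sc$reference)
  nested <- same && ((sf$beta == "free" && sc$beta == "shared") ||
                       (sf$beta == sc$beta))
  if (!nested) stop("models are not nested (specs differ beyond the beta constraint)")
  if (!identical(fit_free$n_groups, fit_constrained$n_groups)) {
    stop("fits are not on the same data (group sizes differ)")
  }
  ddf <- fit_constrained$df - fit_free$df
  if (ddf < 0) stop("constrained model has fewer df than the free model")
  dchisq <- fit_constrained$statistic - fit_free$statistic
  dchisq_p <- max(dchisq, 0)
  tibble::tibble(
    statistic = dchisq, df = ddf,
    p.value = if (ddf > 0) stats::pchisq(dchisq_p, ddf, lower.tail = FALSE)
              else as.numeric(dchisq_p <= 0) * 1
  )
}

#' @export
print.edsem_fit <- function(x, ...) {
  cat("<edsem_fit> one-factor multi-group SEM (",
      paste(names(x$n_groups), x$n_groups, sep = "=", collapse = ", "), ")\n", sep = "")
  cat(sprintf("  chi-square %.3f on %d df (p = %.3g); CFI %.3f, SRMR %.3f, RMSEA %.3f\n",
              x$statistic, x$df, x$p_value,
              x$indices$cfi, x$indices$srmr, x$indices$rmsea))
  if (!x$converged) cat("  WARNING: optimizer did not meet the gradient tolerance\n")
  if (length(x$heywood) > 0) cat("  note: residual variance(s) at the boundary (Heywood)\n")
  invisible(x)
}

#' @rdname tidy.edsem_fit
#' @export
tidy.edsem_fit <- function(x, standardized = FALSE, ...) {
  out <- x$estimates
  if (standardized) {
    std <- standardized_solution(x)
    out <- dplyr::left_join(out, std, by = c("parameter", "group"))
  }
  out
}

#' Tidy and glance methods for fitted models
#'
#' `tidy()` returns the parameter table (optionally joined with the completely
#' standardized solution); `glance()` returns a one-row model summary.
#'
#' @param x An `"edsem_fit"`.
#' @param standardized Join per-group completely standardized estimates?
#' @param ... Unused.
#' @name tidy.edsem_fit
#' @export
glance.edsem_fit <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df = x$df, p.value = x$p_value,
    cfi = x$indices$cfi, srmr = x$indices$srmr, rmsea = x$indices$rmsea,
    discrepancy = x$discrepancy, n = x$n_total,
    converged = x$converged, n_heywood = length(x$heywood)
  )
}
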