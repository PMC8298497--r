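#' Specify a multi-group one-factor structural equation model
#'
#' The model family used throughout the package: one latent factor measured by
#' `indicators` with loadings shared across groups, an optional observed
#' `outcome` regressed on the latent with a group-specific (or shared)
#' regression slope, group-specific intercepts and residual variances, the
#' latent mean fixed to 0 in every group, and the latent variance fixed to 1 in
#' the `reference` group and free elsewhere. Without an `outcome` the model is
#' a multi-group confirmatory factor analysis.
#'
#' @param indicators Character vector (>= 3) of indicator column names.
#' @param outcome Optional single outcome column name (e.g. a nodal topology
#'   measure).
#' @param groups Ordered character vector of group labels.
#' @param reference Group whose latent variance is fixed to 1.
#' @param beta `"free"` (group-specific latent-to-outcome regression) or
#'   `"shared"` (one slope constrained equal across groups). Ignored without an
#'   outcome.
#' @param group_col Name of the grouping column in data frames passed to
#'   [sem_fit_ml()]. Default `"group"`.
#' @return An object of class `"sem_model_spec"`.
#' @export
sem_model_spec <- function(indicators, outcome = NULL, groups,
                           reference = groups[1],
                           beta = c("free", "shared"),
                           group_col = "group") {
  beta <- match.arg(beta)
  if (length(indicators) < 3) stop("at least 3 indicators are required for identification")
  if (!is.null(outcome) && length(outcome) != 1) stop("outcome must be a single variable")
  if (!reference %in% groups) stop("reference group must be one of the groups")
  if (anyDuplicated(c(indicators, outcome))) stop("duplicated variable names")
  structure(
    list(indicators = indicators, outcome = outcome, groups = groups,
         reference = reference, beta = beta, group_col = group_col),
    class = "sem_model_spec"
  )
}

#' @export
print.sem_model_spec <- function(x, ...) {
  cat("<sem_model_spec> one-factor,", length(x$groups), "group(s)\n")
  cat("  indicators:", paste(x$indicators, collapse = ", "), "\n")
  if (!is.null(x$outcome)) cat("  outcome:", x$outcome, "(beta", x$beta, ")\n")
  cat("  latent variance fixed to 1 in:", x$reference, "\n")
  invisible(x)
}

spec_variables <- function(spec) c(spec$indicators, spec$outcome)

#' Model degrees of freedom
#'
#' Total observed moments across groups (covariances plus means) minus the
#' number of free parameters: shared loadings, non-reference latent variances,
#' group-specific residual variances and intercepts, and the regression
#' slope(s) when an outcome is present.
#'
#' @param spec A [sem_model_spec()].
#' @return Integer degrees of freedom.
#' @export
count_df <- function(spec) {
  m <- length(spec$indicators)
  G <- length(spec$groups)
  p <- m + !is.null(spec$outcome)
  moments <- G * (p * (p + 1) / 2 + p)
  free <- m +                    # shared loadings
    (G - 1) +                    # non-reference latent variances
    m * G +                      # indicator residual variances
    p * G                        # intercepts (group-specific, saturate the means)
  if (!is.null(spec$outcome)) {
    free <- free + G +                            # outcome residual variances
      if (spec$beta == "free") G else 1           # regression slope(s)
  }
  df <- as.integer(moments - free)
  if (df < 0) stop("model is not identified: ", -df, " more parameters than moments")
  df
}

#' Model-implied moments of a multi-group one-factor model
#'
#' For each group computes the implied covariance matrix
#' `Sigma = L L' psi + diag(residuals)` (with `L` the loadings vector, extended
#' by the group's regression slope when an outcome is present) and the implied
#' mean vector (the intercepts; the latent mean is 0).
#'
#' @param spec A [sem_model_spec()].
#' @param params Parameter list as produced by [sem_params()] (fields `lambda`,
#'   `psi`, `theta`, `beta`, `zeta`, `nu`, `iota`).
#' @return Named list, one element per group, each `list(sigma, mu)`.
#' @export
model_implied_moments <- function(spec, params) {
  vars <- spec_variables(spec)
  p <- length(vars)
  out <- lapply(spec$groups, function(g) {
    L <- params$lambda
    resid <- params$theta[, g]
    mu <- params$nu[, g]
    if (!is.null(spec$outcome)) {
      L <- c(L, params$beta[g])
      resid <- c(resid, params$zeta[g])
      mu <- c(mu, params$iota[g])
    }
    if (any(!is.finite(L)) || any(!is.finite(resid)) || any(!is.finite(mu)) ||
        !is.finite(params$psi[g])) {
      stop("non-finite parameter value in group ", g)
    }
    sigma <- tcrossprod(L) * params$psi[g] + diag(resid, p)
    dimnames(sigma) <- list(vars, vars)
    list(sigma = sigma, mu = stats::setNames(mu, vars))
  })
  names(out) <- spec$groups
  out
}

#' Construct a full parameter list for a model specification
#'
#' Convenience constructor used for simulation and for the zero-discrepancy
#' checks: assembles loadings, latent variances, residual variances, slopes and
#' intercepts into the list layout consumed by [model_implied_moments()].
#'
#' @param spec A [sem_model_spec()].
#' @param lambda Loadings (length = number of indicators).
#' @param psi Latent variances, named by group or recycled; the reference
#'   group's value is forced to 1.
#' @param theta Indicator residual variances: vector (recycled across groups)
#'   or indicators x groups matrix.
#' @param beta Regression slope(s), named by group or recycled.
#' @param zeta Outcome residual variances, named by group or recycled.
#' @param nu Indicator intercepts (vector or indicators x groups matrix).
#' @param iota Outcome intercepts per group.
#' @return Parameter list with fields `lambda`, `psi`, `theta`, `beta`, `zeta`,
#'   `nu`, `iota`.
#' @export
sem_params <- function(spec, lambda, psi = 1, theta = NULL, beta = NULL,
                       zeta = NULL, nu = 0, iota = 0) {
  m <- length(spec$indicators)
  G <- length(spec$groups)
  stopifnot(length(lambda) == m)
  expand_g <- function(x, what) {
    if (is.null(names(x))) x <- stats::setNames(rep_len(x, G), spec$groups)
    if (!all(spec$groups %in% names(x))) stop(what, " must cover all groups")
    x[spec$groups]
  }
  expand_mg <- function(x, what) {
    if (is.matrix(x)) {
      stopifnot(nrow(x) == m, ncol(x) == G)
    } else {
      x <- matrix(rep_len(x, m), nrow = m, ncol = G)
    }
    dimnames(x) <- list(spec$indicators, spec$groups)
    x
  }
  psi <- expand_g(psi, "psi")
  psi[spec$reference] <- 1
  if (is.null(theta)) theta <- 1 - lambda^2
  out <- list(
    lambda = stats::setNames(as.numeric(lambda), spec$indicators),
    psi = psi,
    theta = expand_mg(theta, "theta"),
    nu = expand_mg(nu, "nu"),
    beta = NULL, zeta = NULL, iota = NULL
  )
  if (!is.null(spec$outcome)) {
    if (is.null(beta)) stop("outcome model needs beta")
    if (is.null(zeta)) stop("outcome model needs zeta")
    out$beta <- expand_g(beta, "beta")
    if (spec$beta == "shared" && length(unique(out$beta)) > 1) {
      stop("beta constrained shared but group-specific values supplied")
    }
    out$zeta <- expand_g(zeta, "zeta")
    out$iota <- expand_g(iota, "iota")
  }
  out
}
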