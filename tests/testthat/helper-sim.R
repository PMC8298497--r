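# Simulation helpers shared across the SEM test files.

paper_loadings <- c(k10_distress = 0.909, sdq_emotional = 0.603,
                    sdq_conduct = 0.546, cprs_lability = 0.428)
paper_psi <- c(HC = 0.300, `ADHD-I` = 1, `ADHD-C/H` = 0.340)
paper_beta_std <- c(HC = 0.091, `ADHD-I` = -0.279, `ADHD-C/H` = 0.844)
paper_groups <- c("HC", "ADHD-I", "ADHD-C/H")

# draw raw data from a one-factor multi-group model given a full parameter list
sim_sem_data <- function(spec, params, n_per_group) {
  if (length(n_per_group) == 1) {
    n_per_group <- stats::setNames(rep(n_per_group, length(spec$groups)), spec$groups)
  }
  m <- length(spec$indicators)
  do.call(rbind, lapply(spec$groups, function(g) {
    n <- n_per_group[[g]]
    eta <- rnorm(n, 0, sqrt(params$psi[[g]]))
    X <- sapply(seq_len(m), function(j) {
      params$nu[j, g] + params$lambda[j] * eta + rnorm(n, 0, sqrt(params$theta[j, g]))
    })
    if (n == 1) X <- matrix(X, nrow = 1)
    colnames(X) <- spec$indicators
    d <- as.data.frame(X)
    if (!is.null(spec$outcome)) {
      d[[spec$outcome]] <- params$iota[[g]] + params$beta[[g]] * eta +
        rnorm(n, 0, sqrt(params$zeta[[g]]))
    }
    d[[spec$group_col]] <- g
    d
  }))
}

# full three-group model with the study's generating values; the standardized
# effect pattern is mapped to unstandardized slopes in a unit-outcome-variance
# metric: beta_g = beta_std_g / sqrt(psi_g), zeta_g = 1 - beta_std_g^2
paper_model <- function(beta_std = paper_beta_std, outcome = "topology") {
  spec <- sem_model_spec(names(paper_loadings), outcome = outcome,
                         groups = paper_groups, reference = "ADHD-I",
                         beta = "free")
  params <- sem_params(spec, lambda = paper_loadings, psi = paper_psi,
                       beta = beta_std / sqrt(paper_psi),
                       zeta = 1 - beta_std^2)
  list(spec = spec, params = params)
}

# random proper parameter set for an arbitrary spec (used by the
# zero-discrepancy checks)
random_params <- function(spec) {
  m <- length(spec$indicators)
  G <- length(spec$groups)
  psi <- runif(G, 0.3, 2)
  names(psi) <- spec$groups
  sem_params(
    spec,
    lambda = runif(m, 0.3, 1.2) * sample(c(-1, 1), m, replace = TRUE),
    psi = psi,
    theta = matrix(runif(m * G, 0.2, 1.5), m, G),
    beta = if (is.null(spec$outcome)) NULL else
      if (spec$beta == "shared") rep(runif(1, -1, 1), G) else runif(G, -1, 1),
    zeta = if (is.null(spec$outcome)) NULL else runif(G, 0.2, 1.5),
    nu = matrix(runif(m * G, -1, 1), m, G),
    iota = if (is.null(spec$outcome)) NULL else runif(G, -1, 1)
  )
}

# multivariate normal log-likelihood, written out (independent of the engine)
mvn_loglik <- function(X, mu, Sigma) {
  p <- ncol(X)
  R <- chol(Sigma)
  logdet <- 2 * sum(log(diag(R)))
  Xc <- sweep(X, 2, mu)
  q <- rowSums((Xc %*% chol2inv(R)) * Xc)
  sum(-0.5 * (p * log(2 * pi) + logdet + q))
}
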