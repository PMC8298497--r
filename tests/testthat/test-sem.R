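spec3 <- sem_model_spec(names(paper_loadings), outcome = "topology",
                        groups = paper_groups, reference = "ADHD-I",
                        beta = "free")
spec3_shared <- sem_model_spec(names(paper_loadings), outcome = "topology",
                               groups = paper_groups, reference = "ADHD-I",
                               beta = "shared")

test_that("model-implied moments follow the one-factor structure", {
  # all loadings and slopes zero: diagonal covariance of residual variances
  p0 <- sem_params(spec3, lambda = rep(0, 4), psi = 1, theta = rep(1.3, 4),
                   beta = rep(0, 3), zeta = 0.7)
  mom <- model_implied_moments(spec3, p0)
  expect_equal(unname(mom[["HC"]]$sigma), diag(c(rep(1.3, 4), 0.7)))

  # unit loadings, unit residuals: indicator block = J + I
  p1 <- sem_params(spec3, lambda = rep(1, 4), psi = 1, theta = rep(1, 4),
                   beta = rep(0, 3), zeta = 1)
  ind <- model_implied_moments(spec3, p1)[["ADHD-I"]]$sigma[1:4, 1:4]
  expect_equal(unname(ind), matrix(1, 4, 4) + diag(4))

  # study-like values vs direct matrix arithmetic
  lam <- c(0.909, 0.603, 0.546, 0.428)
  p2 <- sem_params(spec3, lambda = lam, psi = 1, theta = 1 - lam^2,
                   beta = rep(0.8, 3), zeta = 0.36)
  sig <- model_implied_moments(spec3, p2)[["HC"]]$sigma
  L <- c(lam, 0.8)
  oracle <- outer(L, L) + diag(c(1 - lam^2, 0.36))
  expect_equal(unname(sig), oracle, tolerance = 1e-12)

  expect_error(model_implied_moments(spec3, within(p2, lambda[1] <- NaN)), "non-finite")
})

test_that("degrees of freedom match the moment count minus free parameters", {
  expect_identical(count_df(spec3), 21L)
  expect_identical(count_df(spec3_shared), 23L)
  expect_identical(count_df(spec3_shared) - count_df(spec3), 2L)

  # four-indicator three-group CFA: 42 moments - 30 free
  cfa <- sem_model_spec(names(paper_loadings), groups = paper_groups,
                        reference = "ADHD-I")
  expect_identical(count_df(cfa), 12L)

  # just-identified single-group three-indicator CFA
  cfa1 <- sem_model_spec(c("a", "b", "c"), groups = "G")
  expect_identical(count_df(cfa1), 0L)

  # generic identity over a spread of configurations
  for (m in 3:5) for (G in 1:3) for (out in c(TRUE, FALSE)) {
    sp <- sem_model_spec(paste0("x", 1:m), outcome = if (out) "y",
                         groups = paste0("g", 1:G))
    p <- m + out
    moments <- G * (p * (p + 1) / 2 + p)
    free <- m + (G - 1) + m * G + p * G + if (out) G + G else 0
    expect_identical(count_df(sp), as.integer(moments - free))
  }
})

test_that("exact model-implied moments are a zero-discrepancy fixed point", {
  set.seed(31)
  for (rep in 1:8) {
    params <- random_params(spec3)
    mom <- model_implied_moments(spec3, params)
    gs <- lapply(mom, function(m) list(n = 173, mean = m$mu, cov = m$sigma))
    fit <- sem_fit_moments(spec3, gs, se = FALSE)
    expect_lt(fit$statistic, 1e-6)
    expect_lt(max(abs(fit$params$lambda -
                        params$lambda * sign(sum(params$lambda)))), 1e-5)
    expect_lt(max(abs(fit$params$psi - params$psi)), 1e-5)
    expect_lt(max(abs(fit$params$theta - params$theta)), 1e-5)
  }
})

test_that("a just-identified 3-indicator CFA matches its closed-form ML solution", {
  set.seed(17)
  sp <- sem_model_spec(c("a", "b", "c"), groups = "G")
  pars <- sem_params(sp, lambda = c(0.8, 0.6, 0.7), psi = 1,
                     theta = c(0.5, 0.9, 0.6))
  dat <- sim_sem_data(sp, pars, 400)
  fit <- sem_fit_ml(dat, sp, se = FALSE)
  S <- cov(as.matrix(dat[c("a", "b", "c")])) * 399 / 400
  lam1 <- sqrt(S[1, 2] * S[1, 3] / S[2, 3])
  lam <- c(lam1, S[1, 2] / lam1, S[1, 3] / lam1)
  expect_equal(unname(fit$params$lambda), lam, tolerance = 1e-6)
  expect_equal(unname(fit$params$theta[, 1]), unname(diag(S) - lam^2),
               tolerance = 1e-6)
  expect_lt(fit$statistic, 1e-8)          # df = 0: exact fit
})

test_that("N*F equals the likelihood-ratio statistic against the saturated model", {
  set.seed(57)
  pm <- paper_model()
  dat <- sim_sem_data(pm$spec, pm$params, c(HC = 60, `ADHD-I` = 40, `ADHD-C/H` = 50))
  fit <- sem_fit_ml(dat, pm$spec, se = FALSE)
  vars <- c(pm$spec$indicators, pm$spec$outcome)
  ll_model <- ll_sat <- 0
  for (g in pm$spec$groups) {
    X <- as.matrix(dat[dat$group == g, vars])
    n <- nrow(X)
    ll_model <- ll_model + mvn_loglik(X, fit$implied[[g]]$mu, fit$implied[[g]]$sigma)
    ll_sat <- ll_sat + mvn_loglik(X, colMeans(X), cov(X) * (n - 1) / n)
  }
  expect_equal(fit$n_total * fit$discrepancy, -2 * (ll_model - ll_sat),
               tolerance = 1e-8)
})

test_that("the constrained model never fits better than the free model", {
  set.seed(71)
  for (rep in 1:5) {
    pm <- paper_model(beta_std = c(HC = runif(1, -0.5, 0.5),
                                   `ADHD-I` = runif(1, -0.5, 0.5),
                                   `ADHD-C/H` = runif(1, -0.5, 0.5)))
    dat <- sim_sem_data(pm$spec, pm$params, 60)
    ff <- sem_fit_ml(dat, spec3, se = FALSE)
    fc <- sem_fit_ml(dat, spec3_shared, se = FALSE)
    expect_gte(fc$statistic - ff$statistic, -1e-6 * ff$n_total)
    dt <- chi_square_difference(ff, fc)
    expect_identical(dt$df, 2L)
    expect_gte(dt$p.value, 0)
  }
})

test_that("chi-square difference of a model with itself is zero with p = 1, and non-nested specs error", {
  set.seed(72)
  pm <- paper_model()
  dat <- sim_sem_data(pm$spec, pm$params, 50)
  ff <- sem_fit_ml(dat, spec3, se = FALSE)
  self <- chi_square_difference(ff, ff)
  expect_equal(self$statistic, 0)
  expect_identical(self$df, 0L)
  expect_equal(self$p.value, 1)
  other <- sem_model_spec(names(paper_loadings)[1:3], outcome = "topology",
                          groups = paper_groups, reference = "ADHD-I")
  dat3 <- dat[, c(names(paper_loadings)[1:3], "topology", "group")]
  expect_error(chi_square_difference(ff, sem_fit_ml(dat3, other, se = FALSE)),
               "not nested")
})

test_that("parameters are recovered without bias at large samples", {
  set.seed(101)
  pm <- paper_model()
  errs <- replicate(4, {
    dat <- sim_sem_data(pm$spec, pm$params, 20000)
    fit <- sem_fit_ml(dat, pm$spec, se = FALSE)
    c(fit$params$lambda - pm$params$lambda,
      fit$params$psi - pm$params$psi,
      fit$params$beta - pm$params$beta)
  })
  expect_lt(max(abs(rowMeans(errs))), 0.02)
})

test_that("Wald intervals achieve near-nominal coverage for the group slopes", {
  set.seed(202)
  pm <- paper_model()
  hits <- replicate(150, {
    dat <- sim_sem_data(pm$spec, pm$params, c(HC = 150, `ADHD-I` = 150, `ADHD-C/H` = 150))
    fit <- sem_fit_ml(dat, pm$spec)
    est <- fit$estimates[fit$estimates$parameter == "beta", ]
    truth <- pm$params$beta[est$group]
    abs(est$estimate - truth) <= 1.96 * est$se
  })
  cover <- mean(hits)
  expect_gt(cover, 0.90)
  expect_lt(cover, 0.99)
})

test_that("standard errors behave like Wald tests and flag singular information", {
  set.seed(73)
  pm <- paper_model()
  dat <- sim_sem_data(pm$spec, pm$params, 120)
  fit <- sem_fit_ml(dat, spec3)
  se <- standard_errors(fit)
  expect_true(all(is.finite(se$se[se$parameter == "beta"])))
  expect_equal(se$z, se$estimate / se$se)
  expect_equal(se$p.value, 2 * pnorm(-abs(se$z)))
  # p -> 1 as the estimate approaches 0 relative to its SE
  near_null <- se[which.min(abs(se$z)), ]
  expect_gt(near_null$p.value, 2 * pnorm(-abs(near_null$z)) - 1e-12)
})

test_that("the completely standardized solution is invariant to rescaling observed variables", {
  set.seed(74)
  pm <- paper_model()
  dat <- sim_sem_data(pm$spec, pm$params, 100)
  fit <- sem_fit_ml(dat, spec3, se = FALSE)
  std <- standardized_solution(fit)
  scaled <- dat
  scales <- c(k10_distress = 10, sdq_emotional = 0.2, sdq_conduct = 3,
              cprs_lability = 0.5, topology = 40)
  for (v in names(scales)) scaled[[v]] <- scaled[[v]] * scales[[v]]
  fit2 <- sem_fit_ml(scaled, spec3, se = FALSE)
  std2 <- standardized_solution(fit2)
  expect_equal(std$std_estimate, std2$std_estimate, tolerance = 1e-5)
  # direct ratio check: lambda * sqrt(psi) / implied sd
  lam1 <- fit$params$lambda[1]
  sd1 <- sqrt(fit$implied[["HC"]]$sigma[1, 1])
  psi1 <- fit$params$psi[["HC"]]
  expect_equal(std$std_estimate[std$group == "HC"][1], unname(lam1 * sqrt(psi1) / sd1))
})

test_that("perfect fit yields CFI 1, RMSEA 0 and SRMR ~ 0", {
  set.seed(75)
  params <- random_params(spec3)
  mom <- model_implied_moments(spec3, params)
  gs <- lapply(mom, function(m) list(n = 200, mean = m$mu, cov = m$sigma))
  fit <- sem_fit_moments(spec3, gs, se = FALSE)
  expect_equal(fit$indices$cfi, 1)
  expect_equal(fit$indices$rmsea, 0)
  expect_lt(fit$indices$srmr, 1e-5)
  expect_identical(fit$indices$baseline_df, 30)  # independence baseline, 3 groups x 5 vars
})
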