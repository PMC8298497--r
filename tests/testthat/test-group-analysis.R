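test_that("BH adjustment reproduces the step-up procedure and its invariants", {
  expect_equal(fdr_adjust(0.037), 0.037)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))  # step-up by hand
  expect_equal(fdr_adjust(rep(1, 6)), rep(1, 6))
  set.seed(8)
  p <- runif(40)^2
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= pmin(1, length(p) * p) + 1e-12))
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-12))   # monotone in raw p
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("indicator selection retains strong loadings and drops a null indicator", {
  cfg <- cohort_config(n = c(600, 220, 180))
  base <- generate_phenotypes(cfg, seed = 301, outcomes = FALSE)
  # append a fifth candidate with zero loading: pure noise
  dropped <- 0
  for (rep in 1:12) {
    set.seed(400 + rep)
    dat <- base
    dat$noise_scale <- rnorm(nrow(dat))
    sel <- select_indicators(dat, c(names(cfg$loadings), "noise_scale"))
    expect_setequal(setdiff(names(cfg$loadings), sel$retained), character(0))
    if (!"noise_scale" %in% sel$retained) dropped <- dropped + 1
  }
  expect_gte(dropped, 10)   # ~5% false retention rate under the null

  # all strong loadings at large n -> everything retained
  sel_all <- select_indicators(base, names(cfg$loadings))
  expect_setequal(sel_all$retained, names(cfg$loadings))
  expect_s3_class(tidy(sel_all), "tbl_df")

  # under-identification: three candidates that are pure noise
  set.seed(77)
  noisy <- tibble::tibble(
    group = factor(rep(paper_groups, times = c(60, 50, 50)), levels = paper_groups),
    a = rnorm(160), b = rnorm(160), c = rnorm(160)
  )
  expect_error(select_indicators(noisy, c("a", "b", "c")), "fewer than 3")
})

test_that("post-hoc pairwise models test one constraint per pair with Bonferroni capping", {
  set.seed(55)
  pm <- paper_model(outcome = "node_effect")
  dat <- sim_sem_data(pm$spec, pm$params, c(HC = 180, `ADHD-I` = 90, `ADHD-C/H` = 90))
  ph <- posthoc_pairwise(dat, pm$spec$indicators, "node_effect")
  expect_equal(nrow(ph), 3)
  expect_equal(ph$df, rep(1L, 3))
  expect_equal(ph$p_bonferroni, pmin(ph$p.value * 3, 1))
  # the strongly separated pair should be the most significant
  expect_equal(ph$pair[which.min(ph$p.value)], "ADHD-I vs ADHD-C/H")
})

test_that("the node scan gates density-level tests on the integrated result", {
  cfg <- cohort_config(n = 4 * c(91, 31, 25), n_null_nodes = 3)
  pheno <- generate_phenotypes(cfg, seed = 500)
  node_cols <- grep("^node_", names(pheno), value = TRUE)
  metrics <- tidyr::pivot_longer(pheno[c("subject_id", node_cols)],
                                 -subject_id, names_to = "node", values_to = "value")
  metrics$measure <- "clustering"
  metrics$density <- "integrated"
  # add fake density-level rows (noise) so gated pairs have something to test
  dens <- purrr::map_dfr(c("0.10", "0.20"), function(d) {
    m <- metrics; m$density <- d
    m$value <- m$value + rnorm(nrow(m), 0, 0.5)
    m
  })
  scan <- run_node_scan(dplyr::bind_rows(metrics, dens),
                        pheno[c("subject_id", "group", names(cfg$loadings))],
                        indicators = names(cfg$loadings))
  integ <- dplyr::filter(scan, density == "integrated")
  expect_equal(nrow(integ), 4)
  expect_true(integ$gate_passed[integ$node == "node_effect"])
  # density rows exist only for gated node x measure pairs
  gated <- integ[integ$gate_passed, c("node", "measure")]
  densrows <- dplyr::filter(scan, density != "integrated")
  expect_true(all(paste(densrows$node, densrows$measure) %in%
                    paste(gated$node, gated$measure)))
  # post-hoc only where gated
  has_ph <- !purrr::map_lgl(integ$posthoc, is.null)
  expect_equal(has_ph, integ$gate_passed)
  # adjusted never below raw
  expect_true(all(scan$p_diff_fdr >= scan$p_diff - 1e-12, na.rm = TRUE))
  # determinism: identical inputs give identical results
  scan2 <- run_node_scan(dplyr::bind_rows(metrics, dens),
                         pheno[c("subject_id", "group", names(cfg$loadings))],
                         indicators = names(cfg$loadings))
  expect_equal(scan, scan2)
})

test_that("scan rows record errors instead of aborting", {
  cfg <- cohort_config(n = c(40, 20, 20))
  pheno <- generate_phenotypes(cfg, seed = 501)
  metrics <- tibble::tibble(subject_id = pheno$subject_id, node = "bad",
                            measure = "clustering", density = "integrated",
                            value = 0)  # zero-variance outcome: unfittable
  scan <- run_node_scan(metrics, pheno[c("subject_id", "group", names(cfg$loadings))],
                        indicators = names(cfg$loadings))
  expect_false(is.na(scan$error[1]))
  expect_true(is.na(scan$p_diff[1]))
})

test_that("the overall-connectivity check is calibrated, powerful, and matches a permutation oracle", {
  set.seed(60)
  # null calibration
  rej <- replicate(300, {
    d <- tibble::tibble(group = rep(c("a", "b", "c"), times = c(30, 15, 15)),
                        mean_connectivity = rnorm(60))
    overall_connectivity_test(d)$p.value < 0.05
  })
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)

  # extreme separation
  d <- tibble::tibble(group = rep(c("a", "b"), each = 25),
                      mean_connectivity = c(rnorm(25), rnorm(25, 3)))
  expect_lt(overall_connectivity_test(d)$p.value, 1e-4)

  # agreement with a permutation distribution of the same statistic
  set.seed(61)
  d <- tibble::tibble(group = rep(c("a", "b", "c"), times = c(10, 8, 7)),
                      mean_connectivity = rnorm(25))
  obs <- overall_connectivity_test(d)
  stat_perm <- replicate(4000, {
    kruskal.test(d$mean_connectivity, factor(sample(d$group)))$statistic
  })
  p_perm <- mean(stat_perm >= obs$statistic)
  expect_lt(abs(p_perm - obs$p.value), 0.03)

  expect_error(overall_connectivity_test(
    tibble::tibble(group = "a", mean_connectivity = 1)), "2 groups")
})
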