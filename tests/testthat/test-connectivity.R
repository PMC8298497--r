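test_that("Pearson correlation matrix matches textbook values and a two-pass oracle", {
  # perfect correlation / anticorrelation
  ts <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  r <- compute_correlation_matrix(ts)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_true(isSymmetric(r))

  # hand-computed value via the sum formulas: rows (1,2,3,4) and (1,2,4,3)
  r2 <- compute_correlation_matrix(rbind(x = c(1, 2, 3, 4), y = c(1, 2, 4, 3)))
  expect_equal(r2["x", "y"], 0.8, tolerance = 1e-12)

  # random inputs vs an explicit two-pass covariance computation
  set.seed(42)
  for (rep in 1:5) {
    X <- matrix(rnorm(8 * 30), 8, 30)
    r <- compute_correlation_matrix(X)
    mu <- rowMeans(X)
    Xc <- X - mu
    covm <- Xc %*% t(Xc) / (ncol(X) - 1)
    oracle <- covm / tcrossprod(sqrt(diag(covm)))
    expect_lt(max(abs(r - oracle)), 1e-12)
  }

  # error paths
  flat <- rbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4))
  expect_error(compute_correlation_matrix(flat), "zero-variance.*a")
  expect_error(compute_correlation_matrix(rbind(a = 1:3)), "2 parcels")
  expect_error(compute_correlation_matrix(cbind(1:3, 2:4)), "3 timepoints")
})

test_that("absolute Fisher z-transform is even in r, clipped, and order-insensitive", {
  r <- matrix(c(1, 0, 0.5, -0.5,
                0, 1, 0.3, 1,
                0.5, 0.3, 1, -1,
                -0.5, 1, -1, 1), 4, 4)
  z <- fisher_transform_abs(r)
  expect_equal(z[1, 3], 0.5 * log(1.5 / 0.5), tolerance = 1e-12)  # atanh via log
  expect_equal(z[1, 3], 0.5493, tolerance = 1e-4)
  expect_equal(z[1, 4], z[1, 3])            # |atanh(-r)| = |atanh(r)|
  expect_equal(z[1, 2], 0)
  expect_equal(diag(z), rep(0, 4))
  expect_true(all(is.finite(z)))            # r = +/-1 clipped, not Inf
  expect_true(all(z >= 0))

  # the two readings of the transform order coincide: |atanh(r)| == atanh(|r|)
  grid <- seq(-0.999, 0.999, length.out = 201)
  expect_equal(abs(atanh(grid)), atanh(abs(grid)), tolerance = 1e-12)

  expect_error(fisher_transform_abs(matrix(c(1, 1.5, 1.5, 1), 2, 2)), "outside")
})

test_that("density thresholding keeps exactly the k strongest pairs with a deterministic tie rule", {
  # 5 nodes, 10 pairs, density 0.20 -> the 2 largest weights
  set.seed(7)
  w <- matrix(0, 5, 5)
  w[upper.tri(w)] <- c(5, 9, 1, 2, 8, 3, 4, 7, 6, 0.5) / 10
  w <- w + t(w)
  adj <- binarize_at_density(w, 0.20)
  expect_equal(sum(adj) / 2, 2)
  expect_true(adj[1, 3] && adj[2, 4])       # weights 0.9 and 0.8

  # all weights equal: the lexicographically smallest pair wins the single slot
  eq <- matrix(1, 5, 5); diag(eq) <- 0
  adj1 <- binarize_at_density(eq, 0.10)
  expect_equal(sum(adj1) / 2, 1)
  expect_true(adj1[1, 2])

  # density 1 -> complete graph; k = 0 -> error
  expect_equal(sum(binarize_at_density(w, 1)) / 2, 10)
  expect_error(binarize_at_density(w, 0.01), "zero edges")

  # edge-count exactness over random matrices of varied size
  set.seed(11)
  for (n in c(5, 12, 23, 37, 50)) {
    cm <- matrix(0, n, n)
    cm[upper.tri(cm)] <- runif(n * (n - 1) / 2)
    cm <- cm + t(cm)
    for (d in c(0.1, 0.25, 0.4, 0.77)) {
      k <- floor(d * n * (n - 1) / 2 + 0.5)
      expect_equal(sum(binarize_at_density(cm, d)) / 2, k)
    }
  }
})

test_that("graph sets use the seven default densities, expected edge counts, and are nested", {
  set.seed(3)
  n <- 20
  cm <- matrix(0, n, n)
  cm[upper.tri(cm)] <- sample(rep(c(0.2, 0.5, 0.8), length.out = n * (n - 1) / 2))  # heavy ties
  cm <- cm + t(cm)
  gs <- build_graph_set(cm, subject_id = "s1")
  expect_length(gs$adjacency, 7)
  counts <- vapply(gs$adjacency, function(a) sum(a) / 2, numeric(1))
  expect_equal(unname(counts), c(19, 29, 38, 48, 57, 67, 76))  # round(d * 190)

  # nestedness even with massive ties
  for (k in 1:6) {
    expect_true(all(gs$adjacency[[k]] <= gs$adjacency[[k + 1]]))
  }
  expect_error(build_graph_set(cm, densities = c(0.2, 0.2)), "increasing")
  expect_length(build_graph_set(cm, densities = 0.5)$adjacency, 1)
})

test_that("motion exclusion retains subjects at or below the FD threshold", {
  motion <- tibble::tibble(subject_id = c("s1", "s2", "s3"),
                           rms_fd = c(0.10, 0.30, 0.25))
  scr <- exclude_high_motion(c("s1", "s2", "s3"), motion, quiet = TRUE)
  expect_equal(scr$retained, c(TRUE, FALSE, TRUE))  # boundary 0.25 retained
  expect_equal(scr$subject_id[scr$retained], c("s1", "s3"))
  allkept <- exclude_high_motion(c("s1"), motion, quiet = TRUE)
  expect_true(all(allkept$retained))
  expect_error(exclude_high_motion(c("s1", "s9"), motion), "s9")
})

test_that("node selection is strict and order-preserving", {
  tab <- tibble::tibble(parcel_id = c("a", "b", "c"),
                        overlap_fraction = c(0.31, 0.30, 0.29))
  expect_equal(select_nodes(tab)$parcel_id, "a")   # strictly greater than 0.30
  tab$overlap_fraction <- c(1, 1, 1)
  expect_equal(select_nodes(tab)$parcel_id, c("a", "b", "c"))
  tab$overlap_fraction <- c(0, 0, 0)
  expect_warning(res <- select_nodes(tab), "no parcel")
  expect_equal(nrow(res), 0)
  tab$overlap_fraction <- c(0.5, 1.2, 0)
  expect_error(select_nodes(tab), "\\[0, 1\\]")
})

test_that("mean connectivity averages the upper triangle, symmetric in orientation", {
  cm <- matrix(0, 3, 3)
  cm[upper.tri(cm)] <- c(0.2, 0.4, 0.6)
  cm <- cm + t(cm)
  expect_equal(mean_connectivity(cm), 0.4)
  expect_equal(mean_connectivity(cm), mean(t(cm)[upper.tri(cm)]))
  allc <- matrix(0.7, 4, 4); diag(allc) <- 0
  expect_equal(mean_connectivity(allc), 0.7)
})
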