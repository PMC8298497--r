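# Brute-force oracles for the nodal measures, independent of the package
# implementation (no igraph, no power iteration): Floyd-Warshall distance
# tables, walk-count shortest-path enumeration, dense eigendecomposition.

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- ifelse(A, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

oracle_clustering <- function(A) {
  A1 <- A * 1
  deg <- rowSums(A1)
  tri <- diag(A1 %*% A1 %*% A1)  # 2 * triangles through each node
  ifelse(deg < 2, 0, tri / (deg * (deg - 1)))
}

oracle_nodal_eff <- function(A) {
  D <- oracle_distances(A)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  rowSums(inv) / (nrow(A) - 1)
}

oracle_closeness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  sapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    r <- length(d) + 1
    if (r == 1) 0 else ((r - 1) / (n - 1)) * ((r - 1) / sum(d))
  })
}

oracle_local_eff <- function(A) {
  n <- nrow(A)
  sapply(seq_len(n), function(i) {
    nb <- which(A[i, ])
    if (length(nb) < 2) return(0)
    sub <- A[nb, nb, drop = FALSE]
    D <- oracle_distances(sub)
    inv <- 1 / D[upper.tri(D)]
    inv[!is.finite(inv)] <- 0
    mean(inv)
  })
}

# shortest-path counts from walk counts: since no walk shorter than d(i,j)
# exists, (A^d)[i,j] counts exactly the shortest paths
oracle_betweenness <- function(A) {
  n <- nrow(A)
  A1 <- A * 1
  D <- oracle_distances(A)
  maxd <- max(D[is.finite(D)])
  pows <- vector("list", max(maxd, 1))
  pows[[1]] <- A1
  if (maxd >= 2) for (l in 2:maxd) pows[[l]] <- pows[[l - 1]] %*% A1
  npaths <- function(i, j) {
    d <- D[i, j]
    if (!is.finite(d) || d == 0) return(0)
    pows[[d]][i, j]
  }
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t])) next
    tot <- npaths(s, t)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) && D[s, v] + D[v, t] == D[s, t]) {
        b[v] <- b[v] + npaths(s, v) * npaths(v, t) / tot
      }
    }
  }
  if (n > 2) b / ((n - 1) * (n - 2) / 2) else b
}

# dense eigendecomposition; NULL when the dominant eigenvalue is numerically
# degenerate (centrality then depends on the tie-breaking convention)
oracle_eigenvector <- function(A) {
  e <- eigen(A * 1, symmetric = TRUE)
  if (length(e$values) > 1 && e$values[1] - e$values[2] < 1e-8) return(NULL)
  v <- abs(e$vectors[, 1])
  v / sqrt(sum(v^2))
}

oracle_funs <- list(
  clustering       = oracle_clustering,
  local_efficiency = oracle_local_eff,
  nodal_efficiency = oracle_nodal_eff,
  betweenness      = oracle_betweenness,
  closeness        = oracle_closeness,
  eigenvector      = oracle_eigenvector
)

impl_funs <- list(
  clustering       = clustering_coefficient,
  local_efficiency = local_efficiency,
  nodal_efficiency = nodal_efficiency,
  betweenness      = betweenness_centrality,
  closeness        = closeness_centrality,
  eigenvector      = eigenvector_centrality
)

random_adjacency <- function(n, p) {
  A <- matrix(FALSE, n, n, dimnames = list(paste0("n", 1:n), paste0("n", 1:n)))
  A[upper.tri(A)] <- runif(n * (n - 1) / 2) < p
  A | t(A)
}

# all labeled graphs on n nodes, as a list of adjacency matrices
enumerate_graphs <- function(n) {
  npairs <- n * (n - 1) / 2
  ut <- which(upper.tri(matrix(0, n, n)))
  lapply(seq_len(2^npairs) - 1L, function(code) {
    A <- matrix(FALSE, n, n, dimnames = list(paste0("n", 1:n), paste0("n", 1:n)))
    A[ut] <- bitwAnd(bitwShiftR(code, seq_len(npairs) - 1L), 1L) == 1L
    A | t(A)
  })
}

# max abs error between implementation and oracle over all applicable measures
max_measure_error <- function(A) {
  err <- 0
  for (m in names(impl_funs)) {
    if (m == "eigenvector") {
      if (sum(A) == 0) next
      ov <- oracle_eigenvector(A)
      if (is.null(ov)) next
      err <- max(err, max(abs(unname(impl_funs[[m]](A)) - ov)))
    } else {
      err <- max(err, max(abs(unname(impl_funs[[m]](A)) - oracle_funs[[m]](A))))
    }
  }
  err
}
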