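#' Pearson correlation matrix from a parcellated time series
#'
#' Computes pairwise Pearson correlations between parcel time courses. Rows of
#' `data` are parcels, columns are timepoints, as produced by averaging BOLD
#' intensity within each parcel of an atlas.
#'
#' @param data Numeric matrix, parcels x timepoints. Row names (or `parcel_ids`)
#'   label the parcels.
#' @param parcel_ids Optional character vector of parcel labels; defaults to the
#'   row names of `data` or `"P1"..` when absent.
#' @return Symmetric correlation matrix with unit diagonal, dimnames set to the
#'   parcel labels.
#' @examples
#' ts <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 4, 3))
#' compute_correlation_matrix(ts)
#' @export
compute_correlation_matrix <- function(data, parcel_ids = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 2) stop("need at least 2 parcels")
  if (ncol(data) < 3) stop("need at least 3 timepoints")
  if (anyNA(data) || any(!is.finite(data))) stop("time series contains missing or non-finite values")
  if (is.null(parcel_ids)) parcel_ids <- rownames(data)
  if (is.null(parcel_ids)) parcel_ids <- paste0("P", seq_len(nrow(data)))
  sds <- apply(data, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance parcel(s): ", paste(parcel_ids[sds == 0], collapse = ", "))
  }
  r <- stats::cor(t(data))
  r <- (r + t(r)) / 2           # enforce exact symmetry
  diag(r) <- 1
  dimnames(r) <- list(parcel_ids, parcel_ids)
  r
}

#' Absolute Fisher-z connectivity matrix
#'
#' Applies the Fisher z-transform (`atanh`) to a correlation matrix and takes
#' absolute values, yielding a nonnegative connectivity matrix in which
#' anti-correlations count as connections. Correlations are clipped to
#' `1 - eps` in magnitude so collinear parcels give finite weights.
#'
#' @param r_matrix Symmetric correlation matrix (entries in \[-1, 1\]).
#' @param eps Clipping margin away from |r| = 1. Default `1e-7`.
#' @return Symmetric nonnegative matrix of |atanh(r)| with zero diagonal,
#'   class `"connectivity_matrix"`.
#' @export
fisher_transform_abs <- function(r_matrix, eps = 1e-7) {
  r <- as.matrix(r_matrix)
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("correlations outside [-1, 1]")
  r <- pmin(pmax(r, -(1 - eps)), 1 - eps)
  z <- abs(atanh(r))
  diag(z) <- 0
  structure(z, class = c("connectivity_matrix", class(z)))
}

# Deterministic ranking of the upper-triangle pairs of a connectivity matrix:
# weight descending, then node-pair (i, j) lexicographic ascending. All density
# thresholds share this one ordering, which makes graphs nested across densities.
.pair_order <- function(cm) {
  n <- nrow(cm)
  idx <- which(upper.tri(cm), arr.ind = TRUE)   # column-major: not yet lexicographic
  w <- cm[idx]
  ord <- order(-w, idx[, 1L], idx[, 2L])
  list(i = idx[ord, 1L], j = idx[ord, 2L], w = w[ord], n = n)
}

# round half away from zero (base round() is banker's)
.round_half_up <- function(x) floor(x + 0.5)

#' Binarize a connectivity matrix at a target density
#'
#' Keeps exactly the `round(density * n(n-1)/2)` strongest off-diagonal pairs as
#' edges of a simple undirected graph, so that subjects' graphs have identical
#' edge counts and topology is decoupled from overall connectivity strength.
#' Ties at the cutoff are broken by node-pair lexicographic order, which makes
#' the result deterministic and nested across densities.
#'
#' @param cm Connectivity matrix (symmetric, nonnegative).
#' @param density Target edge density in (0, 1].
#' @return Logical adjacency matrix with dimnames of `cm`.
#' @export
binarize_at_density <- function(cm, density) {
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  po <- .pair_order(cm)
  n <- po$n
  k <- .round_half_up(density * n * (n - 1) / 2)
  if (k == 0) stop("density ", density, " gives zero edges on ", n, " nodes")
  adj <- matrix(FALSE, n, n, dimnames = dimnames(cm))
  sel <- seq_len(k)
  adj[cbind(po$i[sel], po$j[sel])] <- TRUE
  adj | t(adj)
}

#' Build the per-subject family of density-thresholded graphs
#'
#' @param cm Connectivity matrix.
#' @param densities Strictly increasing vector of target densities. The default
#'   is the seven equally spaced levels 0.10-0.40.
#' @param subject_id Optional subject label carried through to metric tables.
#' @return An object of class `"graph_set"`: a list with `subject_id`,
#'   `node_ids`, `densities`, and `adjacency` (one logical matrix per density).
#'   Graphs are nested: the graph at a lower density is an edge-subset of the
#'   graph at any higher density.
#' @export
build_graph_set <- function(cm, densities = seq(0.10, 0.40, by = 0.05),
                            subject_id = NULL) {
  if (any(diff(densities) <= 0)) stop("densities must be strictly increasing")
  adj <- lapply(densities, function(d) binarize_at_density(cm, d))
  names(adj) <- format_density(densities)
  structure(
    list(subject_id = subject_id,
         node_ids = rownames(cm) %||% paste0("P", seq_len(nrow(cm))),
         densities = densities,
         adjacency = adj),
    class = "graph_set"
  )
}

format_density <- function(d) formatC(d, format = "f", digits = 2)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.graph_set <- function(x, ...) {
  cat("<graph_set>", if (!is.null(x$subject_id)) paste0(" subject ", x$subject_id), "\n",
      length(x$node_ids), " nodes; densities ",
      paste(format_density(x$densities), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Exclude high-motion subjects
#'
#' Retains subjects whose root-mean-square framewise displacement does not
#' exceed the threshold (default 0.25 mm).
#'
#' @param subjects Character vector of subject IDs to screen.
#' @param motion Data frame with columns `subject_id` and `rms_fd` (mm).
#' @param threshold Retention bound; a subject is kept iff `rms_fd <= threshold`.
#' @param quiet Suppress the per-exclusion message.
#' @return Tibble with columns `subject_id`, `rms_fd`, `retained`.
#' @export
exclude_high_motion <- function(subjects, motion, threshold = 0.25, quiet = FALSE) {
  motion <- tibble::as_tibble(motion)
  missing <- setdiff(subjects, motion$subject_id)
  if (length(missing) > 0) {
    stop("no motion record for subject(s): ", paste(missing, collapse = ", "))
  }
  out <- motion[match(subjects, motion$subject_id), c("subject_id", "rms_fd")]
  out$retained <- out$rms_fd <= threshold
  if (!quiet && any(!out$retained)) {
    message("excluding ", sum(!out$retained), " subject(s) with rms FD > ", threshold, ": ",
            paste(out$subject_id[!out$retained], collapse = ", "))
  }
  out
}

#' Select analysis nodes by anatomical overlap
#'
#' Keeps parcels whose overlap with the anatomical regions of interest exceeds
#' `min_overlap` (strictly), preserving input order.
#'
#' @param overlap_table Data frame with columns `parcel_id` and
#'   `overlap_fraction` (in \[0, 1\]); an optional `region_label` is carried
#'   through.
#' @param min_overlap Strict lower bound on the overlap fraction; default 0.30.
#' @return Tibble of retained rows.
#' @export
select_nodes <- function(overlap_table, min_overlap = 0.30) {
  overlap_table <- tibble::as_tibble(overlap_table)
  f <- overlap_table$overlap_fraction
  if (any(f < 0 | f > 1)) stop("overlap fractions must be in [0, 1]")
  out <- overlap_table[f > min_overlap, , drop = FALSE]
  if (nrow(out) == 0) warning("no parcel exceeds the overlap threshold ", min_overlap)
  out
}

#' Mean connectivity strength of a subject's network
#'
#' Arithmetic mean of the upper-triangle entries of a connectivity matrix; used
#' as the per-subject overall connectivity strength in robustness checks.
#'
#' @param cm Connectivity matrix.
#' @return Scalar mean connectivity.
#' @export
mean_connectivity <- function(cm) {
  mean(cm[upper.tri(cm)])
}
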