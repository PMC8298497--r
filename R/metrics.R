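#' @title Nodal topology measures on binary undirected graphs
#' @description
#' Six per-node measures of local integration and centrality, computed on a
#' logical adjacency matrix: clustering coefficient, local efficiency, nodal
#' efficiency, betweenness, closeness, and eigenvector centrality. Conventions
#' for disconnected graphs: efficiency contributions of unreachable pairs are
#' zero, closeness is component-scaled, betweenness does not count endpoints,
#' and eigenvector centrality is the dominant eigenvector of the whole graph.
#' All measures lie in \[0, 1\] (eigenvector under L2 normalization).
#' @param adj Logical or 0/1 symmetric adjacency matrix with zero diagonal.
#' @return Named numeric vector, one value per node.
#' @name nodal-measures
NULL

.as_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected", diag = FALSE)
}

#' @rdname nodal-measures
#' @export
clustering_coefficient <- function(adj) {
  g <- .as_igraph(adj)
  out <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(out) <- rownames(adj)
  out
}

#' @rdname nodal-measures
#' @details
#' Local efficiency of node *i* is the global efficiency of the subgraph
#' induced by the neighbors of *i* (paths may not detour through *i* itself or
#' any non-neighbor): the mean over unordered neighbor pairs of the inverse
#' within-subgraph distance, with unreachable pairs contributing 0, and 0 for
#' nodes of degree < 2.
#' @export
local_efficiency <- function(adj) {
  n <- nrow(adj)
  out <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ])
    if (length(nb) < 2) return(0)
    d <- igraph::distances(.as_igraph(adj[nb, nb, drop = FALSE]))
    inv <- 1 / d[upper.tri(d)]
    inv[!is.finite(inv)] <- 0
    mean(inv)
  }, numeric(1))
  names(out) <- rownames(adj)
  out
}

#' @rdname nodal-measures
#' @export
nodal_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) stop("nodal efficiency needs at least 2 nodes")
  d <- igraph::distances(.as_igraph(adj))
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  out <- rowSums(inv) / (n - 1)
  names(out) <- rownames(adj)
  out
}

#' @rdname nodal-measures
#' @export
betweenness_centrality <- function(adj) {
  n <- nrow(adj)
  g <- .as_igraph(adj)
  b <- igraph::betweenness(g, directed = FALSE)
  if (n > 2) b <- b / ((n - 1) * (n - 2) / 2)
  names(b) <- rownames(adj)
  b
}

#' @rdname nodal-measures
#' @export
closeness_centrality <- function(adj) {
  # component-scaled (Wasserman-Faust) closeness: ((r-1)/(n-1)) * ((r-1)/sum d),
  # with r the size of the node's reachable set (incl. itself); isolated -> 0
  n <- nrow(adj)
  d <- igraph::distances(.as_igraph(adj))
  out <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    r <- length(reach) + 1
    if (r == 1) return(0)
    ((r - 1) / (n - 1)) * ((r - 1) / sum(reach))
  }, numeric(1))
  names(out) <- rownames(adj)
  out
}

#' @rdname nodal-measures
#' @param tol Convergence tolerance of the power iteration (max-abs change
#'   between successive normalized iterates).
#' @param max_iter Iteration cap.
#' @details
#' Eigenvector centrality is computed by power iteration on `A + I` from a
#' uniform start vector. The identity shift leaves the eigenvectors of `A`
#' unchanged while making the dominant eigenvalue strictly largest in
#' magnitude, so the iteration also converges on bipartite graphs. The result
#' is entrywise nonnegative and L2-normalized.
#' @export
eigenvector_centrality <- function(adj, tol = 1e-12, max_iter = 50000) {
  n <- nrow(adj)
  A <- (adj * 1) + diag(n)
  if (sum(adj) == 0) stop("eigenvector centrality needs at least one edge")
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    y <- as.numeric(A %*% x)
    y <- y / sqrt(sum(y^2))
    if (max(abs(y - x)) < tol) {
      names(y) <- rownames(adj)
      return(abs(y))
    }
    x <- y
  }
  stop("power iteration did not converge in ", max_iter,
       " iterations (last change ", format(max(abs(y - x))), ")")
}

#' Density-integrate per-density metric values
#'
#' Summarizes a nodal measure across equally spaced density thresholds by the
#' arithmetic mean, removing the dependence on any single cutoff.
#'
#' @param values Numeric vector of per-density values (equally spaced levels).
#' @return Scalar integrated value.
#' @export
density_integrate <- function(values) {
  if (length(values) < 1 || any(!is.finite(values))) {
    stop("density integration requires at least one finite value per level")
  }
  mean(values)
}

.measure_funs <- list(
  clustering       = clustering_coefficient,
  local_efficiency = local_efficiency,
  nodal_efficiency = nodal_efficiency,
  betweenness      = betweenness_centrality,
  closeness        = closeness_centrality,
  eigenvector      = eigenvector_centrality
)

#' Available nodal measures
#' @return Character vector of measure names understood by
#'   [compute_nodal_metrics()].
#' @export
nodal_measures <- function() names(.measure_funs)

#' Compute a tidy nodal metric table for one or many subjects
#'
#' Evaluates the requested nodal measures on every density-specific graph of
#' each subject and (optionally) appends the density-integrated value, i.e. the
#' mean across density levels, labelled `"integrated"`.
#'
#' @param graph_sets A single `graph_set` (from [build_graph_set()]) or a list
#'   of them.
#' @param measures Character vector of measures; default all six.
#' @param integrate Append density-integrated rows? Default `TRUE`.
#' @param nodes Optional subset of node IDs to report (metrics are still
#'   computed on the full graphs).
#' @return Tibble with columns `subject_id`, `node`, `measure`, `density`
#'   (formatted density level or `"integrated"`), `value`.
#' @export
compute_nodal_metrics <- function(graph_sets, measures = nodal_measures(),
                                  integrate = TRUE, nodes = NULL) {
  if (inherits(graph_sets, "graph_set")) graph_sets <- list(graph_sets)
  measures <- match.arg(measures, nodal_measures(), several.ok = TRUE)
  purrr::map_dfr(graph_sets, function(gs) {
    per_density <- purrr::map_dfr(seq_along(gs$densities), function(k) {
      adj <- gs$adjacency[[k]]
      purrr::map_dfr(measures, function(m) {
        tibble::tibble(
          subject_id = gs$subject_id %||% NA_character_,
          node = gs$node_ids,
          measure = m,
          density = format_density(gs$densities[k]),
          value = unname(.measure_funs[[m]](adj))
        )
      })
    })
    out <- per_density
    if (integrate) {
      integ <- per_density |>
        dplyr::group_by(.data$subject_id, .data$node, .data$measure) |>
        dplyr::summarise(density = "integrated",
                         value = density_integrate(.data$value),
                         .groups = "drop")
      out <- dplyr::bind_rows(per_density, integ)
    }
    if (!is.null(nodes)) out <- dplyr::filter(out, .data$node %in% nodes)
    out
  })
}

#' Plot nodal metrics across density thresholds
#'
#' One line per node, faceted by measure; the density-integrated value is shown
#' as a dashed horizontal reference.
#'
#' @param metrics Metric table from [compute_nodal_metrics()].
#' @param nodes Optional node subset.
#' @return A ggplot object.
#' @export
plot_metric_profiles <- function(metrics, nodes = NULL) {
  if (!is.null(nodes)) metrics <- dplyr::filter(metrics, .data$node %in% nodes)
  dens <- dplyr::filter(metrics, .data$density != "integrated") |>
    dplyr::mutate(density = as.numeric(.data$density))
  integ <- dplyr::filter(metrics, .data$density == "integrated")
  p <- ggplot2::ggplot(dens, ggplot2::aes(x = .data$density, y = .data$value,
                                          group = .data$node, colour = .data$node)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y") +
    ggplot2::labs(x = "network density", y = "nodal measure")
  if (nrow(integ) > 0) {
    p <- p + ggplot2::geom_hline(data = integ,
                                 ggplot2::aes(yintercept = .data$value, colour = .data$node),
                                 linetype = "dashed", alpha = 0.5)
  }
  p
}
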