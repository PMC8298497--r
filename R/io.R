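# Plain-text interchange: per-subject time-series tables, motion and overlap
# tables, edge lists and long metric tables. All TSV/CSV via readr.

#' Read a parcellated time-series table
#'
#' Expects one file per subject: first column the parcel ID, remaining columns
#' timepoints.
#'
#' @param path File path (TSV by default; `delim` is passed to
#'   [readr::read_delim()]).
#' @param delim Field delimiter.
#' @return Numeric matrix, parcels x timepoints, with parcel IDs as row names.
#' @export
read_subject_timeseries <- function(path, delim = "\t") {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Read a cohort of time series from a manifest
#'
#' @param manifest_path CSV with columns `subject_id`, `path` (paths relative
#'   to the manifest's directory or absolute).
#' @return Named list of time-series matrices.
#' @export
read_timeseries_manifest <- function(manifest_path) {
  man <- readr::read_csv(manifest_path, show_col_types = FALSE)
  base <- dirname(manifest_path)
  paths <- ifelse(file.exists(man$path), man$path, file.path(base, man$path))
  out <- lapply(paths, read_subject_timeseries)
  names(out) <- man$subject_id
  out
}

#' Write a graph set as an edge-list table
#'
#' @param graph_set A `graph_set` (see [build_graph_set()]).
#' @param path Output TSV with columns `subject_id`, `density`, `node_u`,
#'   `node_v`.
#' @export
write_graph_set <- function(graph_set, path) {
  rows <- purrr::map_dfr(seq_along(graph_set$densities), function(k) {
    adj <- graph_set$adjacency[[k]]
    idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
    tibble::tibble(
      subject_id = graph_set$subject_id %||% NA_character_,
      density = format_density(graph_set$densities[k]),
      node_u = rownames(adj)[idx[, 1]],
      node_v = colnames(adj)[idx[, 2]]
    )
  })
  readr::write_tsv(rows, path)
  invisible(path)
}

#' Write / read a long nodal-metric table
#'
#' @param metrics Metric tibble from [compute_nodal_metrics()].
#' @param path TSV path.
#' @export
write_metric_table <- function(metrics, path) {
  readr::write_tsv(metrics, path)
  invisible(path)
}

#' @rdname write_metric_table
#' @export
read_metric_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(density = readr::col_character()))
}

#' Write scan results as a flat table
#'
#' Unnests the per-group effects (dropping the post-hoc list-column, which is
#' written to `<path>_posthoc.tsv` alongside when present).
#'
#' @param scan An `"edsem_scan"`.
#' @param path Output TSV path.
#' @export
write_scan_results <- function(scan, path) {
  readr::write_tsv(tidy(scan), path)
  ph <- dplyr::filter(tibble::as_tibble(scan), .data$density == "integrated",
                      !purrr::map_lgl(.data$posthoc, is.null))
  if (nrow(ph) > 0) {
    flat <- ph[c("node", "measure", "posthoc")]
    flat <- tidyr::unnest(flat, "posthoc")
    readr::write_tsv(flat, sub("(\\.[^.]+)?$", "_posthoc.tsv", path))
  }
  invisible(path)
}
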