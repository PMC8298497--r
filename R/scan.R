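# The study-level inference pipeline: indicator selection by multi-group CFA,
# the node x measure SEM scan with chi-square difference tests, FDR gatekeeping,
# and pairwise post-hoc models.

.default_reference <- function(groups) {
  if ("ADHD-I" %in% groups) "ADHD-I" else groups[1]
}

.group_levels <- function(x) {
  if (is.factor(x)) levels(x) else unique(as.character(x))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1); a thin wrapper around
#' [stats::p.adjust()] kept as the package's single point of control for the
#' multiple-testing procedure.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select latent-factor indicators by multi-group CFA
#'
#' Fits a multi-group confirmatory factor analysis with shared loadings (latent
#' variance standardized in the reference group) on all candidate indicators,
#' retains those whose loading is significant at `alpha`, and refits on the
#' retained set.
#'
#' @param phenotypes Data frame with a grouping column and the candidate
#'   indicator columns.
#' @param indicators Character vector (>= 3) of candidate indicator columns.
#' @param alpha Significance level for a loading to be retained. Default 0.05.
#' @param reference Reference group (latent variance fixed to 1); defaults to
#'   `"ADHD-I"` when present.
#' @param group_col Grouping column name. Default `"group"`.
#' @return Object of class `"edsem_selection"`: list with `retained`,
#'   `dropped`, `loadings` (tibble of loading tests on the full set),
#'   `fit_full`, `fit_retained`.
#' @export
select_indicators <- function(phenotypes, indicators, alpha = 0.05,
                              reference = NULL, group_col = "group") {
  if (length(indicators) < 3) stop("at least 3 candidate indicators are required")
  groups <- .group_levels(phenotypes[[group_col]])
  reference <- reference %||% .default_reference(groups)
  spec_full <- sem_model_spec(indicators, groups = groups, reference = reference,
                              group_col = group_col)
  fit_full <- sem_fit_ml(phenotypes, spec_full)
  loadings <- dplyr::filter(fit_full$estimates, grepl("^lambda\\[", .data$parameter))
  loadings$indicator <- sub("^lambda\\[(.*)\\]$", "\\1", loadings$parameter)
  loadings$retained <- !is.na(loadings$p.value) & loadings$p.value < alpha
  retained <- loadings$indicator[loadings$retained]
  if (length(retained) < 3) {
    stop("fewer than 3 indicators retained (", length(retained),
         "); the latent variable is under-identified")
  }
  spec_ret <- sem_model_spec(retained, groups = groups, reference = reference,
                             group_col = group_col)
  structure(
    list(retained = retained,
         dropped = setdiff(indicators, retained),
         loadings = loadings[c("indicator", "estimate", "se", "z", "p.value", "retained")],
         fit_full = fit_full,
         fit_retained = sem_fit_ml(phenotypes, spec_ret),
         alpha = alpha),
    class = "edsem_selection"
  )
}

#' @export
print.edsem_selection <- function(x, ...) {
  cat("<edsem_selection> retained", length(x$retained), "of",
      nrow(x$loadings), "candidate indicators (alpha =", x$alpha, ")\n")
  print(x$loadings)
  invisible(x)
}

#' @export
tidy.edsem_selection <- function(x, ...) x$loadings

# fit the free and shared-slope models for one outcome column and return the
# row-level summary used by the scan; errors are captured, not propagated.
# Model variables are standardized by their overall SD first: every reported
# quantity (z, difference-test p, completely standardized estimates, fit
# indices) is invariant to this, and it keeps the optimizer well-scaled when
# topology outcomes have tiny raw variance.
.scan_cell <- function(data, indicators, outcome, groups, reference, group_col) {
  tryCatch({
    for (v in c(indicators, outcome)) {
      s <- stats::sd(data[[v]])
      if (!is.finite(s) || s == 0) stop("variable ", v, " has zero variance")
      data[[v]] <- data[[v]] / s
    }
    spec_f <- sem_model_spec(indicators, outcome = outcome, groups = groups,
                             reference = reference, beta = "free", group_col = group_col)
    spec_c <- sem_model_spec(indicators, outcome = outcome, groups = groups,
                             reference = reference, beta = "shared", group_col = group_col)
    fit_f <- sem_fit_ml(data, spec_f)
    fit_c <- sem_fit_ml(data, spec_c, se = FALSE)
    dt <- chi_square_difference(fit_f, fit_c)
    betas <- dplyr::filter(fit_f$estimates, .data$parameter == "beta")
    std <- dplyr::filter(standardized_solution(fit_f), .data$parameter == "beta")
    eff <- tibble::tibble(
      group = betas$group, z = betas$z, p.value = betas$p.value,
      beta_std = std$std_estimate[match(betas$group, std$group)]
    )
    tibble::tibble(
      chisq = fit_f$statistic, df = fit_f$df, p_model = fit_f$p_value,
      cfi = fit_f$indices$cfi, srmr = fit_f$indices$srmr, rmsea = fit_f$indices$rmsea,
      p_diff = dt$p.value, delta_chisq = dt$statistic, delta_df = dt$df,
      converged = fit_f$converged && fit_c$converged,
      group_effects = list(eff), error = NA_character_
    )
  }, error = function(e) {
    tibble::tibble(
      chisq = NA_real_, df = NA_integer_, p_model = NA_real_,
      cfi = NA_real_, srmr = NA_real_, rmsea = NA_real_,
      p_diff = NA_real_, delta_chisq = NA_real_, delta_df = NA_integer_,
      converged = FALSE, group_effects = list(NULL),
      error = conditionMessage(e)
    )
  })
}

#' Post-hoc pairwise two-group SEM comparisons
#'
#' For each pair of groups fits the two-group analogue of the scan model (free
#' versus shared regression slope, one constraint) and Bonferroni-corrects the
#' chi-square difference p-values by the number of pairs.
#'
#' @param data Data frame with the grouping column, indicators and the outcome
#'   column.
#' @param indicators Retained indicator columns.
#' @param outcome Outcome column (a nodal topology value).
#' @param reference Preferred reference group; used for a pair whenever it is a
#'   member, otherwise the pair's first group.
#' @param group_col Grouping column name.
#' @return Tibble with one row per pair: `pair`, `statistic`, `df`, `p.value`,
#'   `p_bonferroni`.
#' @export
posthoc_pairwise <- function(data, indicators, outcome, reference = NULL,
                             group_col = "group") {
  groups <- .group_levels(data[[group_col]])
  reference <- reference %||% .default_reference(groups)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    sub <- data[as.character(data[[group_col]]) %in% pr, , drop = FALSE]
    ref <- if (reference %in% pr) reference else pr[1]
    res <- tryCatch({
      spec_f <- sem_model_spec(indicators, outcome = outcome, groups = pr,
                               reference = ref, beta = "free", group_col = group_col)
      spec_c <- sem_model_spec(indicators, outcome = outcome, groups = pr,
                               reference = ref, beta = "shared", group_col = group_col)
      dt <- chi_square_difference(sem_fit_ml(sub, spec_f, se = FALSE),
                                  sem_fit_ml(sub, spec_c, se = FALSE))
      tibble::tibble(statistic = dt$statistic, df = dt$df, p.value = dt$p.value,
                     error = NA_character_)
    }, error = function(e) {
      tibble::tibble(statistic = NA_real_, df = NA_integer_, p.value = NA_real_,
                     error = conditionMessage(e))
    })
    dplyr::bind_cols(tibble::tibble(pair = paste(pr, collapse = " vs ")), res)
  })
  out$p_bonferroni <- pmin(out$p.value * length(pairs), 1)
  out
}

#' Node x measure SEM scan with density-integrated gatekeeping
#'
#' The study's main inference loop. For every node x measure pair, the
#' density-integrated topology value is regressed on the latent factor in a
#' three-group SEM; the group-specific-slope model is compared with the
#' shared-slope model by a chi-square difference test. The integrated-level
#' p-values form one FDR family across all node x measure pairs. Pairs that are
#' significant at the integrated level (the gate; FDR-adjusted by default) are
#' then tested at each density threshold, with a second FDR family across
#' densities within the pair, and followed up with Bonferroni-corrected
#' pairwise two-group models on the integrated value.
#'
#' @param metrics Long metric table ([compute_nodal_metrics()]): columns
#'   `subject_id`, `node`, `measure`, `density` (incl. `"integrated"`), `value`.
#' @param phenotypes Data frame with `subject_id`, the grouping column, and the
#'   indicator columns.
#' @param indicators Retained indicator columns (see [select_indicators()]).
#' @param nodes,measures Optional subsets; default everything in `metrics`.
#' @param alpha Significance level for the gate and post-hoc flags. Default 0.05.
#' @param gate `"fdr"` (gate on FDR-adjusted integrated p, default) or
#'   `"raw"`.
#' @param posthoc Run pairwise follow-up models for gated pairs? Default `TRUE`.
#' @param reference Reference group; defaults to `"ADHD-I"` when present.
#' @param group_col Grouping column name.
#' @return Tibble of class `"edsem_scan"`, one row per node x measure x
#'   density level (integrated rows always present; density rows only for
#'   gated pairs), with model fit statistics, the difference-test p-values raw
#'   and FDR-adjusted, per-group effects in the `group_effects` list-column,
#'   and post-hoc results in the `posthoc` list-column of integrated rows.
#' @export
run_node_scan <- function(metrics, phenotypes, indicators,
                          nodes = NULL, measures = NULL, alpha = 0.05,
                          gate = c("fdr", "raw"), posthoc = TRUE,
                          reference = NULL, group_col = "group") {
  gate <- match.arg(gate)
  metrics <- tibble::as_tibble(metrics)
  phenotypes <- tibble::as_tibble(phenotypes)
  nodes <- nodes %||% unique(metrics$node)
  measures <- measures %||% unique(metrics$measure)
  groups <- .group_levels(phenotypes[[group_col]])
  reference <- reference %||% .default_reference(groups)
  if (!all(unique(metrics$subject_id) %in% phenotypes$subject_id)) {
    stop("metrics contain subject IDs absent from the phenotype table")
  }

  cells <- tidyr::expand_grid(node = nodes, measure = measures)
  one_level <- function(node, measure, level) {
    vals <- metrics[metrics$node == node & metrics$measure == measure &
                      metrics$density == level, c("subject_id", "value")]
    dat <- dplyr::inner_join(phenotypes, vals, by = "subject_id")
    dat$.outcome <- dat$value
    .scan_cell(dat, indicators, ".outcome", groups, reference, group_col)
  }

  integrated <- purrr::map2_dfr(cells$node, cells$measure, function(nd, ms) {
    dplyr::bind_cols(tibble::tibble(node = nd, measure = ms, density = "integrated"),
                     one_level(nd, ms, "integrated"))
  })
  integrated$p_diff_fdr <- fdr_adjust(integrated$p_diff)
  gate_p <- if (gate == "fdr") integrated$p_diff_fdr else integrated$p_diff
  integrated$gate_passed <- !is.na(gate_p) & gate_p < alpha

  density_levels <- setdiff(unique(metrics$density), "integrated")
  density_rows <- purrr::map_dfr(which(integrated$gate_passed), function(i) {
    nd <- integrated$node[i]; ms <- integrated$measure[i]
    rows <- purrr::map_dfr(density_levels, function(dl) {
      dplyr::bind_cols(tibble::tibble(node = nd, measure = ms, density = dl),
                       one_level(nd, ms, dl))
    })
    if (nrow(rows) == 0) return(rows)
    rows$p_diff_fdr <- fdr_adjust(rows$p_diff)
    rows$gate_passed <- NA
    rows
  })

  integrated$posthoc <- vector("list", nrow(integrated))
  if (posthoc) {
    for (i in which(integrated$gate_passed)) {
      vals <- metrics[metrics$node == integrated$node[i] &
                        metrics$measure == integrated$measure[i] &
                        metrics$density == "integrated", c("subject_id", "value")]
      dat <- dplyr::inner_join(phenotypes, vals, by = "subject_id")
      dat$.outcome <- dat$value
      integrated$posthoc[[i]] <- posthoc_pairwise(dat, indicators, ".outcome",
                                                  reference = reference,
                                                  group_col = group_col)
    }
  }
  out <- dplyr::bind_rows(integrated, density_rows)
  out <- dplyr::arrange(out, .data$node, .data$measure,
                        .data$density != "integrated", .data$density)
  attr(out, "alpha") <- alpha
  attr(out, "gate") <- gate
  attr(out, "reference") <- reference
  class(out) <- c("edsem_scan", class(out))
  out
}

#' Unnest per-group effects of a scan
#'
#' @param x An `"edsem_scan"`.
#' @param ... Unused.
#' @return Long tibble with one row per node x measure x density x group.
#' @export
tidy.edsem_scan <- function(x, ...) {
  flat <- dplyr::select(tibble::as_tibble(x), -dplyr::any_of("posthoc"))
  tidyr::unnest(flat, "group_effects")
}

#' Kruskal-Wallis test of overall connectivity strength across groups
#'
#' Robustness check that group differences in topology are not driven by
#' overall connectivity: a rank-based omnibus comparison of per-subject mean
#' connectivity.
#'
#' @param data Data frame with the grouping column and a connectivity column.
#' @param value_col Column of per-subject mean connectivity
#'   (see [mean_connectivity()]). Default `"mean_connectivity"`.
#' @param group_col Grouping column name.
#' @return One-row tibble: `statistic`, `df`, `p.value`, `method`.
#' @export
overall_connectivity_test <- function(data, value_col = "mean_connectivity",
                                      group_col = "group") {
  g <- factor(data[[group_col]])
  if (nlevels(g) < 2) stop("at least 2 groups are required")
  if (any(table(g) < 2)) stop("every group needs at least 2 subjects")
  kt <- stats::kruskal.test(data[[value_col]], g)
  tibble::tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
                 p.value = kt$p.value, method = "Kruskal-Wallis rank sum test")
}

#' Plot the integrated-level scan results
#'
#' Minus-log10 FDR-adjusted difference-test p-values per node, faceted by
#' measure, with the significance threshold drawn as a dashed line.
#'
#' @param object An `"edsem_scan"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.edsem_scan <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  dat <- dplyr::filter(tibble::as_tibble(object), .data$density == "integrated")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$node, y = -log10(.data$p_diff_fdr))) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure)) +
    ggplot2::labs(x = "node", y = expression(-log[10]~"FDR-adjusted p (group difference)")) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Per-group standardized regression estimates for one scan cell
#'
#' Companion plot to the scan: group-specific completely standardized slopes of
#' the topology outcome on the latent factor, with approximate 95% confidence
#' intervals (delta-scaled from the unstandardized Wald intervals).
#'
#' @param scan An `"edsem_scan"`.
#' @param node,measure Cell to plot.
#' @param density Density level; default `"integrated"`.
#' @return A ggplot object.
#' @export
plot_group_effects <- function(scan, node, measure, density = "integrated") {
  row <- dplyr::filter(tibble::as_tibble(scan), .data$node == !!node,
                       .data$measure == !!measure, .data$density == !!density)
  if (nrow(row) != 1 || is.null(row$group_effects[[1]])) {
    stop("no fitted cell for that node/measure/density")
  }
  eff <- row$group_effects[[1]]
  eff$ci <- 1.96 * abs(eff$beta_std / eff$z)
  ggplot2::ggplot(eff, ggplot2::aes(x = .data$group, y = .data$beta_std)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta_std - .data$ci,
                                        ymax = .data$beta_std + .data$ci), width = 0.15) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "standardized regression on latent factor",
                  title = paste(node, measure, density, sep = " / "))
}
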