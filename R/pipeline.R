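# End-to-end orchestration: time series -> wavelet correlation -> TOM ->
# MST -> per-subject measures; and the two-group topological comparison.

#' Wavelet correlation matrix of one subject
#'
#' @param ts An `fc_timeseries` (timepoints x regions).
#' @param config An [fc_config()].
#' @return An `fc_wavelet_cor` at the configured analysis scale.
#' @export
subject_correlation <- function(ts, config = fc_config()) {
  coeffs <- modwt(ts, filter = config$wavelet_filter,
                  n_scales = config$n_scales)
  wavelet_correlation(coeffs, scale = config$analysis_scale)
}

#' TOM-weighted full graph and MST from a correlation matrix
#'
#' Applies the significance filter, the topological overlap transform, the
#' capped inverse-TOM weight map, and Prim's algorithm.
#'
#' @param m An `fc_wavelet_cor`.
#' @param config An [fc_config()].
#' @return List with `graph` (`fc_tom_graph`) and `tree` (`mst_tree`).
#' @export
tom_mst <- function(m, config = fc_config()) {
  filt <- significance_filter(m, sig_alpha = config$sig_alpha)
  tom <- compute_tom(filt)
  graph <- tom_weights(tom, cap = config$tom_cap)
  list(graph = graph, tree = prim_mst(graph))
}

#' The 12 per-subject analysis measures
#'
#' Runs the full single-subject pipeline and returns the three global
#' connectivity measures (strength, diversity, zero-correlation fraction),
#' the seven MST metrics, and the extreme-value-index fit (alpha and its
#' R-squared).
#'
#' @param ts An `fc_timeseries`.
#' @param config An [fc_config()].
#' @return One-row data.frame with columns `strength`, `diversity`,
#'   `zero_correlation` (fraction), `k_max`, `B_max`, `d`, `Ecc`, `Ass`,
#'   `K`, `Lf`, `alpha`, `r_squared`.
#' @export
subject_measures <- function(ts, config = fc_config()) {
  m <- subject_correlation(ts, config)
  gm <- global_measures(m, sig_alpha = config$sig_alpha)
  net <- tom_mst(m, config)
  met <- mst_metrics(net$tree)
  fit <- fit_extreme_value_index(net$graph)
  cbind(data.frame(strength = gm$strength, diversity = gm$diversity,
                   zero_correlation = gm$zero_fraction),
        met,
        data.frame(alpha = fit$alpha_hat, r_squared = fit$r_squared))
}

#' Measure table for a whole cohort
#'
#' @param cohort A `synthetic_cohort`, or a list with `manifest` and
#'   `series` in the same layout.
#' @param config An [fc_config()].
#' @return Measure table: one row per subject with `subject_id`, `group`,
#'   `age`, `sex` and the 12 measures.
#' @export
cohort_measures <- function(cohort, config = fc_config()) {
  man <- cohort$manifest
  rows <- lapply(man$subject_id, function(id)
    subject_measures(cohort$series[[id]], config))
  cbind(man[, c("subject_id", "group", "age", "sex")], do.call(rbind, rows))
}

#' Two-group topological comparison
#'
#' Averages the subject wavelet correlation matrices within each group,
#' builds the two group MSTs from TOM weights, and derives the comparison
#' outputs: superhighway sets, the betweenness gain/loss table with its
#' threshold `b`, geodesic cluster labels (same dendrogram cut in both
#' groups), hubs, and the survival ratio between the two trees.
#'
#' @param matrices_case,matrices_control Lists of `fc_wavelet_cor`, one per
#'   subject.
#' @param config An [fc_config()].
#' @return List of class `fc_group_topology` with elements `case` and
#'   `control` (each: `average`, `graph`, `tree`, `superhighways`,
#'   `clusters`, `hubs`), plus `betweenness` and `survival_ratio`.
#' @export
compare_groups <- function(matrices_case, matrices_control,
                           config = fc_config()) {
  one <- function(mats, label) {
    avg <- group_average(mats, group = label)
    net <- tom_mst(avg, config)
    list(average = avg, graph = net$graph, tree = net$tree,
         superhighways = extract_superhighways(net$graph, net$tree),
         clusters = geodesic_cluster(net$tree, cut_height = config$dendro_cut),
         hubs = hub_nodes(net$tree, threshold = config$hub_degree_threshold))
  }
  case <- one(matrices_case, "case")
  control <- one(matrices_control, "control")
  structure(list(case = case, control = control,
                 betweenness = betweenness_differences(case$tree, control$tree),
                 survival_ratio = survival_ratio(case$tree, control$tree)),
            class = "fc_group_topology")
}
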