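#' Analysis configuration
#'
#' Bundles the tunable parameters of the connectivity pipeline. Defaults
#' reproduce the reference analysis: length-8 Daubechies extremal-phase
#' MODWT filter, four wavelet scales with scale 2 analysed, a 0.05
#' significance level for the mutual-information test, the
#' `w = min(1/TOM, 100)/100` weight cap, a 0.2 dendrogram cut for geodesic
#' clustering, hubs defined as tree degree > 5, and 10000 permutations.
#'
#' @param tr_seconds Repetition time of the acquisition, in seconds.
#' @param wavelet_filter `"d8"` (Daubechies extremal phase, length 8) or
#'   `"la8"` (least asymmetric, length 8).
#' @param n_scales Number of MODWT detail scales.
#' @param analysis_scale Scale whose wavelet correlations feed the network
#'   stages (scale 2 corresponds to 0.05--0.1 Hz at TR = 2.5 s).
#' @param sig_alpha Significance level for the MI test used to zero
#'   non-significant correlations.
#' @param tom_cap Cap applied in the TOM-to-weight transform; must be > 1.
#' @param dendro_cut Dendrogram cut height for geodesic clustering.
#' @param hub_degree_threshold Tree degree above which a node is a hub.
#' @param n_permutations Number of label permutations for the group
#'   permutation test.
#' @param rng_seed Integer seed recorded with the configuration.
#' @return An object of class `fc_config` (a validated list).
#' @export
fc_config <- function(tr_seconds = 2.5,
                      wavelet_filter = c("d8", "la8"),
                      n_scales = 4L,
                      analysis_scale = 2L,
                      sig_alpha = 0.05,
                      tom_cap = 100,
                      dendro_cut = 0.2,
                      hub_degree_threshold = 5L,
                      n_permutations = 10000L,
                      rng_seed = 1L) {
  wavelet_filter <- match.arg(wavelet_filter)
  stopifnot(tr_seconds > 0, n_scales >= 1,
            analysis_scale >= 1, analysis_scale <= n_scales,
            sig_alpha > 0, sig_alpha < 1, tom_cap > 1,
            dendro_cut > 0, n_permutations >= 1)
  structure(list(tr_seconds = tr_seconds,
                 wavelet_filter = wavelet_filter,
                 n_scales = as.integer(n_scales),
                 analysis_scale = as.integer(analysis_scale),
                 sig_alpha = sig_alpha,
                 tom_cap = tom_cap,
                 dendro_cut = dendro_cut,
                 hub_degree_threshold = as.integer(hub_degree_threshold),
                 n_permutations = as.integer(n_permutations),
                 rng_seed = as.integer(rng_seed)),
            class = "fc_config")
}

#' @export
print.fc_config <- function(x, ...) {
  cat("<fc_config>\n")
  for (nm in names(x)) cat(sprintf("  %-21s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
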