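#' AAL-116 atlas table
#'
#' Returns the packaged 116-region atlas: region index (1..116), region name,
#' macro-region (one of the 8 lobes: Frontal, Insular, Limbic, Occipital,
#' Parietal, SCGM, Temporal, Cerebellum), hemisphere (`L`, `R`, `midline`
#' for vermis structures), and schematic 2-D plot coordinates. The
#' coordinates are a generated axial-style layout for plotting, not
#' stereotaxic centroids.
#'
#' @return A data.frame with 116 rows and columns `region_index`,
#'   `region_name`, `macro_region`, `hemisphere`, `x`, `y`.
#' @export
aal116_atlas <- function() {
  path <- system.file("extdata", "aal116_atlas.csv", package = "mstconnect",
                      mustWork = TRUE)
  atlas <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_atlas(atlas)
  atlas
}

#' Validate an atlas table
#'
#' Checks the invariants required of any atlas table: contiguous unique
#' 1-based region indices and a single macro-region per region.
#'
#' @param atlas A data.frame with at least `region_index`, `region_name`,
#'   `macro_region`, `hemisphere`.
#' @return The atlas, invisibly; errors on violation.
#' @export
validate_atlas <- function(atlas) {
  need <- c("region_index", "region_name", "macro_region", "hemisphere")
  miss <- setdiff(need, names(atlas))
  if (length(miss))
    stop("atlas is missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(atlas)
  if (!identical(as.integer(atlas$region_index), seq_len(n)))
    stop("atlas region_index must be contiguous 1..", n)
  if (anyDuplicated(atlas$region_name))
    stop("atlas region names must be unique")
  if (anyNA(atlas$macro_region))
    stop("every region must map to exactly one macro_region")
  invisible(atlas)
}
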