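#' Read a regional time-series table
#'
#' Reads a delimited numeric table of BOLD time series, timepoints in rows
#' and regions in columns. The delimiter is auto-detected among comma, tab
#' and whitespace; an optional header row of region names is recognised by
#' its non-numeric cells. Malformed input (ragged rows, non-numeric or
#' missing cells) raises an error naming the offending row and column.
#'
#' @param path Path to the file.
#' @param tr_seconds Repetition time in seconds, attached to the result.
#' @param n_regions_expected Optional region count (e.g. from an atlas);
#'   a mismatch is an error.
#' @return A numeric matrix of class `fc_timeseries` (timepoints x regions)
#'   with attribute `tr_seconds`; column names come from the header when
#'   present.
#' @export
read_timeseries <- function(path, tr_seconds = 2.5,
                            n_regions_expected = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty time-series file: ", path)
  sep <- detect_delimiter(lines[[1]])
  toks <- lapply(lines, function(l) {
    l <- trimws(l)
    if (is.null(sep)) strsplit(l, "[ \t]+")[[1]] else strsplit(l, sep, fixed = TRUE)[[1]]
  })
  toks <- lapply(toks, trimws)
  widths <- lengths(toks)
  if (length(unique(widths)) > 1L) {
    bad <- which(widths != widths[[1]])[1]
    stop(sprintf("ragged table in %s: row %d has %d fields, expected %d",
                 path, bad, widths[bad], widths[1]))
  }
  header <- NULL
  first <- suppressWarnings(as.numeric(toks[[1]]))
  if (anyNA(first)) {
    header <- toks[[1]]
    toks <- toks[-1]
    if (!length(toks)) stop("time-series file has a header but no data: ", path)
  }
  vals <- suppressWarnings(vapply(toks, as.numeric, numeric(widths[[1]])))
  mat <- t(matrix(vals, nrow = widths[[1]]))
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing value in %s at data row %d, column %d",
                 path, bad[["row"]], bad[["col"]]))
  }
  if (!is.null(n_regions_expected) && ncol(mat) != n_regions_expected)
    stop(sprintf("%s has %d regions but %d were expected",
                 path, ncol(mat), n_regions_expected))
  colnames(mat) <- header
  as_fc_timeseries(mat, tr_seconds)
}

#' @keywords internal
detect_delimiter <- function(line) {
  if (grepl(",", line, fixed = TRUE)) return(",")
  if (grepl("\t", line, fixed = TRUE)) return("\t")
  NULL # generic whitespace
}

#' Construct a time-series matrix object
#'
#' @param values Numeric matrix, timepoints x regions, no missing values.
#' @param tr_seconds Repetition time in seconds.
#' @return A matrix of class `fc_timeseries` with a `tr_seconds` attribute.
#' @export
as_fc_timeseries <- function(values, tr_seconds = 2.5) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("time series must not contain missing values")
  storage.mode(values) <- "double"
  attr(values, "tr_seconds") <- tr_seconds
  class(values) <- c("fc_timeseries", class(values))
  values
}

#' Read a cohort manifest
#'
#' Reads a CSV manifest with columns `subject_id`, `group` (`control` or
#' `case`), `age`, `sex` (`M`/`F`) and `timeseries_path`, validates its
#' invariants and returns it as a data.frame.
#'
#' @param path Path to the manifest CSV. Relative `timeseries_path` entries
#'   are resolved against the manifest's directory.
#' @return The validated manifest data.frame.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  rel <- !file.exists(man$timeseries_path)
  man$timeseries_path[rel] <- file.path(dirname(path), man$timeseries_path[rel])
  validate_manifest(man)
}

#' Validate a cohort manifest
#'
#' @param man Manifest data.frame.
#' @param require_two_groups If `TRUE`, both groups must be present.
#' @return The manifest, invisibly-checked and returned.
#' @export
validate_manifest <- function(man, require_two_groups = FALSE) {
  need <- c("subject_id", "group", "age", "sex")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(man$subject_id)) stop("subject_id must be unique")
  if (!all(man$group %in% c("control", "case")))
    stop("group must be 'control' or 'case'")
  if (any(man$age <= 0)) stop("ages must be positive")
  if (!all(man$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  if (require_two_groups && length(unique(man$group)) < 2L)
    stop("both groups must be represented")
  man
}

#' Write a minimum spanning tree to GraphML
#'
#' Serialises a tree with per-node attributes (region name, macro-region,
#' cluster, degree, raw betweenness, hub flag) and per-edge attributes
#' (weight, superhighway flag) to GraphML. The file round-trips losslessly
#' through [read_tree()].
#'
#' @param tree An `mst_tree` object.
#' @param atlas Atlas table whose `region_index` covers the tree nodes.
#' @param path Output file path.
#' @param cluster Optional integer cluster label per node.
#' @param superhighway Optional logical flag per tree edge (in the order of
#'   `tree$edges`).
#' @param hub_degree_threshold Degree above which a node is flagged as hub.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, atlas, path, cluster = NULL,
                       superhighway = NULL, hub_degree_threshold = 5L) {
  validate_atlas(atlas)
  n <- tree$n
  if (n > nrow(atlas)) stop("tree has node ids not present in the atlas")
  g <- igraph::graph_from_data_frame(
    tree$edges[, c("i", "j", "weight")],
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(n))))
  igraph::V(g)$region_name <- atlas$region_name[seq_len(n)]
  igraph::V(g)$macro_region <- atlas$macro_region[seq_len(n)]
  igraph::V(g)$cluster <- as.integer(if (is.null(cluster)) rep(0L, n) else cluster)
  igraph::V(g)$degree <- as.integer(tree$degree)
  igraph::V(g)$betweenness <- tree$betweenness_raw
  igraph::V(g)$hub <- tree$degree > hub_degree_threshold
  shw <- if (is.null(superhighway)) rep(FALSE, nrow(tree$edges)) else superhighway
  igraph::E(g)$superhighway <- as.logical(shw)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML tree written by [write_tree()]
#'
#' @param path GraphML file path.
#' @return A list with the reconstructed `tree` (`mst_tree`), the node
#'   attribute data.frame `nodes`, and the edge table `edges` including the
#'   `superhighway` flag.
#' @export
read_tree <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  i <- as.integer(el$from); j <- as.integer(el$to)
  edges <- data.frame(i = pmin(i, j), j = pmax(i, j),
                      weight = el$weight,
                      superhighway = as.logical(el$superhighway))
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- igraph::as_data_frame(g, what = "vertices")
  nodes <- nodes[order(as.integer(nodes$name)), , drop = FALSE]
  rownames(nodes) <- NULL
  tree <- mst_tree(edges[, c("i", "j", "weight")], n = igraph::vcount(g))
  list(tree = tree, nodes = nodes, edges = edges)
}

#' Write a symmetric matrix as CSV
#'
#' @param m Matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
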