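# Two-group topological comparison on group-average matrices.

#' Element-wise average of wavelet correlation matrices
#'
#' @param matrices List of `fc_wavelet_cor` objects (or plain matrices) of
#'   identical dimension.
#' @param group Optional group label attached to the result.
#' @return An `fc_wavelet_cor` whose `r` is the element-wise mean; `n_obs`
#'   is taken from the first matrix (all inputs share the acquisition
#'   length) and `n_subjects`/`group` are recorded.
#' @export
group_average <- function(matrices, group = NULL) {
  stopifnot(length(matrices) >= 1)
  get_r <- function(m) if (inherits(m, "fc_wavelet_cor")) m$r else as.matrix(m)
  r1 <- get_r(matrices[[1]])
  acc <- matrix(0, nrow(r1), ncol(r1))
  for (m in matrices) {
    r <- get_r(m)
    if (!all(dim(r) == dim(r1))) stop("matrices must have identical dimensions")
    acc <- acc + r
  }
  n_obs <- if (inherits(matrices[[1]], "fc_wavelet_cor")) matrices[[1]]$n_obs else nrow(r1)
  scale <- if (inherits(matrices[[1]], "fc_wavelet_cor")) matrices[[1]]$scale else NA_integer_
  out <- structure(list(r = acc / length(matrices), scale = scale, n_obs = n_obs),
                   class = "fc_wavelet_cor")
  out$n_subjects <- length(matrices)
  out$group <- group
  out
}

#' Superhighway extraction by weight-ordered percolation
#'
#' Identifies the information-flow backbone of a group MST. Edges of the
#' TOM-weighted full graph are deleted in descending weight order (the
#' weakest neighbourhood connections first, since small weight means strong
#' overlap), recomputing the degree divergence `K = <k^2>/<k>` over nodes
#' of non-zero degree after each deletion. At the first step where `K < 2`
#' (the Molloy-Reed percolation criterion) the largest remaining connected
#' component is taken; the superhighway set is, by default, the MST edges
#' with both endpoints inside that component.
#'
#' @param g An `fc_tom_graph` (the group full graph).
#' @param tree The group MST from the same matrix.
#' @param mode `"mst"` returns MST edges induced by the percolation
#'   component (superhighways as tree paths); `"component"` returns the raw
#'   surviving component edges.
#' @return List with `edges` (data.frame `i`, `j`, `weight`),
#'   `component_nodes`, `K_stop` (first K below 2), `n_removed`, and
#'   `shw_flag`, a logical per `tree$edges` row.
#' @export
extract_superhighways <- function(g, tree, mode = c("mst", "component")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "mst_tree"))
  w <- if (inherits(g, "fc_tom_graph")) g$w else as.matrix(g)
  n <- nrow(w)
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  ew <- w[ut]
  # descending weight; ties resolved lexicographically for reproducibility
  ord <- order(-ew, ut[, 1], ut[, 2])
  ei <- ut[ord, 1]; ej <- ut[ord, 2]; ew <- ew[ord]
  deg <- tabulate(c(ei, ej), nbins = n)
  sum_k <- sum(deg)
  sum_k2 <- sum(deg^2)
  K <- sum_k2 / sum_k
  if (K < 2) {
    warning("degree divergence already below 2 on the full graph; empty superhighway set")
    return(list(edges = tree$edges[0, ], component_nodes = integer(0),
                K_stop = K, n_removed = 0L,
                shw_flag = rep(FALSE, nrow(tree$edges))))
  }
  stop_at <- NA_integer_
  for (m in seq_along(ew)) {
    for (v in c(ei[m], ej[m])) {
      k <- deg[v]
      sum_k2 <- sum_k2 - 2 * k + 1
      sum_k <- sum_k - 1
      deg[v] <- k - 1L
    }
    if (sum_k == 0) { K <- 0; stop_at <- m; break }
    K <- sum_k2 / sum_k
    if (K < 2) { stop_at <- m; break }
  }
  keep <- seq_along(ew) > stop_at
  gr <- igraph::graph_from_edgelist(cbind(ei[keep], ej[keep]), directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0, n - igraph::vcount(gr)))
  comp <- igraph::components(gr)
  # largest component; ties to the one containing the smallest node id
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    first_node <- vapply(best, function(b) min(which(comp$membership == b)), numeric(1))
    best <- best[which.min(first_node)]
  }
  nodes <- which(comp$membership == best)
  flag <- tree$edges$i %in% nodes & tree$edges$j %in% nodes
  edges <- if (mode == "mst") {
    tree$edges[flag, , drop = FALSE]
  } else {
    data.frame(i = ei[keep], j = ej[keep], weight = ew[keep])[
      ei[keep] %in% nodes & ej[keep] %in% nodes, , drop = FALSE]
  }
  rownames(edges) <- NULL
  list(edges = edges, component_nodes = nodes, K_stop = K,
       n_removed = stop_at, shw_flag = flag)
}

#' Node betweenness gain/loss between two trees
#'
#' Compares raw (pair-count) node betweenness between the case and control
#' group MSTs. The threshold `b` is the non-zero median of the absolute
#' differences; nodes with `diff > b` are betweenness gains in the case
#' group, nodes with `diff < -b` losses, the rest neutral.
#'
#' @param t_case,t_control `mst_tree` objects on the same node set.
#' @return List with `table` (data.frame `node`, `b_case`, `b_control`,
#'   `diff`, `label`) and threshold `b` (`NA` when all differences vanish).
#' @export
betweenness_differences <- function(t_case, t_control) {
  stopifnot(inherits(t_case, "mst_tree"), inherits(t_control, "mst_tree"))
  if (t_case$n != t_control$n) stop("trees must share the same node set")
  diff <- t_case$betweenness_raw - t_control$betweenness_raw
  nz <- abs(diff)[diff != 0]
  b <- if (length(nz)) stats::median(nz) else NA_real_
  label <- rep("neutral", t_case$n)
  if (!is.na(b)) {
    label[diff > b] <- "gain"
    label[diff < -b] <- "loss"
  }
  list(table = data.frame(node = seq_len(t_case$n),
                          b_case = t_case$betweenness_raw,
                          b_control = t_control$betweenness_raw,
                          diff = diff, label = label),
       b = b)
}

#' Geodesic clustering of tree nodes
#'
#' Clusters MST nodes by the similarity of their hop-distance profiles: the
#' geodesic distance matrix `D` holds path lengths in edges; rows are
#' compared with the Spearman distance `d_S = 1 - r_S` (rank correlation
#' computed on off-diagonal entries with the self and mutual positions
#' removed symmetrically, midranks for ties); average-linkage hierarchical
#' clustering of `d_S` is cut at `cut_height` (default 0.2) -- or into `k`
#' clusters when `k` is given -- to produce flat labels.
#'
#' If a row pair has both profiles constant, `r_S` is taken as 1 (identical
#' shapes); if exactly one is constant, as 0.
#'
#' @param t An `mst_tree` with at least 3 nodes.
#' @param cut_height Dendrogram cut height.
#' @param k Optional fixed number of clusters (overrides `cut_height`).
#' @return List with `D`, `d_s`, `hclust`, `labels`, `n_clusters`,
#'   `cut_height`.
#' @export
geodesic_cluster <- function(t, cut_height = 0.2, k = NULL) {
  stopifnot(inherits(t, "mst_tree"))
  n <- t$n
  if (n < 3) stop("clustering needs at least 3 nodes")
  D <- t$D
  dS <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      x <- D[i, -c(i, j)]
      y <- D[j, -c(i, j)]
      cx <- stats::sd(x) == 0
      cy <- stats::sd(y) == 0
      rs <- if (cx && cy) 1 else if (cx || cy) 0 else
        stats::cor(x, y, method = "spearman")
      dS[i, j] <- dS[j, i] <- 1 - rs
    }
  }
  hc <- stats::hclust(stats::as.dist(dS), method = "average")
  labels <- if (is.null(k)) stats::cutree(hc, h = cut_height)
            else stats::cutree(hc, k = k)
  list(D = D, d_s = dS, hclust = hc, labels = unname(labels),
       n_clusters = length(unique(labels)), cut_height = cut_height)
}

#' Hub nodes of a tree
#'
#' Nodes whose degree centrality exceeds the threshold (default 5).
#'
#' @param t An `mst_tree`.
#' @param threshold Degree threshold; hubs have degree strictly above it.
#' @return Integer vector of node indices.
#' @export
hub_nodes <- function(t, threshold = 5L) {
  stopifnot(inherits(t, "mst_tree"))
  which(t$degree > threshold)
}
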