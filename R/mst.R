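# Minimum spanning tree extraction and global tree metrics.

#' Prim minimum spanning tree
#'
#' Extracts the minimum spanning tree of a weighted full graph with Prim's
#' algorithm. Ties are broken deterministically: among equal-weight
#' candidate edges the smallest node index is attached first, and an
#' equal-weight parent update keeps the smaller parent index, so the same
#' weight matrix always yields the same tree.
#'
#' @param g An `fc_tom_graph`, or a symmetric weight matrix with positive
#'   off-diagonal weights (zeros off the diagonal are treated as absent
#'   edges).
#' @return An [mst_tree()] object.
#' @export
prim_mst <- function(g) {
  w <- if (inherits(g, "fc_tom_graph")) g$w else as.matrix(g)
  n <- nrow(w)
  if (n < 2) stop("need at least 2 nodes")
  w[w == 0] <- Inf
  diag(w) <- Inf
  in_tree <- logical(n)
  in_tree[1] <- TRUE
  best_w <- w[, 1]
  best_parent <- rep(1L, n)
  ei <- integer(n - 1); ej <- integer(n - 1); ew <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best_w[cand])] # which.min takes first == smallest index
    if (!is.finite(best_w[v])) {
      comp <- igraph::components(igraph::graph_from_adjacency_matrix(
        is.finite(w), mode = "undirected", diag = FALSE))$membership
      stop("graph is disconnected; components: ",
           paste(tapply(seq_len(n), comp, paste, collapse = ","), collapse = " | "))
    }
    in_tree[v] <- TRUE
    ei[step] <- min(best_parent[v], v)
    ej[step] <- max(best_parent[v], v)
    ew[step] <- best_w[v]
    upd <- !in_tree & w[, v] < best_w
    best_w[upd] <- w[upd, v]
    best_parent[upd] <- v
    # equal-weight alternative parent: keep the lexicographically smaller edge
    tie <- which(!in_tree & w[, v] == best_w & best_parent != v)
    for (u in tie) {
      old <- c(min(u, best_parent[u]), max(u, best_parent[u]))
      new <- c(min(u, v), max(u, v))
      if (new[1] < old[1] || (new[1] == old[1] && new[2] < old[2]))
        best_parent[u] <- v
    }
  }
  edges <- data.frame(i = ei, j = ej, weight = ew)
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  mst_tree(edges, n)
}

#' Construct a tree object with per-node centralities
#'
#' Validates that the edge list is a spanning tree (N-1 edges, connected,
#' hence acyclic) and computes node degrees, raw and normalised betweenness,
#' hop-distance matrix, eccentricities and leaf flags.
#'
#' Raw betweenness of node `v` counts the node pairs whose unique tree path
#' passes through `v`: with component sizes `s_c` of the forest left by
#' deleting `v`, it equals `C(n-1, 2) - sum_c C(s_c, 2)`. Normalised
#' betweenness divides by `(n-1)(n-2)/2`.
#'
#' @param edges data.frame with columns `i`, `j` (1-based node ids) and
#'   `weight`.
#' @param n Number of nodes.
#' @return Object of class `mst_tree`: list with `n`, `edges`, `degree`,
#'   `betweenness_raw`, `betweenness`, `D` (hop distances), `eccentricity`,
#'   `is_leaf`, `total_weight`.
#' @export
mst_tree <- function(edges, n) {
  edges <- as.data.frame(edges)
  if (nrow(edges) != n - 1)
    stop("a spanning tree on ", n, " nodes must have ", n - 1, " edges")
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    i <- edges$i[e]; j <- edges$j[e]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  D <- tree_hop_distances(adj, n)
  if (any(is.infinite(D))) stop("edge list is not connected: not a spanning tree")
  deg <- lengths(adj)
  b_raw <- tree_betweenness_raw(adj, n)
  ecc <- apply(D, 1, max)
  structure(list(n = n,
                 edges = edges,
                 degree = as.integer(deg),
                 betweenness_raw = b_raw,
                 betweenness = if (n > 2) b_raw / ((n - 1) * (n - 2) / 2) else b_raw,
                 D = D,
                 eccentricity = ecc,
                 is_leaf = deg == 1L,
                 total_weight = sum(edges$weight)),
            class = "mst_tree")
}

# BFS hop distances from every node over an adjacency list
#' @keywords internal
tree_hop_distances <- function(adj, n) {
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[dist[nxt] == Inf]
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

# Raw pair-count betweenness on a tree via the deleted-node component sizes
#' @keywords internal
tree_betweenness_raw <- function(adj, n) {
  total_pairs <- choose(n - 1, 2)
  vapply(seq_len(n), function(v) {
    seen <- logical(n)
    seen[v] <- TRUE
    acc <- 0
    for (start in adj[[v]]) {
      if (seen[start]) next
      size <- 0
      frontier <- start
      seen[start] <- TRUE
      while (length(frontier)) {
        size <- size + length(frontier)
        nxt <- unlist(adj[frontier], use.names = FALSE)
        nxt <- unique(nxt[!seen[nxt]])
        seen[nxt] <- TRUE
        frontier <- nxt
      }
      acc <- acc + choose(size, 2)
    }
    total_pairs - acc
  }, numeric(1))
}

#' Global tree metrics
#'
#' The seven global measures characterising an MST between its line and
#' star extremes:
#' * `k_max`: maximum node degree;
#' * `B_max`: maximum betweenness, normalised to `[0, 1]` by
#'   `(N-1)(N-2)/2`;
#' * `d`: diameter (longest hop distance), between 2 and N-1;
#' * `Ecc`: mean node eccentricity;
#' * `Ass`: assortativity, the Pearson correlation of endpoint degrees over
#'   edges (both orientations); negative in hub-leaf hierarchies;
#' * `K`: degree divergence `<k^2>/<k>`, the Molloy-Reed ratio whose
#'   critical value 2 drives the superhighway stopping rule;
#' * `Lf`: leaf fraction, leaves / (N-1); 1 for a star, 2/(N-1) for a path.
#'
#' @param t An `mst_tree`.
#' @return One-row data.frame with columns `k_max`, `B_max`, `d`, `Ecc`,
#'   `Ass`, `K`, `Lf`.
#' @export
mst_metrics <- function(t) {
  stopifnot(inherits(t, "mst_tree"))
  n <- t$n
  if (n < 3) stop("tree metrics are undefined for fewer than 3 nodes")
  deg <- t$degree
  x <- c(deg[t$edges$i], deg[t$edges$j])
  y <- c(deg[t$edges$j], deg[t$edges$i])
  ass <- if (stats::sd(x) == 0) NA_real_ else stats::cor(x, y)
  data.frame(k_max = max(deg),
             B_max = max(t$betweenness),
             d = max(t$D),
             Ecc = mean(t$eccentricity),
             Ass = ass,
             K = mean(deg^2) / mean(deg),
             Lf = sum(t$is_leaf) / (n - 1))
}

#' Extreme value index of the weight distribution
#'
#' Diagnoses the strong-disorder regime of the TOM-weighted full graph: the
#' near-zero weight distribution is modelled as `F(x) = Pr(X <= x) ~ c x^alpha`
#' and `alpha` is estimated as the slope of the ordinary least-squares fit
#' of `log10 F(x)` on `log10 x` over the empirical CDF of the
#' upper-triangle weights. Weights saturated at the cap (`w = 1`) are
#' excluded, as are duplicated abscissae. `alpha < 1` flags the
#' strong-disorder regime, in which the MST carries essentially all
#' shortest paths of the full graph; `alpha = 1` corresponds to uniform
#' weights.
#'
#' @param g An `fc_tom_graph`, or a numeric vector of weights in `(0, 1]`.
#' @return List with `alpha_hat`, `intercept` (log10 c), `r_squared`,
#'   `n_points`, `strong_disorder`.
#' @export
fit_extreme_value_index <- function(g) {
  x <- if (inherits(g, "fc_tom_graph")) g$w[upper.tri(g$w)] else as.numeric(g)
  x <- x[x > 0 & x < 1] # drop cap-saturated weights
  xs <- sort(unique(x))
  if (length(xs) < 10)
    stop("degenerate fit: fewer than 10 distinct non-saturated weights")
  Fx <- stats::ecdf(x)(xs)
  keep <- Fx > 0
  fit <- stats::lm(log10(Fx[keep]) ~ log10(xs[keep]))
  alpha <- unname(stats::coef(fit)[2])
  list(alpha_hat = alpha,
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n_points = sum(keep),
       strong_disorder = alpha < 1)
}

#' Fraction of edges shared by two trees
#'
#' The survival ratio: `|E(t1) intersect E(t2)| / (N - 1)`, edges taken as
#' unordered pairs. 1 for identical trees, 0 for edge-disjoint ones.
#'
#' @param t1,t2 `mst_tree` objects on the same node set.
#' @return Fraction in `[0, 1]`.
#' @export
survival_ratio <- function(t1, t2) {
  stopifnot(inherits(t1, "mst_tree"), inherits(t2, "mst_tree"))
  if (t1$n != t2$n) stop("trees must share the same node set")
  key <- function(t) paste(pmin(t$edges$i, t$edges$j),
                           pmax(t$edges$i, t$edges$j), sep = "-")
  length(intersect(key(t1), key(t2))) / (t1$n - 1)
}
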