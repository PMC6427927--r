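# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force loops, Prufer-sequence tree
# enumeration, BFS path walking.

# Decode a Prufer sequence into the edge list of a labelled tree on n nodes.
decode_prufer <- function(seq, n) {
  degree <- rep(1L, n)
  for (v in seq) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1, 2)
  ptr <- 1L
  for (e in seq_along(seq)) {
    leaf <- which(degree == 1L)[1]
    edges[e, ] <- c(min(leaf, seq[e]), max(leaf, seq[e]))
    degree[leaf] <- 0L
    degree[seq[e]] <- degree[seq[e]] - 1L
  }
  last <- which(degree == 1L)
  edges[n - 1, ] <- c(min(last), max(last))
  edges
}

# All spanning trees of K_n as an (n^(n-2)) x (n-1) matrix of edge ids
# into the upper-triangle edge ordering of an n x n weight matrix.
all_tree_edge_ids <- function(n) {
  if (n == 2) return(matrix(1L, 1, 1))
  pair_id <- matrix(0L, n, n)
  pair_id[upper.tri(pair_id)] <- seq_len(choose(n, 2))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  t(apply(seqs, 1, function(s) {
    ed <- decode_prufer(as.integer(s), n)
    pair_id[cbind(ed[, 1], ed[, 2])]
  }))
}

# Exhaustive minimum spanning tree weight of a complete graph.
exhaustive_mst_weight <- function(w) {
  n <- nrow(w)
  ids <- all_tree_edge_ids(n)
  wv <- w[upper.tri(w)]
  min(rowSums(matrix(wv[ids], nrow = nrow(ids))))
}

# Random labelled tree edge list via a random Prufer sequence.
random_tree_edges <- function(n) {
  if (n == 2) return(data.frame(i = 1L, j = 2L, weight = 1))
  ed <- decode_prufer(sample.int(n, n - 2, replace = TRUE), n)
  data.frame(i = ed[, 1], j = ed[, 2], weight = 1)
}

# BFS path between two nodes of a tree given as an edge data.frame.
bfs_path <- function(edges, n, s, t) {
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    i <- edges$i[e]; j <- edges$j[e]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  parent <- rep(NA_integer_, n)
  parent[s] <- s
  frontier <- s
  while (is.na(parent[t]) && length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) for (u in adj[[v]]) if (is.na(parent[u])) {
      parent[u] <- v; nxt <- c(nxt, u)
    }
    frontier <- nxt
  }
  path <- t
  while (path[1] != s) path <- c(parent[path[1]], path)
  path
}

# Triple-loop topological overlap, straight from the definition.
brute_tom <- function(A) {
  n <- nrow(A)
  diag(A) <- 0
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[j, u]
    ki <- sum(A[i, -i]); kj <- sum(A[j, -j])
    out[i, j] <- (l + A[i, j]) / (min(ki, kj) + 1 - A[i, j])
  }
  out
}

# Random symmetric matrix with entries in [0, 1] and zero diagonal.
random_adjacency <- function(n) {
  A <- matrix(runif(n * n), n)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

# Star and path trees as mst_tree objects.
star_tree <- function(n) mst_tree(data.frame(i = 1L, j = 2:n, weight = 1), n)
path_tree <- function(n) mst_tree(data.frame(i = 1:(n - 1), j = 2:n, weight = 1), n)

# A small synthetic correlation object for unit tests.
fake_wavelet_cor <- function(r, n_obs = 193L, scale = 2L) {
  structure(list(r = r, scale = scale, n_obs = n_obs),
            class = "fc_wavelet_cor")
}

# Default small cohort spec used by pipeline-level tests.
small_spec <- function(seed, n_per_group = 10, n_regions = 40,
                       case_attenuation = 0.5) {
  synthetic_spec(n_control = n_per_group, n_case = n_per_group,
                 n_regions = n_regions, n_timepoints = 193,
                 block_sizes = rep(n_regions / 4, 4),
                 hub_regions = c(5, 25),
                 case_attenuation = case_attenuation, seed = seed)
}
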