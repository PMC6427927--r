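#' Zero out non-significant wavelet correlations
#'
#' Builds the full graph used by the TOM/MST stage: entries whose MI-test
#' p-value is at least `sig_alpha` are set to zero, significant entries are
#' kept as-is. The diagonal is set to zero (self-correlation is not an
#' edge).
#'
#' @param m An `fc_wavelet_cor` object.
#' @param sig_alpha Significance level.
#' @return Object of class `fc_sigfiltered`: list with matrix `r0`,
#'   `n_zeroed` (upper-triangle entries zeroed), `sig_alpha`, `n_obs`.
#' @export
significance_filter <- function(m, sig_alpha = 0.05) {
  stopifnot(inherits(m, "fc_wavelet_cor"))
  r0 <- m$r
  p <- mi_pvalue(r0, m$n_obs)
  drop <- p >= sig_alpha
  n_zeroed <- sum(drop[upper.tri(drop)])
  r0[drop] <- 0
  diag(r0) <- 0
  structure(list(r0 = r0, n_zeroed = n_zeroed, sig_alpha = sig_alpha,
                 n_obs = m$n_obs),
            class = "fc_sigfiltered")
}

#' Topological overlap matrix
#'
#' Computes `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `a_ij` is the network adjacency, `l_ij = sum_u a_iu a_ju` (u != i, j) is
#' the shared-neighbour overlap and `k_i = sum_u a_iu` the node
#' connectivity. With adjacencies in `[0, 1]` the TOM is bounded in
#' `[0, 1]`; high values mark node pairs embedded in the same
#' neighbourhood. By default the adjacency is the absolute value of the
#' significance-filtered correlation, which keeps the bounds valid in the
#' presence of negative correlations; `signed = TRUE` uses the raw values
#' instead.
#'
#' @param f An `fc_sigfiltered` object, or a plain symmetric adjacency
#'   matrix with entries in `[0, 1]` (diagonal ignored).
#' @param signed Use signed correlations as adjacency (bounds no longer
#'   guaranteed); default `FALSE`.
#' @return Object of class `fc_tom`: list with matrices `tom` (unit
#'   diagonal), `a`, `l`, and connectivity vector `k`.
#' @export
compute_tom <- function(f, signed = FALSE) {
  A <- if (inherits(f, "fc_sigfiltered")) f$r0 else as.matrix(f)
  if (!isTRUE(all.equal(A, t(A), tolerance = 1e-10)))
    stop("adjacency must be symmetric")
  if (!signed) A <- abs(A)
  diag(A) <- 0
  k <- rowSums(A)
  L <- A %*% A # diag(A)=0 makes this the u != i, j overlap sum
  kmin <- outer(k, k, pmin)
  tom <- (L + A) / (kmin + 1 - A)
  diag(tom) <- 1
  structure(list(tom = tom, a = A, l = L, k = k), class = "fc_tom")
}

#' TOM-based edge weights for the full graph
#'
#' Transforms topological overlap into edge weights
#' `w_ij = min(1/TOM_ij, cap)/cap`, mapping weights into `(0, 1]`: large
#' overlaps become small weights (strong connections), and overlaps at or
#' below `1/cap` (including `TOM = 0`) saturate at `w = 1`.
#'
#' @param t An `fc_tom` object (or a plain TOM-like matrix).
#' @param cap Saturation cap (default 100).
#' @return Object of class `fc_tom_graph`: list with weight matrix `w`
#'   (zero diagonal), `cap`, and the source `tom` matrix.
#' @export
tom_weights <- function(t, cap = 100) {
  stopifnot(cap > 1)
  tom <- if (inherits(t, "fc_tom")) t$tom else as.matrix(t)
  w <- pmin(1 / tom, cap) / cap
  diag(w) <- 0
  structure(list(w = w, cap = cap, tom = tom), class = "fc_tom_graph")
}
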