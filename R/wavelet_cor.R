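#' Wavelet correlation matrix at one scale
#'
#' Pearson correlation between the scale-`s` MODWT detail coefficients of
#' every pair of regions: `r_ij = cov(lambda_i(s), lambda_j(s)) /
#' sqrt(var(lambda_i(s)) var(lambda_j(s)))`. Coefficients affected by the
#' circular boundary are retained by default so that the effective sample
#' size equals the series length; set `drop_boundary = TRUE` to discard
#' them.
#'
#' @param coeffs An `fc_modwt` object.
#' @param scale Detail scale to use.
#' @param drop_boundary Drop wrap-around-affected coefficients before
#'   correlating.
#' @return Object of class `fc_wavelet_cor`: list with the symmetric
#'   unit-diagonal matrix `r`, `scale` and `n_obs` (rows used).
#' @export
wavelet_correlation <- function(coeffs, scale = 2L, drop_boundary = FALSE) {
  stopifnot(inherits(coeffs, "fc_modwt"))
  if (scale < 1 || scale > coeffs$n_scales)
    stop("scale ", scale, " not available (1..", coeffs$n_scales, ")")
  W <- coeffs$W[[scale]]
  if (drop_boundary) {
    nb <- coeffs$n_boundary[[scale]]
    if (nb >= nrow(W) - 2) stop("too few non-boundary coefficients at scale ", scale)
    W <- W[(nb + 1):nrow(W), , drop = FALSE]
  }
  sds <- apply(W, 2, stats::sd)
  degenerate <- sds == 0
  r <- matrix(0, ncol(W), ncol(W))
  ok <- !degenerate
  if (any(ok)) r[ok, ok] <- stats::cor(W[, ok, drop = FALSE])
  if (any(degenerate)) {
    warning("zero-variance region(s) at scale ", scale, ": ",
            paste(which(degenerate), collapse = ", "),
            "; their correlations set to 0")
  }
  diag(r) <- 1
  dimnames(r) <- list(colnames(W), colnames(W))
  structure(list(r = r, scale = as.integer(scale), n_obs = nrow(W)),
            class = "fc_wavelet_cor")
}

#' Mutual-information test p-value for a correlation
#'
#' Tests `H0: rho = 0` with the statistic `MI = -n ln(1 - r^2)/2`. Under
#' the null, `2 MI = -n ln(1 - r^2)` is asymptotically chi-square with one
#' degree of freedom (it is the likelihood-ratio statistic for a bivariate
#' Gaussian), giving a two-sided p-value. Vectorised over `r`.
#'
#' @param r Correlation(s), `|r| <= 1`. `|r| = 1` yields p = 0.
#' @param n_obs Effective sample size (the reference analysis uses the
#'   coefficient series length).
#' @return Numeric p-value(s) in `[0, 1]`.
#' @export
mi_pvalue <- function(r, n_obs) {
  stopifnot(n_obs > 3, all(abs(r) <= 1 + 1e-12))
  r <- pmin(pmax(r, -1), 1)
  mi2 <- -n_obs * log1p(-r^2) # 2 * MI
  p <- stats::pchisq(mi2, df = 1, lower.tail = FALSE)
  p[abs(r) == 1] <- 0
  p
}

#' Mutual-information statistic
#'
#' `MI = -n ln(1 - r^2) / 2`; see [mi_pvalue()].
#' @inheritParams mi_pvalue
#' @return The MI statistic(s).
#' @export
mi_statistic <- function(r, n_obs) -n_obs * log1p(-r^2) / 2

#' Global bivariate connectivity measures
#'
#' Summarises a wavelet correlation matrix with three scalars:
#' * `strength`: average over columns of each column's mean correlation
#'   (off-diagonal entries only);
#' * `diversity`: average over columns of each column's correlation
#'   variance (off-diagonal only);
#' * `zero_correlation`: number (and fraction) of upper-triangle pairs
#'   whose MI-test p-value exceeds `sig_alpha`, i.e. correlations
#'   indistinguishable from zero.
#'
#' @param m An `fc_wavelet_cor` object.
#' @param sig_alpha Significance level for the zero-correlation count.
#' @return List with `strength`, `diversity`, `zero_correlation` (count)
#'   and `zero_fraction`.
#' @export
global_measures <- function(m, sig_alpha = 0.05) {
  stopifnot(inherits(m, "fc_wavelet_cor"))
  r <- m$r
  n <- nrow(r)
  off <- matrix(r[row(r) != col(r)], nrow = n - 1) # column-wise off-diagonal
  strength <- mean(colMeans(off))
  diversity <- mean(apply(off, 2, stats::var))
  ut <- r[upper.tri(r)]
  p <- mi_pvalue(ut, m$n_obs)
  zc <- sum(p > sig_alpha)
  list(strength = strength, diversity = diversity,
       zero_correlation = zc, zero_fraction = zc / length(ut))
}
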