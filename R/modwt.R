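# Maximal-overlap discrete wavelet transform (pyramid algorithm, periodic
# boundary). Length-preserving and energy-preserving: for every input,
# sum of squares of the detail coefficients over all scales plus the final
# smooth equals the input sum of squares.

#' Length-8 wavelet filters
#'
#' Scaling (`g`) and wavelet (`h`) filters for the two length-8 Daubechies
#' variants: extremal phase (`"d8"`) and least asymmetric (`"la8"`). The
#' wavelet filter is the quadrature mirror of the scaling filter,
#' `h[l] = (-1)^l g[L-1-l]`.
#'
#' @param filter `"d8"` or `"la8"`.
#' @return List with unit-energy `g` and `h` (DWT normalisation; the MODWT
#'   rescales by `1/sqrt(2)` internally).
#' @export
wavelet_filter <- function(filter = c("d8", "la8")) {
  filter <- match.arg(filter)
  g <- switch(filter,
    d8 = c(0.23037781330885523, 0.71484657055254153, 0.63088076792959036,
           -0.02798376941698385, -0.18703481171888114, 0.03084138183598697,
           0.03288301166698295, -0.01059740178499728),
    la8 = c(0.03222310060404270, -0.01260396726203783, -0.09921954357684722,
            0.29785779560527736, 0.80373875180591614, 0.49761866763201545,
            -0.02963552764599851, -0.07576571478927333))
  L <- length(g)
  h <- (-1)^(0:(L - 1)) * rev(g)
  list(g = g, h = h, length = L, name = filter)
}

#' Maximal-overlap discrete wavelet transform
#'
#' Decomposes each column of a timepoints x regions matrix into `n_scales`
#' detail-coefficient series plus a final smooth, all of the same length as
#' the input (periodic boundary). Scale `s` detail coefficients carry the
#' frequency band `(Nyquist/2^s, Nyquist/2^(s-1))`.
#'
#' @param ts Numeric matrix or vector (timepoints x regions), or an
#'   `fc_timeseries`.
#' @param filter `"d8"` or `"la8"`, or a list from [wavelet_filter()].
#' @param n_scales Number of detail scales.
#' @return Object of class `fc_modwt`: list with `W` (list of detail
#'   matrices, one per scale), `V` (final smooth matrix), `filter`,
#'   `n_scales`, `n_boundary` (per-scale count of coefficients affected by
#'   circular wrap-around) and `tr_seconds` when available.
#' @export
modwt <- function(ts, filter = "d8", n_scales = 4L) {
  x <- unclass(as.matrix(ts))
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("time series must not contain missing values")
  flt <- if (is.list(filter)) filter else wavelet_filter(filter)
  n_scales <- as.integer(n_scales)
  Tn <- nrow(x)
  Lj_max <- (2^(n_scales - 1)) * (flt$length - 1) + 1
  if (Tn < flt$length * 2^(n_scales - 1))
    stop(sprintf("series too short: %d timepoints for %d scales of a length-%d filter (need >= %d)",
                 Tn, n_scales, flt$length, flt$length * 2^(n_scales - 1)))
  g <- flt$g / sqrt(2)
  h <- flt$h / sqrt(2)
  W <- vector("list", n_scales)
  V <- x
  for (s in seq_len(n_scales)) {
    step <- 2^(s - 1)
    Ws <- matrix(0, Tn, ncol(x))
    Vs <- matrix(0, Tn, ncol(x))
    for (l in seq_along(g)) {
      rows <- ((seq_len(Tn) - 1L - step * (l - 1L)) %% Tn) + 1L
      Ws <- Ws + h[l] * V[rows, , drop = FALSE]
      Vs <- Vs + g[l] * V[rows, , drop = FALSE]
    }
    W[[s]] <- Ws
    V <- Vs
  }
  n_boundary <- pmin((2^(seq_len(n_scales)) - 1) * (flt$length - 1), Tn)
  structure(list(W = W, V = V, filter = flt$name, n_scales = n_scales,
                 n_boundary = n_boundary,
                 tr_seconds = attr(ts, "tr_seconds")),
            class = "fc_modwt")
}

#' Wavelet scale-to-frequency band table
#'
#' Maps MODWT detail scales to nominal frequency bands. The Nyquist
#' frequency is `1/(2 tr_seconds)`; scale `s` covers
#' `(Nyquist/2^s, Nyquist/2^(s-1))`, so the bands tile `(Nyquist/2^n, Nyquist]`
#' and the final smooth covers the remainder down to 0. At TR = 2.5 s the
#' Nyquist is 0.2 Hz and scale 2 is the 0.05--0.1 Hz band.
#'
#' @param tr_seconds Repetition time in seconds.
#' @param n_scales Number of detail scales.
#' @return data.frame with columns `scale`, `f_lo`, `f_hi` (Hz).
#' @export
scale_bands <- function(tr_seconds, n_scales = 4L) {
  stopifnot(tr_seconds > 0)
  nyq <- 1 / (2 * tr_seconds)
  s <- seq_len(n_scales)
  data.frame(scale = s, f_lo = nyq / 2^s, f_hi = nyq / 2^(s - 1))
}
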