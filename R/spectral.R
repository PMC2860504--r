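# Frequency-domain similarity: lag-window spectral coherence.
#
# For zero-mean series x_t, y_t of length T the sample cross-covariance at
# lag k >= 0 is c_xy(k) = (1/T) sum_{t=1}^{T-k} x_t y_{t+k}, with
# c_xy(-k) = c_yx(k). The lag-window cross-spectral density at angular
# frequency w (radians per sample) is
#   f_xy(w) = sum_{k=-M}^{M} w_|k| c_xy(k) e^{+iwk}
# whose real part is the cospectrum c(w) and imaginary part the quadrature
# spectrum q(w). Coherence is the magnitude-squared form
#   C_xy(w) = (c(w)^2 + q(w)^2) / (f_xx(w) f_yy(w))  in [0, 1]
# and phase coherence is atan2(q, c). With the e^{+iwk} sign convention a
# series y that lags x by tau samples has phase +w*tau.

#' Lag-window weights
#'
#' Tukey (Tukey-Hanning) window `0.5 (1 + cos(pi k / M))` or Parzen window,
#' evaluated at lags `0..M`. Both satisfy `w_0 = 1`, `w_M = 0` (Tukey) and
#' decrease monotonically.
#'
#' @param n_lags Truncation point `M >= 1`.
#' @param window `"tukey"` or `"parzen"`.
#' @return Numeric vector of `M + 1` weights for lags `0..M`.
#' @export
lag_window <- function(n_lags, window = c("tukey", "parzen")) {
  window <- match.arg(window)
  k <- 0:n_lags
  if (window == "tukey") {
    0.5 * (1 + cos(pi * k / n_lags))
  } else {
    u <- k / n_lags
    ifelse(u <= 0.5, 1 - 6 * u^2 + 6 * u^3, 2 * (1 - u)^3)
  }
}

#' Spectral estimation settings
#'
#' @param frequency_hz Frequency of interest in Hz; must not exceed the
#'   Nyquist frequency `1 / (2 TR)`.
#' @param tr_seconds Sampling interval (repetition time) in seconds.
#' @param n_lags Lag truncation point `M`; `NULL` selects the rule-of-thumb
#'   default [default_n_lags()] once `T` is known.
#' @param window Lag window, `"tukey"` (default) or `"parzen"`.
#' @return An object of class `spectral_config`.
#' @export
spectral_config <- function(frequency_hz, tr_seconds, n_lags = NULL,
                            window = c("tukey", "parzen")) {
  window <- match.arg(window)
  if (frequency_hz <= 0) stop("frequency must be positive")
  if (tr_seconds <= 0) stop("tr_seconds must be positive")
  nyquist <- 1 / (2 * tr_seconds)
  if (frequency_hz > nyquist + 1e-12) {
    stop(sprintf("frequency %.4g Hz exceeds Nyquist %.4g Hz at TR %.3g s",
                 frequency_hz, nyquist, tr_seconds))
  }
  if (!is.null(n_lags) && n_lags < 1) stop("n_lags must be >= 1")
  structure(list(frequency_hz = frequency_hz, tr_seconds = tr_seconds,
                 n_lags = n_lags, window = window),
            class = "spectral_config")
}

#' Rule-of-thumb lag count
#'
#' `round(2 sqrt(T))`, clamped to `[T/10, T/3]` — the classical guidance that
#' the truncation point grow like a small multiple of `sqrt(T)` while staying
#' well below `T`.
#'
#' @param t_len Series length `T`.
#' @return Integer lag count `M`.
#' @export
default_n_lags <- function(t_len) {
  m <- round(2 * sqrt(t_len))
  m <- max(m, ceiling(t_len / 10))
  m <- min(m, floor(t_len / 3))
  max(1L, as.integer(m))
}

resolve_lags <- function(cfg, t_len) {
  m <- if (is.null(cfg$n_lags)) default_n_lags(t_len) else as.integer(cfg$n_lags)
  if (m >= t_len) stop("n_lags M = ", m, " must be smaller than T = ", t_len)
  m
}

# angular frequency in radians per sample
omega_of <- function(cfg) 2 * pi * cfg$frequency_hz * cfg$tr_seconds

#' Cross-spectral estimate for one voxel pair
#'
#' Windowed cross-covariance estimate of the cross-spectral density at a
#' single frequency. Series are mean-centered internally.
#'
#' @param x,y Numeric series of equal length `T`.
#' @param cfg A [spectral_config()]; `M < T` required.
#' @return An object of class `spectral_estimate` with fields `cospectrum`,
#'   `quadrature`, `auto_x`, `auto_y`, plus `omega` and `frequency_hz`.
#' @export
cross_spectral_estimate <- function(x, y, cfg) {
  stopifnot(inherits(cfg, "spectral_config"))
  if (length(x) != length(y)) stop("series lengths differ")
  t_len <- length(x)
  m <- resolve_lags(cfg, t_len)
  x <- x - mean(x)
  y <- y - mean(y)
  if (all(x == 0) || all(y == 0)) stop("degenerate (constant) series: zero auto-spectrum")

  w <- lag_window(m, cfg$window)
  omega <- omega_of(cfg)
  k <- 0:m
  cosk <- cos(omega * k)
  sink <- sin(omega * k)

  cxy <- vapply(k, function(l) sum(x[seq_len(t_len - l)] * y[seq_len(t_len - l) + l]) / t_len, 0)
  cyx <- vapply(k, function(l) sum(y[seq_len(t_len - l)] * x[seq_len(t_len - l) + l]) / t_len, 0)
  cxx <- vapply(k, function(l) sum(x[seq_len(t_len - l)] * x[seq_len(t_len - l) + l]) / t_len, 0)
  cyy <- vapply(k, function(l) sum(y[seq_len(t_len - l)] * y[seq_len(t_len - l) + l]) / t_len, 0)

  # sum over k = -M..M: positive lags use c_xy(k), negative use c_yx(k)
  co <- sum(w * cosk * cxy) + sum((w * cosk * cyx)[-1])
  qu <- sum(w * sink * cxy) - sum((w * sink * cyx)[-1])
  auto_x <- cxx[1] + 2 * sum((w * cosk * cxx)[-1])
  auto_y <- cyy[1] + 2 * sum((w * cosk * cyy)[-1])
  if (auto_x <= 0 || auto_y <= 0) {
    stop("non-positive auto-spectral estimate; series degenerate at this frequency")
  }
  structure(list(cospectrum = co, quadrature = qu,
                 auto_x = auto_x, auto_y = auto_y,
                 omega = omega, frequency_hz = cfg$frequency_hz),
            class = "spectral_estimate")
}

#' Magnitude-squared coherence from a cross-spectral estimate
#'
#' `(c^2 + q^2) / (f_xx f_yy)`, guaranteed in `[0, 1]` by Cauchy-Schwarz up
#' to numerical tolerance (clipped).
#'
#' @param est A [cross_spectral_estimate()] result.
#' @return Coherence in `[0, 1]`.
#' @export
coherence <- function(est) {
  stopifnot(inherits(est, "spectral_estimate"))
  if (est$auto_x <= 0 || est$auto_y <= 0) stop("zero auto-spectrum")
  val <- (est$cospectrum^2 + est$quadrature^2) / (est$auto_x * est$auto_y)
  min(max(val, 0), 1)
}

#' Phase coherence from a cross-spectral estimate
#'
#' Phase angle of the cross-spectrum, `atan2(q, c)` in `(-pi, pi]`.
#' Antisymmetric under swapping the two series.
#'
#' @param est A [cross_spectral_estimate()] result.
#' @return Phase in radians.
#' @export
phase_coherence <- function(est) {
  stopifnot(inherits(est, "spectral_estimate"))
  if (est$cospectrum == 0 && est$quadrature == 0) {
    stop("zero cross-spectrum: phase undefined")
  }
  atan2(est$quadrature, est$cospectrum)
}

#' Pairwise coherence similarity of a masked series
#'
#' Dense symmetric matrix of pairwise magnitude-squared coherences at one
#' frequency. The lag-`k` cross-covariances for all pairs are computed as
#' `n x n` matrix products (one per lag), so the whole matrix costs
#' `O(M n^2 T)` flops through BLAS; results are identical to calling
#' [cross_spectral_estimate()] per pair.
#'
#' @param series A [masked_series()] (or bare `n x T` matrix); rows are
#'   mean-centered (and optionally detrended) before estimation.
#' @param cfg A [spectral_config()]; when `n_lags` is `NULL` the
#'   [default_n_lags()] rule is applied.
#' @param detrend Remove a per-voxel linear trend first (default off).
#' @return A [similarity_matrix()] (dense) with unit diagonal and metric tag
#'   `"coherence@<f>Hz"`.
#' @export
coherence_similarity <- function(series, cfg, detrend = FALSE) {
  stopifnot(inherits(cfg, "spectral_config"))
  data <- if (inherits(series, "masked_series")) series$data else series
  n <- nrow(data)
  if (n < 2L) stop("need at least 2 voxels")
  t_len <- ncol(data)
  m <- resolve_lags(cfg, t_len)

  data <- data - rowMeans(data)
  if (detrend) {
    tt <- seq_len(t_len) - (t_len + 1) / 2
    slope <- (data %*% tt) / sum(tt^2)
    data <- data - tcrossprod(drop(slope), tt)
  }
  if (any(rowSums(data^2) == 0)) {
    stop("constant voxel series present; filter the mask first")
  }

  w <- lag_window(m, cfg$window)
  omega <- omega_of(cfg)

  re <- matrix(0, n, n)
  im <- matrix(0, n, n)
  for (l in 0:m) {
    # entry (i, j): c_{ij}(l) = (1/T) sum_t data[i, t] data[j, t + l]
    cc <- tcrossprod(data[, seq_len(t_len - l), drop = FALSE],
                     data[, seq_len(t_len - l) + l, drop = FALSE]) / t_len
    if (l == 0L) {
      re <- re + w[1] * cc
    } else {
      wl <- w[l + 1]
      re <- re + wl * cos(omega * l) * (cc + t(cc))
      # f_ij = sum_{k>=0} w c_ij(k) e^{iwk} + sum_{k>0} w c_ji(k) e^{-iwk}
      im <- im + wl * sin(omega * l) * (cc - t(cc))
    }
  }
  auto <- diag(re)
  if (any(auto <= 0)) {
    stop("non-positive auto-spectral estimate for voxel(s) ",
         paste(utils::head(which(auto <= 0), 5L), collapse = ", "))
  }
  coh <- (re^2 + im^2) / outer(auto, auto)
  coh <- pmin(pmax(coh, 0), 1)
  diag(coh) <- 1
  coh <- (coh + t(coh)) / 2
  similarity_matrix(n, "dense", dense = coh,
                    metric = sprintf("coherence@%gHz", cfg$frequency_hz))
}
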