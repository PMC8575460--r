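#' Haemodynamic response function kernels
#'
#' Samples a canonical haemodynamic response function (HRF) at a given
#' resolution. Two kernels are available: a single-gamma HRF (used as the
#' reference response for travelling-wave phase mapping) peaking near 6 s, and
#' the double-gamma HRF (a positive gamma response minus a scaled later gamma,
#' giving the characteristic post-stimulus undershoot) used for blocked-design
#' GLM modelling.
#'
#' The kernel is normalised to unit peak. The peak is located on a fine
#' internal grid (0.01 s), not on the requested sampling grid, so that a
#' kernel sampled at a coarse \code{dt} is exactly the decimation of the same
#' kernel sampled finely.
#'
#' @param kind \code{"gamma"} or \code{"double_gamma"}.
#' @param dt sampling interval in seconds (> 0).
#' @param duration kernel support in seconds (default 32).
#' @return numeric vector: the kernel sampled at \code{0, dt, 2*dt, ...} up to
#'   \code{duration}, with attributes \code{dt} and \code{kind}.
#' @examples
#' h <- make_hrf("double_gamma", dt = 0.1)
#' which.max(h) # peak near 5 s
#' min(h) < 0   # undershoot
#' @export
make_hrf <- function(kind = c("double_gamma", "gamma"), dt, duration = 32) {
  kind <- match.arg(kind)
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) stop("dt must be a positive scalar")
  f <- switch(kind,
    gamma = function(t) stats::dgamma(t, shape = 7, rate = 1),
    double_gamma = function(t) {
      stats::dgamma(t, shape = 6, rate = 1) - stats::dgamma(t, shape = 16, rate = 1) / 6
    }
  )
  # unit-peak normalisation on a fixed fine grid, independent of dt
  fine <- f(seq(0, duration, by = 0.01))
  peak <- max(fine)
  t <- seq(0, duration, by = dt)
  h <- f(t) / peak
  structure(h, dt = dt, kind = kind)
}

# First temporal derivative of the HRF, same sampling/normalisation
# conventions as make_hrf (scaled by the same unit-peak constant).
make_hrf_derivative <- function(kind = c("double_gamma", "gamma"), dt, duration = 32) {
  kind <- match.arg(kind)
  eps <- 1e-4
  base <- switch(kind,
    gamma = function(t) stats::dgamma(t, shape = 7, rate = 1),
    double_gamma = function(t) {
      stats::dgamma(t, shape = 6, rate = 1) - stats::dgamma(t, shape = 16, rate = 1) / 6
    }
  )
  fine <- base(seq(0, duration, by = 0.01))
  peak <- max(fine)
  t <- seq(0, duration, by = dt)
  d <- (base(t + eps) - base(pmax(t - eps, 0))) / (eps + pmin(t, eps))
  structure(d / peak, dt = dt, kind = kind)
}

# Convolve a neural indicator sampled on a fine grid with an HRF kernel and
# resample at acquisition times. `onsets`/`durations` in seconds; returns the
# regressor at t = (0:(n_vol-1)) * tr, scaled to unit peak height when
# `normalise` (peak computed over this run).
convolve_boxcar <- function(onsets, durations, n_vol, tr, hrf_kind = "double_gamma",
                            dt = 0.1, normalise = TRUE, kernel = NULL) {
  total <- n_vol * tr
  t_fine <- seq(0, total, by = dt)
  box <- numeric(length(t_fine))
  for (i in seq_along(onsets)) {
    box[t_fine >= onsets[i] & t_fine < onsets[i] + durations[i]] <- 1
  }
  if (is.null(kernel)) kernel <- make_hrf(hrf_kind, dt = dt)
  conv <- fast_conv(box, kernel)[seq_along(t_fine)] * dt
  idx <- round((0:(n_vol - 1)) * tr / dt) + 1
  reg <- conv[idx]
  if (normalise && max(abs(conv)) > 0) reg <- reg / max(conv)
  reg
}

# Linear convolution via power-of-two padded FFT (lengths like 7281 are slow
# in R's mixed-radix fft).
fast_conv <- function(x, k) {
  n <- length(x) + length(k) - 1
  N <- stats::nextn(n, 2)
  xf <- stats::fft(c(x, numeric(N - length(x))))
  kf <- stats::fft(c(k, numeric(N - length(k))))
  Re(stats::fft(xf * kf, inverse = TRUE))[seq_len(n)] / N
}
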