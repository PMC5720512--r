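#' Windowed root-mean-square amplitude
#'
#' \deqn{RMS = \sqrt{\sum_i x_i^2 / N}} over non-overlapping windows of
#' `window_ms` (2500 ms by default, the windowing used throughout the
#' feature analysis); the reported value is the mean across complete
#' windows. A signal shorter than one window is one window.
#'
#' @param signal Numeric vector, or a data frame with a `voltage` column.
#' @param fs Sampling rate, Hz.
#' @param window_ms Window length, ms.
#' @return A tibble with columns `window`, `rms`, plus the across-window
#'   mean in attribute `mean`; use [semg_rms_mean()] for the scalar.
#' @export
semg_rms <- function(signal, fs = 1000, window_ms = 2500) {
  x <- waveform_samples(signal)
  if (length(x) == 0L) stop("empty signal", call. = FALSE)
  idx <- window_indices(length(x), fs, window_ms)
  vals <- purrr::map_dbl(idx, function(j) sqrt(mean(x[j]^2)))
  out <- tibble::tibble(window = seq_along(vals), rms = vals)
  attr(out, "mean") <- mean(vals)
  out
}

#' @rdname semg_rms
#' @export
semg_rms_mean <- function(signal, fs = 1000, window_ms = 2500) {
  attr(semg_rms(signal, fs, window_ms), "mean")
}

window_indices <- function(n, fs, window_ms) {
  w <- round(window_ms * fs / 1000)
  if (n < w) return(list(seq_len(n)))
  starts <- seq(1L, n - w + 1L, by = w)
  purrr::map(starts, function(s) s:(s + w - 1L))
}

#' Median frequency of the power spectrum
#'
#' The frequency splitting the periodogram power into equal halves:
#' \deqn{\sum_{j \le MDF} P_j = \sum_{j \ge MDF} P_j = \tfrac12 \sum_j P_j.}
#' Estimated from the rectangular-window periodogram of the whole segment
#' (`detrend`ed to remove the DC bin). The two-sided condition is applied
#' symmetrically: the half-power point is interpolated linearly on the
#' cumulative power from below and on the reversed cumulative from above,
#' and the two estimates are averaged, so two equal-power tones give their
#' midpoint and a spectrum concentrated in one bin gives that bin.
#'
#' @inheritParams semg_rms
#' @param detrend Subtract the mean before the FFT (default `TRUE`).
#' @return Median frequency in Hz.
#' @examples
#' t <- seq(0, 1, by = 1/1000)
#' median_frequency(sin(2 * pi * 100 * t), fs = 1000)  # ~100 Hz
#' @export
median_frequency <- function(signal, fs = 1000, detrend = TRUE) {
  x <- waveform_samples(signal)
  if (length(x) < 256L) stop("need at least 256 samples", call. = FALSE)
  if (all(x == 0)) stop("median frequency undefined for an all-zero signal", call. = FALSE)
  if (detrend) x <- x - mean(x)
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  half <- floor(n / 2) + 1L
  p <- p[seq_len(half)]                     # one-sided
  freq <- (seq_len(half) - 1L) * fs / n
  tot <- sum(p)
  if (tot == 0) stop("median frequency undefined: zero total power", call. = FALSE)
  half_cross <- function(pw, fr) {
    cum <- cumsum(pw)
    # tolerance so an exact half-power bin counts as the crossing
    k <- which(cum >= tot / 2 * (1 - 1e-9))[1]
    if (k == 1L) return(fr[1])
    frac <- (tot / 2 - cum[k - 1L]) / (cum[k] - cum[k - 1L])
    fr[k - 1L] + frac * (fr[k] - fr[k - 1L])
  }
  (half_cross(p, freq) + half_cross(rev(p), rev(freq))) / 2
}

#' Higuchi fractal dimension
#'
#' For each interval `k = 1..k_max`, the signal is decimated into `k`
#' sub-series starting at offsets `m = 1..k`; each sub-series' normalised
#' curve length
#' \deqn{L_m(k) = \frac{\sum_i |y(m+ik) - y(m+(i-1)k)|\,(N-1)}
#'   {\lfloor (N-m)/k \rfloor\, k^2}}
#' is averaged over `m` to give `L(k)`. The fractal dimension is the slope
#' of the least-squares fit of `ln L(k)` on `ln(1/k)`; `k_max = 6` is the
#' tuning used for surface EMG.
#'
#' @inheritParams semg_rms
#' @param k_max Largest decimation interval (default 6).
#' @return Fractal dimension (about 1 for a smooth curve, 2 for white noise).
#' @export
higuchi_fd <- function(signal, k_max = 6) {
  y <- waveform_samples(signal)
  n <- length(y)
  if (n < 100L) stop("need at least 100 samples", call. = FALSE)
  lk <- purrr::map_dbl(seq_len(k_max), function(k) {
    lm <- purrr::map_dbl(seq_len(k), function(m) {
      n_seg <- floor((n - m) / k)
      if (n_seg < 1L) return(NA_real_)
      i <- seq_len(n_seg)
      len <- sum(abs(y[m + i * k] - y[m + (i - 1L) * k]))
      len * (n - 1) / (n_seg * k^2)
    })
    mean(lm, na.rm = TRUE)
  })
  if (any(lk <= 0)) {
    stop("Higuchi FD undefined: zero curve length (constant signal?)", call. = FALSE)
  }
  as.numeric(stats::coef(stats::lm(log(lk) ~ log(1 / seq_len(k_max))))[2])
}

#' Feature set of a surface EMG signal
#'
#' The three validation features in one tibble: windowed-mean RMS, the
#' median frequency of the whole segment, and the windowed-mean Higuchi
#' fractal dimension (windows of `window_ms`, FD with `k_max`).
#'
#' @inheritParams semg_rms
#' @param k_max Higuchi decimation bound.
#' @return One-row tibble with columns `rms`, `mdf`, `fd`, `window_ms`,
#'   `k_max`.
#' @export
semg_features <- function(signal, fs = 1000, window_ms = 2500, k_max = 6) {
  x <- waveform_samples(signal)
  idx <- window_indices(length(x), fs, window_ms)
  tibble::tibble(
    rms = semg_rms_mean(x, fs, window_ms),
    mdf = median_frequency(x, fs),
    fd = mean(purrr::map_dbl(idx, function(j) higuchi_fd(x[j], k_max))),
    window_ms = window_ms,
    k_max = k_max
  )
}
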