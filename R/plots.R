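#' Plot methods
#'
#' `autoplot()` methods render the package's result types with ggplot2:
#' a sampled waveform (`sfap_waveform`, `semg_signal`) as a voltage trace,
#' and a [pennation_sweep()] as shape correlation and composite features
#' against the pennation angle.
#'
#' @param object Object to plot.
#' @param ... Unused.
#' @return A ggplot object (patch of panels for the sweep).
#' @name autoplot-pennemg
NULL

#' @rdname autoplot-pennemg
#' @exportS3Method ggplot2::autoplot
autoplot.sfap_waveform <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_ms, .data$voltage)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "differential potential (a.u.)",
                  title = sprintf("SFAP, pennation %g deg",
                                  attr(object, "pennation"))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-pennemg
#' @exportS3Method ggplot2::autoplot
autoplot.semg_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_ms / 1000, .data$voltage)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "sEMG (a.u.)",
                  title = sprintf("Simulated sEMG at %g %%MVC",
                                  attr(object, "mvc"))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-pennemg
#' @exportS3Method ggplot2::autoplot
autoplot.pennation_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("angle", "correlation", "rms", "mdf", "fd")],
    -"angle", names_to = "feature", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$angle, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "pennation angle (deg)", y = NULL,
                  title = "Pennation sweep: SFAP shape and composite features") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-pennemg
#' @param x Object to plot (base `plot()` delegate).
#' @param y Unused.
#' @export
plot.pennation_sweep <- function(x, y, ...) print(autoplot.pennation_sweep(x, ...))

#' Bland-Altman plot
#'
#' Scatter of pairwise differences against pairwise means with the mean
#' difference and the +/- `n_sd` SD limits of agreement used as TOST
#' margins.
#'
#' @param a,b Numeric samples of equal length (sorted-by-magnitude pairing
#'   applied when `pair_by_magnitude`).
#' @param n_sd Limit width in SDs (default 2).
#' @param pair_by_magnitude Sort both samples before pairing.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(a, b, n_sd = 2, pair_by_magnitude = TRUE) {
  if (pair_by_magnitude) {
    a <- sort(a)
    b <- sort(b)
  }
  ba <- bland_altman_bounds(a, b, n_sd = n_sd)
  df <- tibble::tibble(mean = (a + b) / 2, diff = a - b)
  ggplot2::ggplot(df, ggplot2::aes(.data$mean, .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$mean_diff, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(ba$lower, ba$upper), linetype = 2) +
    ggplot2::labs(x = "pairwise mean", y = "pairwise difference",
                  title = sprintf("Bland-Altman limits: %.3g to %.3g",
                                  ba$lower, ba$upper)) +
    ggplot2::theme_minimal()
}

#' Firing-rate schedule of a pool
#'
#' Firing rate of every motor unit against drive: silent below the
#' recruitment threshold, linear from the minimum rate at threshold to the
#' peak rate at 100 %MVC.
#'
#' @param pool A [build_pool()] tibble.
#' @param drives Drive grid, %MVC.
#' @return A ggplot object.
#' @export
plot_rate_coding <- function(pool, drives = seq(0, 100, by = 1)) {
  p <- attr(pool, "params")
  df <- tidyr::expand_grid(unit = pool$unit, drive = drives)
  df <- dplyr::mutate(
    dplyr::left_join(df, tibble::as_tibble(pool)[c("unit", "threshold")], by = "unit"),
    rate = purrr::map2_dbl(.data$threshold, .data$drive,
                           ~ firing_rate(.x, .y, p$mfr, p$pfr))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$drive, .data$rate, group = .data$unit)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::labs(x = "drive (%MVC)", y = "firing rate (Hz)",
                  title = "Recruitment and rate coding") +
    ggplot2::theme_minimal()
}
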