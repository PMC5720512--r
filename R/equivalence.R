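#' Two-sample t-test p-value
#'
#' Thin wrapper around [stats::t.test()] comparing a feature computed on two
#' groups of trials (e.g. simulated vs recorded). Welch's unequal-variance
#' test by default; set `pooled = TRUE` for the classic equal-variance test
#' or `paired = TRUE` for the paired variant.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param pooled Use the pooled-variance test.
#' @param paired Use the paired test (equal lengths required).
#' @return A one-row tibble: `p_value`, `t`, `df`, `mean_a`, `mean_b`,
#'   `significant` (at 0.05).
#' @export
two_sample_t <- function(a, b, pooled = FALSE, paired = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("zero variance in both samples: t-test undefined", call. = FALSE)
  }
  fit <- stats::t.test(a, b, var.equal = pooled, paired = paired)
  tibble::tibble(
    p_value = fit$p.value,
    t = unname(fit$statistic),
    df = unname(fit$parameter),
    mean_a = mean(a),
    mean_b = mean(b),
    significant = fit$p.value < 0.05
  )
}

#' Bland-Altman limits of agreement
#'
#' Mean difference of paired measurements plus/minus `n_sd` standard
#' deviations of the differences; the limits used as TOST equivalence
#' margins. When the samples are not naturally paired (independent batches
#' of simulated and recorded trials), pairing by sorted magnitude is applied
#' first when `pair_by_magnitude = TRUE`.
#'
#' @param a,b Numeric samples of equal length.
#' @param n_sd Width of the limits in SDs of the difference (default 2).
#' @param pair_by_magnitude Sort both samples before differencing.
#' @return A one-row tibble: `lower`, `upper`, `mean_diff`, `sd_diff`, `n_sd`.
#' @export
bland_altman_bounds <- function(a, b, n_sd = 2, pair_by_magnitude = FALSE) {
  if (length(a) != length(b)) {
    stop("Bland-Altman limits need paired samples of equal length", call. = FALSE)
  }
  if (pair_by_magnitude) {
    a <- sort(a)
    b <- sort(b)
  }
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  tibble::tibble(lower = m - n_sd * s, upper = m + n_sd * s,
                 mean_diff = m, sd_diff = s, n_sd = n_sd)
}

#' Two one-sided tests of equivalence (TOST)
#'
#' Tests whether the mean difference between two samples lies inside the
#' margin `(lower, upper)`: one one-sided t-test of H0 `diff <= lower` and
#' one of H0 `diff >= upper`; the TOST p-value is the larger of the two, and
#' equivalence is declared when it falls below `alpha`. With `alpha = 0.10`
#' this is the 90%-confidence-interval criterion: equivalence holds exactly
#' when the `(1 - 2 alpha)` CI of the difference sits inside the margins.
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @param lower,upper Equivalence margins in feature units, `lower < upper`
#'   (typically Bland-Altman limits, see [bland_altman_bounds()]).
#' @param alpha Significance level (default 0.10).
#' @param pooled Pooled-variance variant (default Welch).
#' @param feature_name,mvc_level Optional labels carried into the result.
#' @return Object of class `tost_equivalence`; see [tidy.tost_equivalence()].
#' @examples
#' a <- rnorm(20); b <- rnorm(20)
#' res <- tost(a, b, lower = -1, upper = 1)
#' glance(res)
#' @export
tost <- function(a, b, lower, upper, alpha = 0.10, pooled = FALSE,
                 feature_name = NA_character_, mvc_level = NA_real_) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (!(lower < upper)) stop("degenerate bounds: lower must be < upper", call. = FALSE)
  welch <- function(mu, alternative) {
    stats::t.test(a, b, mu = mu, alternative = alternative,
                  var.equal = pooled)$p.value
  }
  p_lower <- welch(lower, "greater")  # H0: diff <= lower vs H1: diff > lower
  p_upper <- welch(upper, "less")     # H0: diff >= upper vs H1: diff < upper
  d <- if (length(a) == length(b)) a - b else NULL
  structure(
    list(
      feature_name = feature_name, mvc_level = mvc_level,
      t_p = two_sample_t(a, b, pooled = pooled)$p_value,
      tost_p = max(p_lower, p_upper),
      p_lower = p_lower, p_upper = p_upper,
      lower_bound = lower, upper_bound = upper,
      mean_difference = mean(a) - mean(b),
      sd_difference = if (is.null(d)) NA_real_ else stats::sd(d),
      alpha = alpha,
      equivalent = max(p_lower, p_upper) < alpha,
      n_a = length(a), n_b = length(b),
      a = a, b = b
    ),
    class = "tost_equivalence"
  )
}

#' Equivalence analysis of one feature between two trial batches
#'
#' The full pipeline for one feature at one contraction level: Bland-Altman
#' limits (mean difference +/- `n_sd` SD, pairing by sorted magnitude since
#' the batches are not naturally paired) supply the margins, then [tost()]
#' tests equivalence at `alpha`.
#'
#' @inheritParams tost
#' @inheritParams bland_altman_bounds
#' @return A `tost_equivalence` object.
#' @export
equivalence_test <- function(a, b, n_sd = 2, alpha = 0.10, pooled = FALSE,
                             feature_name = NA_character_,
                             mvc_level = NA_real_) {
  ba <- bland_altman_bounds(a, b, n_sd = n_sd, pair_by_magnitude = TRUE)
  tost(a, b, lower = ba$lower, upper = ba$upper, alpha = alpha,
       pooled = pooled, feature_name = feature_name, mvc_level = mvc_level)
}

#' @export
print.tost_equivalence <- function(x, ...) {
  cat("<TOST equivalence test>\n")
  if (!is.na(x$feature_name)) cat(sprintf("  feature: %s", x$feature_name),
                                  if (!is.na(x$mvc_level)) sprintf(" at %g %%MVC", x$mvc_level), "\n", sep = "")
  cat(sprintf("  mean difference: %.4g  margins: (%.4g, %.4g)\n",
              x$mean_difference, x$lower_bound, x$upper_bound))
  cat(sprintf("  TOST p = %.4g (alpha = %g) -> %s\n", x$tost_p, x$alpha,
              if (x$equivalent) "equivalent" else "not shown equivalent"))
  cat(sprintf("  two-sample t-test p = %.4g\n", x$t_p))
  invisible(x)
}

#' Tidy a TOST equivalence result
#'
#' @param x A `tost_equivalence` object.
#' @param ... Unused.
#' @return `tidy()`: one row per one-sided test with `term`, `p.value`;
#'   `glance()`: a one-row model summary.
#' @exportS3Method generics::tidy
tidy.tost_equivalence <- function(x, ...) {
  tibble::tibble(
    term = c("diff > lower", "diff < upper"),
    null.value = c(x$lower_bound, x$upper_bound),
    estimate = x$mean_difference,
    p.value = c(x$p_lower, x$p_upper)
  )
}

#' @rdname tidy.tost_equivalence
#' @exportS3Method generics::glance
glance.tost_equivalence <- function(x, ...) {
  tibble::tibble(
    feature = x$feature_name, mvc = x$mvc_level,
    mean_difference = x$mean_difference,
    lower_bound = x$lower_bound, upper_bound = x$upper_bound,
    tost_p = x$tost_p, t_p = x$t_p, alpha = x$alpha,
    equivalent = x$equivalent, n_a = x$n_a, n_b = x$n_b
  )
}
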