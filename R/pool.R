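#' Motor-unit pool parameters
#'
#' Parameters of the Fuglevand-style motor-unit population: pool size,
#' muscle geometry, the firing-rate law bounds and the recruitment range.
#'
#' @param n_units Total number of motor units (Tibialis Anterior literature
#'   range 125-652).
#' @param muscle_radius Radius of the circular muscle cross-section, mm.
#' @param mfr Minimum firing rate, Hz (onset rate of a newly recruited unit).
#' @param pfr Peak firing rate, Hz (every unit saturates there at 100% MVC).
#' @param rr Recruitment range, %MVC: the drive at which the last (largest)
#'   unit is recruited.
#' @param slow_fraction Proportion of slow (type-1) motor units.
#' @param fiber_density Fibres per mm^2 of motor-unit territory; also sets
#'   the muscle's total fibre budget `fiber_density * pi * muscle_radius^2`.
#' @param half_length Fibre half-length, mm.
#' @param pennation Pennation angle applied to every fibre, degrees.
#' @param cutaneous_mm Thickness of the skin + subcutaneous layer, mm.
#' @param iz_spread_mm Half-width of the innervation-zone band, mm: each
#'   fibre's neuromuscular junction sits at mid-fibre but the junctions
#'   scatter uniformly within `+/- iz_spread_mm` along the muscle axis, as
#'   end-plate bands do in vivo. 0 puts every junction in one plane.
#' @return Object of class `pool_params`.
#' @export
pool_params <- function(n_units = 200, muscle_radius = 20, mfr = 8, pfr = 30,
                        rr = 30, slow_fraction = 0.7, fiber_density = 20,
                        half_length = 45, pennation = 20, cutaneous_mm = 3,
                        iz_spread_mm = 10) {
  stopifnot(n_units >= 1, muscle_radius > 0, fiber_density > 0,
            half_length > 0, pennation >= 0, pennation <= 30,
            iz_spread_mm >= 0)
  if (!(mfr < pfr)) stop("mfr must be below pfr", call. = FALSE)
  if (rr <= 0 || rr > 100) stop("rr must lie in (0, 100] %MVC", call. = FALSE)
  if (slow_fraction < 0 || slow_fraction > 1) {
    stop("slow_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_units = as.integer(n_units), muscle_radius = muscle_radius,
         mfr = mfr, pfr = pfr, rr = rr, slow_fraction = slow_fraction,
         fiber_density = fiber_density, half_length = half_length,
         pennation = pennation, cutaneous_mm = cutaneous_mm,
         iz_spread_mm = iz_spread_mm),
    class = "pool_params"
  )
}

#' Recruitment thresholds (size principle)
#'
#' Exponential threshold ladder
#' \deqn{RT_i = \exp\!\big( (\ln RR / T_{Mu})\, i \big), \quad i = 1..T_{Mu}}
#' so that thresholds are geometric in the size rank and the last unit is
#' recruited exactly at the recruitment range `rr`.
#'
#' @param n_units Number of motor units.
#' @param rr Recruitment range, %MVC.
#' @return Numeric vector of strictly increasing thresholds (%MVC).
#' @examples
#' recruitment_thresholds(2, 100)  # 10, 100
#' @export
recruitment_thresholds <- function(n_units, rr) {
  stopifnot(n_units >= 1)
  if (rr <= 0) stop("rr must be positive (log of the recruitment range)", call. = FALSE)
  rt <- exp(log(rr) / n_units * seq_len(n_units))
  rt[n_units] <- rr # exact by construction; exp/log round-trip drifts in fp
  rt
}

#' Firing rate of a motor unit under a constant drive
#'
#' Below its recruitment threshold a unit is silent; above it the rate rises
#' linearly from `mfr` at threshold with slope
#' \eqn{\alpha_i = (PFR - MFR) / (100 - RT_i)}, reaching `pfr` exactly at
#' 100 %MVC. Rates are clamped at `pfr`. A unit with threshold 100 fires
#' only at exactly 100 %MVC, at `pfr` (degenerate slope branch).
#'
#' @param threshold Recruitment threshold(s) RT_i, %MVC.
#' @param drive Excitation drive, %MVC in [0, 100].
#' @param mfr,pfr Minimum and peak firing rates, Hz.
#' @return Firing rate(s), Hz (0 for inactive units).
#' @export
firing_rate <- function(threshold, drive, mfr = 8, pfr = 30) {
  if (drive < 0 || drive > 100) stop("drive must lie in [0, 100] %MVC", call. = FALSE)
  alpha <- ifelse(threshold >= 100, Inf, (pfr - mfr) / (100 - threshold))
  fr <- ifelse(threshold > drive, 0,
               ifelse(is.infinite(alpha), pfr,
                      pmin(pfr, mfr + (drive - threshold) * alpha)))
  as.numeric(fr)
}

#' Build the motor-unit pool
#'
#' Constructs the population as a tibble, one row per motor unit: thresholds
#' from [recruitment_thresholds()], fibre counts proportional to the
#' threshold (large-threshold units are large, per the size principle) and
#' normalised so the whole muscle holds
#' `fiber_density * pi * muscle_radius^2` fibres, circular territories sized
#' to hold the unit's fibres at `fiber_density`, territory centres uniform
#' over the muscle disc (kept inside it), fibres uniform within each
#' territory, and fibre types assigned to whole units by `slow_fraction`
#' with slow/fast membrane parameter sets.
#'
#' @param p A [pool_params()] object.
#' @param membrane_slow,membrane_fast Membrane parameter sets for the two
#'   fibre types.
#' @param seed Integer RNG seed; two builds with the same seed are identical.
#' @return A tibble of class `motor_unit_pool` with columns `unit`,
#'   `threshold`, `type`, `n_fibers`, `territory_x`, `territory_y`,
#'   `territory_radius`, and list-columns `fiber_x`, `fiber_y`, `fiber_z`
#'   (fibre neuromuscular-junction positions, mm; z within the
#'   innervation-zone band). Pool-level parameters in attributes.
#' @export
build_pool <- function(p = pool_params(),
                       membrane_slow = membrane_params_slow(),
                       membrane_fast = membrane_params_fast(),
                       seed = 1L) {
  stopifnot(inherits(p, "pool_params"))
  set.seed(seed)
  n <- p$n_units
  rt <- recruitment_thresholds(n, p$rr)

  total_fibers <- p$fiber_density * pi * p$muscle_radius^2
  counts <- pmax(1L, round(total_fibers * rt / sum(rt)))
  terr_r <- sqrt(counts / (pi * p$fiber_density))
  if (any(terr_r >= p$muscle_radius)) {
    stop("a territory exceeds the muscle cross-section; increase fiber_density or muscle_radius",
         call. = FALSE)
  }

  # territory centres uniform over the disc, shrunk so territories fit inside
  ang <- stats::runif(n, 0, 2 * pi)
  rad <- pmax(0, p$muscle_radius - terr_r) * sqrt(stats::runif(n))
  cx <- rad * cos(ang)
  cy <- rad * sin(ang)

  n_slow <- round(p$slow_fraction * n)
  type <- sample(c(rep("slow", n_slow), rep("fast", n - n_slow)))

  fib <- purrr::map(seq_len(n), function(i) {
    a <- stats::runif(counts[i], 0, 2 * pi)
    r <- terr_r[i] * sqrt(stats::runif(counts[i]))
    list(x = cx[i] + r * cos(a), y = cy[i] + r * sin(a),
         z = stats::runif(counts[i], -p$iz_spread_mm, p$iz_spread_mm))
  })

  out <- tibble::tibble(
    unit = seq_len(n),
    threshold = rt,
    type = type,
    n_fibers = as.integer(counts),
    territory_x = cx,
    territory_y = cy,
    territory_radius = terr_r,
    fiber_x = purrr::map(fib, "x"),
    fiber_y = purrr::map(fib, "y"),
    fiber_z = purrr::map(fib, "z")
  )
  class(out) <- c("motor_unit_pool", class(out))
  attr(out, "params") <- p
  attr(out, "membrane") <- list(slow = membrane_slow, fast = membrane_fast)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Generate spike trains for the pool at a constant drive
#'
#' Active units (threshold <= drive) fire as renewal processes with mean
#' inter-spike interval `1000 / FR_i` ms and Gaussian ISI jitter of
#' coefficient of variation `isi_cv` (truncated at 10% of the mean so
#' intervals stay positive); `isi_cv = 0` gives perfectly periodic trains.
#' The first spike of each unit is uniform over one mean ISI, so units are
#' desynchronised. Inactive units return empty trains.
#'
#' @param pool A [build_pool()] tibble.
#' @param drive Constant excitation, %MVC.
#' @param duration_ms Train duration, ms.
#' @param mfr,pfr Firing-rate bounds, Hz; default from the pool's parameters.
#' @param isi_cv ISI coefficient of variation (default 0.2).
#' @param seed Integer RNG seed.
#' @return A tibble with columns `unit`, `rate_hz`, and list-column
#'   `firing_times` (ms, strictly increasing).
#' @export
generate_spike_trains <- function(pool, drive, duration_ms,
                                  mfr = NULL, pfr = NULL,
                                  isi_cv = 0.2, seed = 1L) {
  stopifnot(inherits(pool, "motor_unit_pool"), duration_ms > 0)
  p <- attr(pool, "params")
  if (is.null(mfr)) mfr <- p$mfr
  if (is.null(pfr)) pfr <- p$pfr
  set.seed(seed)
  rates <- firing_rate(pool$threshold, drive, mfr = mfr, pfr = pfr)
  trains <- purrr::map(rates, function(fr) {
    if (fr <= 0) return(numeric(0))
    mean_isi <- 1000 / fr
    n_max <- ceiling(duration_ms / mean_isi) + 10L
    first <- stats::runif(1, 0, mean_isi)
    if (isi_cv > 0) {
      isi <- stats::rnorm(n_max, mean_isi, isi_cv * mean_isi)
      isi <- pmax(isi, 0.1 * mean_isi)
    } else {
      isi <- rep(mean_isi, n_max)
    }
    t <- first + cumsum(c(0, isi))
    while (t[length(t)] < duration_ms) {
      t <- c(t, t[length(t)] + max(stats::rnorm(1, mean_isi, isi_cv * mean_isi),
                                   0.1 * mean_isi))
    }
    t[t < duration_ms]
  })
  out <- tibble::tibble(unit = pool$unit, rate_hz = rates,
                        firing_times = trains)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "drive") <- drive
  attr(out, "duration_ms") <- duration_ms
  out
}
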