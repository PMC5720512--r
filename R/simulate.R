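#' Simulation configuration
#'
#' Everything a composite-sEMG simulation needs: the pool description, the
#' differential electrode pair (by default 10 mm inter-electrode distance,
#' one cutaneous layer above the muscle surface, offset 10 mm toward the
#' tendon), sampling, duration, the %MVC levels of interest, and the
#' physiological parameter ranges redrawn on every batch repetition.
#'
#' @param pool A [pool_params()] object.
#' @param electrodes An [electrode_pair()], or `NULL` to place the default
#'   pair at `y = muscle_radius + cutaneous_mm`.
#' @param fs Sampling rate, Hz.
#' @param duration_ms Signal duration, ms (experiment protocol: 15 s trials).
#' @param mvc_levels %MVC levels simulated by [semg_batch()].
#' @param n_repeats Batch repetitions with independently redrawn parameters.
#' @param parameter_ranges Named list of parameter sampling rules, entries
#'   `list(dist = "uniform", min=, max=)` or `list(dist = "normal", mean=, sd=)`;
#'   see [ta_parameter_ranges()] for the default set and names.
#' @param isi_cv Inter-spike-interval coefficient of variation.
#' @param dz_mm Fibre discretisation step, mm.
#' @param redraw_pennation Redraw the pennation angle with the other batch
#'   parameters (`TRUE`, default) or pin it at `pool$pennation`.
#' @param source_model Source formulation used for every waveform,
#'   `"progressive"` (charge-conserving, default) or `"truncated"`; see
#'   [sfap()].
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(pool = pool_params(), electrodes = NULL,
                              fs = 1000, duration_ms = 15000,
                              mvc_levels = c(25, 50, 75), n_repeats = 20,
                              parameter_ranges = ta_parameter_ranges(),
                              isi_cv = 0.2, dz_mm = 0.5,
                              redraw_pennation = TRUE,
                              source_model = c("progressive", "truncated")) {
  source_model <- match.arg(source_model)
  stopifnot(inherits(pool, "pool_params"), n_repeats >= 1, fs >= 1000)
  if (any(mvc_levels <= 0 | mvc_levels > 100)) {
    stop("mvc_levels must lie in (0, 100]", call. = FALSE)
  }
  if (is.null(electrodes)) {
    electrodes <- electrode_pair_default(pool$muscle_radius + pool$cutaneous_mm)
  }
  stopifnot(inherits(electrodes, "electrode_pair"))
  structure(
    list(pool = pool, electrodes = electrodes, fs = fs,
         duration_ms = duration_ms, mvc_levels = mvc_levels,
         n_repeats = as.integer(n_repeats),
         parameter_ranges = parameter_ranges, isi_cv = isi_cv,
         dz_mm = dz_mm, redraw_pennation = redraw_pennation,
         source_model = source_model),
    class = "simulation_config"
  )
}

#' Physiological parameter ranges for batch randomisation
#'
#' The Tibialis Anterior literature values used by the repeated-simulation
#' study: motor-unit count 125-652 (uniform), muscle radius 20 +/- 2 mm,
#' slow/fast conduction velocities 3.9/4.9 +/- 0.3 m/s, fibre half-length
#' 45 +/- 0.4 mm, minimum firing rate 7-23 Hz, peak firing rate 14-50 Hz,
#' pennation angle 20 +/- 2 degrees. Gaussian draws are clamped to
#' mean +/- 4 SD.
#'
#' @param n_units_min,n_units_max Bounds for the motor-unit count draw.
#' @return Named list of sampling rules.
#' @export
ta_parameter_ranges <- function(n_units_min = 125, n_units_max = 652) {
  list(
    n_units    = list(dist = "uniform", min = n_units_min, max = n_units_max),
    muscle_radius = list(dist = "normal", mean = 20, sd = 2),
    velocity_slow = list(dist = "normal", mean = 3.9, sd = 0.3),
    velocity_fast = list(dist = "normal", mean = 4.9, sd = 0.3),
    half_length   = list(dist = "normal", mean = 45, sd = 0.4),
    mfr        = list(dist = "uniform", min = 7, max = 23),
    pfr        = list(dist = "uniform", min = 14, max = 50),
    pennation  = list(dist = "normal", mean = 20, sd = 2)
  )
}

draw_parameter <- function(rule) {
  switch(rule$dist,
    uniform = stats::runif(1, rule$min, rule$max),
    normal  = {
      x <- stats::rnorm(1, rule$mean, rule$sd)
      min(max(x, rule$mean - 4 * rule$sd), rule$mean + 4 * rule$sd)
    },
    stop(sprintf("unknown distribution '%s'", rule$dist), call. = FALSE)
  )
}

#' Motor-unit action potential
#'
#' The MUAP of one motor unit at the differential pair: the sample-wise sum
#' of the SFAPs of all its fibres. All fibres of a unit share type, membrane
#' parameters, half-length and pennation, so the sum collapses to one time
#' kernel weighted by the fibre-summed volume-conductor weights; the result
#' is identical to brute-force per-fibre [sfap()] summation.
#'
#' @param fiber_x,fiber_y Fibre NMJ cross-section positions, mm.
#' @param fiber_z Fibre NMJ positions along the muscle axis, mm (the
#'   innervation-zone scatter); scalar 0 recycles to all fibres.
#' @param params [membrane_params()] shared by the unit's fibres.
#' @param electrodes An [electrode_pair()].
#' @param fs Sampling rate, Hz.
#' @param half_length,pennation Fibre geometry shared by the unit.
#' @param dz_mm Axial discretisation step, mm.
#' @param clip_radius Muscle cylinder radius for fascia clipping, mm.
#' @param source_model `"progressive"` (charge-conserving) or `"truncated"`;
#'   see [sfap()].
#' @param contact_halfbar_mm Half-length of each contact bar, mm. Physical
#'   differential contacts are bars transverse to the fibre direction;
#'   setting a positive half-length averages the kernel over the bar, which
#'   spatially smooths the near field of the closest fibres. Default 0
#'   (point contacts, matching [sfap()]); the averaging changes composite
#'   features by well under 1% at the default geometry.
#' @return `sfap_waveform` tibble (the unit's template waveform).
#' @export
muap <- function(fiber_x, fiber_y, params, electrodes, fs = 1000,
                 half_length = 45, pennation = 20, dz_mm = 0.5,
                 clip_radius = Inf, fiber_z = 0,
                 source_model = c("progressive", "truncated"),
                 contact_halfbar_mm = 0) {
  source_model <- match.arg(source_model)
  stopifnot(length(fiber_x) >= 1L, length(fiber_x) == length(fiber_y),
            inherits(params, "membrane_params"),
            inherits(electrodes, "electrode_pair"))
  fiber_z <- rep_len(fiber_z, length(fiber_x))
  v <- params$velocity
  duration_ms <- half_length / v + source_support_ms(params)
  n <- max(2L, round(duration_ms * fs / 1000))
  t_ms <- (seq_len(n) - 1L) / fs * 1000

  n_half <- max(1L, ceiling(half_length / dz_mm))
  du <- half_length / n_half
  u <- (seq_len(n_half) - 0.5) * du
  u_all <- c(-rev(u), u)                     # axial positions, fibre-local
  delay <- abs(u_all) / v

  th <- pennation * pi / 180
  sr <- params$sigma_i / params$sigma_e

  # transverse quadrature nodes over each contact bar (midpoint rule)
  bar_dx <- if (contact_halfbar_mm > 0) {
    contact_halfbar_mm * (2 * (1:4) - 5) / 4  # 4 midpoints over [-h, h]
  } else 0

  # fibre-summed kernel weights at each axial point, one contact at a time,
  # averaged over the bar nodes
  contact_weights_at <- function(contact) {
    ex <- contact[1] - fiber_x                # per fibre
    ey <- contact[2] - fiber_y
    ez <- contact[3] - fiber_z
    ey_loc <- cos(th) * ey + sin(th) * ez     # electrode in fibre-local frame
    ez_loc <- -sin(th) * ey + cos(th) * ez    # (+z fibre half tilts deep)
    dz2 <- outer(u_all, ez_loc, "-")^2        # axial gap, points x fibres
    q <- matrix(sr * (ex^2 + ey_loc^2), nrow = length(u_all),
                ncol = length(ex), byrow = TRUE)
    w <- if (source_model == "truncated") {
      1 / (4 * pi * params$sigma_e * sqrt(dz2 + q))
    } else {
      (2 * dz2 - q) / (4 * pi * params$sigma_e * (dz2 + q)^2.5)
    }
    if (is.finite(clip_radius)) {
      gy <- outer(-u_all * sin(th), fiber_y, "+") # global y of each point
      gx2 <- matrix(fiber_x^2, nrow = length(u_all), ncol = length(ex),
                    byrow = TRUE)
      w[gx2 + gy^2 > clip_radius^2] <- 0
    }
    rowSums(w)
  }
  contact_weights <- function(contact) {
    ws <- purrr::map(bar_dx, function(dx) {
      contact_weights_at(contact + c(dx, 0, 0))
    })
    Reduce(`+`, ws) / length(ws)
  }
  w_diff <- contact_weights(electrodes$contact0) -
    contact_weights(electrodes$contact1)

  timefun <- if (source_model == "truncated") transmembrane_current
             else intracellular_pulse
  tt <- outer(t_ms, delay, "-")
  im <- matrix(0, nrow = n, ncol = length(delay))
  pos <- tt >= 0
  im[pos] <- timefun(tt[pos], params)
  new_sfap(t_ms, as.numeric(im %*% w_diff) * du, fs = fs, pennation = pennation)
}

muap_for_unit <- function(pool, i, electrodes, fs, dz_mm, clip = TRUE,
                          source_model = "progressive") {
  p <- attr(pool, "params")
  memb <- attr(pool, "membrane")[[pool$type[i]]]
  muap(pool$fiber_x[[i]], pool$fiber_y[[i]], memb, electrodes, fs = fs,
       half_length = p$half_length, pennation = p$pennation, dz_mm = dz_mm,
       clip_radius = if (clip) p$muscle_radius else Inf,
       fiber_z = pool$fiber_z[[i]], source_model = source_model)
}

#' Simulate a composite surface EMG signal
#'
#' Builds the pool, draws spike trains at the commanded drive, computes one
#' MUAP template per motor unit and superposes the templates linearly at the
#' firing times (nearest-sample placement). Deterministic given `seed`.
#'
#' @param config A [simulation_config()].
#' @param mvc Drive level, %MVC.
#' @param seed Integer RNG seed.
#' @param pool Optional pre-built pool (skips the build; its parameters
#'   override `config$pool`).
#' @return A tibble of class `semg_signal` with columns `time_ms`, `voltage`
#'   and attributes `fs`, `mvc`, `pennation`, `seed`.
#' @examples
#' cfg <- simulation_config(pool_params(n_units = 30), duration_ms = 3000)
#' sig <- simulate_semg(cfg, mvc = 50, seed = 7)
#' semg_features(sig, fs = 1000)
#' @export
simulate_semg <- function(config, mvc, seed = 1L, pool = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (mvc < 0 || mvc > 100) stop("mvc must lie in [0, 100]", call. = FALSE)
  if (is.null(pool)) pool <- build_pool(config$pool, seed = seed)
  pp <- attr(pool, "params")
  n_out <- round(config$duration_ms * config$fs / 1000)
  if (mvc > 0) {
    # shortest template must fit within the signal
    min_support <- pp$half_length / attr(pool, "membrane")$fast$velocity
    if (config$duration_ms < min_support) {
      stop("duration shorter than one MUAP support", call. = FALSE)
    }
  }
  sig <- numeric(n_out)
  trains <- generate_spike_trains(pool, drive = mvc,
                                  duration_ms = config$duration_ms,
                                  isi_cv = config$isi_cv, seed = seed + 1L)
  active <- which(lengths(trains$firing_times) > 0)
  for (i in active) {
    tmpl <- muap_for_unit(pool, i, config$electrodes, config$fs, config$dz_mm,
                          source_model = config$source_model %||% "progressive")$voltage
    idx0 <- round(trains$firing_times[[i]] * config$fs / 1000) + 1L
    for (s in idx0) {
      j <- s:min(n_out, s + length(tmpl) - 1L)
      if (length(j) > 0 && j[1] <= n_out) {
        sig[j] <- sig[j] + tmpl[seq_along(j)]
      }
    }
  }
  out <- tibble::tibble(time_ms = (seq_len(n_out) - 1L) / config$fs * 1000,
                        voltage = sig)
  class(out) <- c("semg_signal", class(out))
  attr(out, "fs") <- config$fs
  attr(out, "mvc") <- mvc
  attr(out, "pennation") <- pp$pennation
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Repeated-simulation batch with parameter randomisation
#'
#' Runs `config$n_repeats` independent repetitions. Each repetition redraws
#' the physiological parameters from `config$parameter_ranges` (uniform over
#' min-max ranges, Gaussian for mean +/- SD entries, the minimum firing rate
#' kept strictly below the peak), then simulates every level in
#' `config$mvc_levels`. Per-repeat seeds are derived from the master seed
#' and recorded in the output.
#'
#' @param config A [simulation_config()].
#' @param seed Master integer seed.
#' @return A tibble with one row per (repeat, mvc): columns `repeat_id`,
#'   `mvc`, `seed`, the drawn parameters, and list-column `signal`
#'   (`semg_signal` tibbles).
#' @export
semg_batch <- function(config, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, config$n_repeats)
  purrr::map_dfr(seq_len(config$n_repeats), function(r) {
    set.seed(rep_seeds[r])
    draws <- purrr::map(config$parameter_ranges, draw_parameter)
    if (!is.null(draws$mfr) && !is.null(draws$pfr)) {
      # the published MFR and PFR ranges overlap; redraw until the rate law is valid
      while (draws$pfr <= draws$mfr + 1) {
        draws$mfr <- draw_parameter(config$parameter_ranges$mfr)
        draws$pfr <- draw_parameter(config$parameter_ranges$pfr)
      }
    }
    pp <- config$pool
    pool_r <- pool_params(
      n_units = round(draws$n_units %||% pp$n_units),
      muscle_radius = draws$muscle_radius %||% pp$muscle_radius,
      mfr = draws$mfr %||% pp$mfr, pfr = draws$pfr %||% pp$pfr,
      rr = pp$rr, slow_fraction = pp$slow_fraction,
      fiber_density = pp$fiber_density,
      half_length = draws$half_length %||% pp$half_length,
      pennation = if (config$redraw_pennation)
        min(max(draws$pennation %||% pp$pennation, 0), 30) else pp$pennation,
      cutaneous_mm = pp$cutaneous_mm,
      iz_spread_mm = pp$iz_spread_mm
    )
    memb_s <- membrane_params_slow(velocity = draws$velocity_slow %||% 3.9)
    memb_f <- membrane_params_fast(velocity = draws$velocity_fast %||% 4.9)
    electrodes <- electrode_pair_default(pool_r$muscle_radius + pool_r$cutaneous_mm)
    cfg_r <- simulation_config(
      pool = pool_r, electrodes = electrodes, fs = config$fs,
      duration_ms = config$duration_ms, mvc_levels = config$mvc_levels,
      n_repeats = 1L, parameter_ranges = config$parameter_ranges,
      isi_cv = config$isi_cv, dz_mm = config$dz_mm
    )
    pool_built <- build_pool(pool_r, membrane_slow = memb_s,
                             membrane_fast = memb_f, seed = rep_seeds[r])
    purrr::map_dfr(config$mvc_levels, function(lv) {
      sig <- simulate_semg(cfg_r, mvc = lv, seed = rep_seeds[r], pool = pool_built)
      tibble::tibble(
        repeat_id = r, mvc = lv, seed = rep_seeds[r],
        !!!draws[names(draws) != "n_units"],
        n_units = pool_r$n_units,
        signal = list(sig)
      )
    })
  })
}

#' Pennation-angle sweep
#'
#' For each angle: the reference single-fibre SFAP (one fibre under a 3 mm
#' cutaneous layer by default), its shape correlation against the
#' parallel-fibre (0 degree) SFAP, and the RMS, median frequency and Higuchi
#' fractal dimension of a composite signal simulated with every fibre at
#' that angle.
#'
#' @param config A [simulation_config()]; its pool is reused at each angle
#'   with only the pennation changed.
#' @param angles Pennation angles, degrees, each in [0, 30]; angle 0 is
#'   added if absent (it is the correlation reference).
#' @param mvc Drive for the composite feature signal, %MVC.
#' @param seed Integer seed (shared across angles so only the angle varies).
#' @param fiber_depth_mm Depth of the reference fibre's innervation point
#'   below the electrode plane, mm: intramuscular depth plus the cutaneous
#'   layer. The default 13 mm is a mid-depth fibre (10 mm under the fascia
#'   of a 20 mm radius muscle) under the 3 mm cutaneous layer.
#' @param sfap_fs Sampling rate for the reference SFAP, Hz (high by default
#'   so shape correlations are resolved).
#' @return A tibble of class `pennation_sweep` with columns `angle`,
#'   `correlation`, `rms`, `mdf`, `fd` and list-column `sfap`.
#' @export
pennation_sweep <- function(config = simulation_config(), angles = c(0, 5, 10, 20),
                            mvc = 50, seed = 1L, fiber_depth_mm = 13,
                            sfap_fs = 10000) {
  if (any(angles < 0 | angles > 30)) {
    stop("angles must lie in [0, 30] degrees", call. = FALSE)
  }
  angles <- sort(unique(c(0, angles)))
  ref <- reference_sfap(0, config, fiber_depth_mm, sfap_fs)
  purrr::map_dfr(angles, function(a) {
    w <- reference_sfap(a, config, fiber_depth_mm, sfap_fs)
    pool_a <- utils::modifyList(unclass(config$pool), list(pennation = a))
    pool_a <- do.call(pool_params, pool_a)
    cfg_a <- simulation_config(
      pool = pool_a, electrodes = config$electrodes, fs = config$fs,
      duration_ms = config$duration_ms, mvc_levels = mvc, n_repeats = 1L,
      parameter_ranges = config$parameter_ranges, isi_cv = config$isi_cv,
      dz_mm = config$dz_mm, source_model = config$source_model %||% "progressive"
    )
    sig <- simulate_semg(cfg_a, mvc = mvc, seed = seed)
    fe <- semg_features(sig, fs = config$fs)
    tibble::tibble(angle = a,
                   correlation = sfap_shape_correlation(ref, w),
                   rms = fe$rms, mdf = fe$mdf, fd = fe$fd,
                   sfap = list(w))
  }) -> out
  class(out) <- c("pennation_sweep", class(out))
  out
}

# Reference fibre for shape studies: NMJ under `depth` mm of tissue, the
# differential pair straight above it, no fascia clipping (single-fibre
# geometry; Table-1 slow-fibre membrane constants).
reference_sfap <- function(angle, config, depth_mm, fs) {
  fib <- emg_fiber(origin = c(0, 0, 0), half_length = config$pool$half_length,
                   pennation = angle, params = membrane_params_slow())
  el <- electrode_pair_default(depth_mm,
                               config$electrodes$inter_electrode_distance)
  sfap(fib, el, fs = fs, dz_mm = config$dz_mm,
       source_model = config$source_model %||% "progressive")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
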