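#' Differential electrode pair
#'
#' Two point contacts above the skin. The coordinate convention, shared by
#' the whole package, places the neuromuscular junction of the reference
#' fibre at the origin, `z` along the muscle's line of traction, `y` toward
#' the skin and `x` transverse. The skin surface sits at
#' `y = muscle_radius + cutaneous_mm`, so a contact must not lie below it.
#'
#' @param contact0,contact1 Numeric length-3 positions (x, y, z) in mm.
#' @param skin_y Height of the skin plane (mm); both contacts must satisfy
#'   `y >= skin_y`. Default `NULL` skips the check (single-fibre studies
#'   place the skin wherever the cutaneous layer ends).
#' @return An object of class `electrode_pair`.
#' @examples
#' electrode_pair_default()  # 10 mm inter-electrode distance, 3 mm standoff
#' @export
electrode_pair <- function(contact0, contact1, skin_y = NULL) {
  stopifnot(length(contact0) == 3L, length(contact1) == 3L,
            is.numeric(contact0), is.numeric(contact1))
  ied <- sqrt(sum((contact1 - contact0)^2))
  if (ied < 1e-9) {
    stop("the two contacts must be distinct", call. = FALSE)
  }
  if (!is.null(skin_y) && (contact0[2] < skin_y - 1e-9 || contact1[2] < skin_y - 1e-9)) {
    stop("electrode contacts must lie at or above the skin surface plane",
         call. = FALSE)
  }
  structure(
    list(contact0 = as.numeric(contact0), contact1 = as.numeric(contact1),
         inter_electrode_distance = ied),
    class = "electrode_pair"
  )
}

#' @rdname electrode_pair
#' @param depth_mm Height of the contacts above the reference fibre (mm);
#'   fibre depth plus the cutaneous layer.
#' @param ied_mm Inter-electrode distance along z (mm).
#' @param z_center_mm Position of the pair's midpoint along the fibre axis,
#'   mm from the innervation zone. A pair centred exactly over the
#'   innervation zone (`z_center_mm = 0`) sees mirror-image potentials at
#'   the two contacts and its differential signal cancels identically, so
#'   the default offsets the pair toward the tendon, the conventional
#'   bipolar placement.
#' @export
electrode_pair_default <- function(depth_mm = 3, ied_mm = 10, z_center_mm = 10) {
  electrode_pair(c(0, depth_mm, z_center_mm - ied_mm / 2),
                 c(0, depth_mm, z_center_mm + ied_mm / 2))
}

#' @export
print.electrode_pair <- function(x, ...) {
  cat("<electrode_pair>\n")
  cat(sprintf("  contact0: (%g, %g, %g) mm\n", x$contact0[1], x$contact0[2], x$contact0[3]))
  cat(sprintf("  contact1: (%g, %g, %g) mm\n", x$contact1[1], x$contact1[2], x$contact1[3]))
  cat(sprintf("  inter-electrode distance: %g mm\n", x$inter_electrode_distance))
  invisible(x)
}

#' Single muscle fibre
#'
#' A fibre is described in its own frame: the neuromuscular junction (NMJ,
#' the innervation point at mid-fibre) sits at `origin`, and the fibre runs
#' `half_length` mm in both directions along an axis tilted by the pennation
#' angle `theta` (degrees) away from z, within the y-z plane.
#'
#' @param origin NMJ position (x, y, z) in mm, global frame.
#' @param half_length Half the fibre length, mm.
#' @param pennation Pennation angle, degrees; `0 <= theta <= pennation_cap`.
#' @param params A [membrane_params()] object.
#' @param type_label `"slow"` or `"fast"`.
#' @param pennation_cap Upper bound for the angle (degrees, default 30).
#' @return Object of class `emg_fiber`.
#' @export
emg_fiber <- function(origin = c(0, 0, 0), half_length = 45, pennation = 0,
                      params = membrane_params(), type_label = "slow",
                      pennation_cap = 30) {
  stopifnot(length(origin) == 3L, inherits(params, "membrane_params"))
  if (half_length <= 0) stop("half_length must be positive", call. = FALSE)
  if (pennation < 0 || pennation > pennation_cap) {
    stop(sprintf("pennation must lie in [0, %g] degrees", pennation_cap),
         call. = FALSE)
  }
  structure(
    list(origin = as.numeric(origin), half_length = half_length,
         pennation = pennation, params = params,
         type_label = match.arg(type_label, c("slow", "fast"))),
    class = "emg_fiber"
  )
}

#' Volume-conductor weighting, parallel fibre
#'
#' Point-source weighting of an anisotropic unbounded medium for a fibre
#' aligned with z:
#' \deqn{f = \frac{1}{4\pi\sigma_e\sqrt{(z-z')^2 +
#'   \sigma\,[(x-x')^2 + (y-y')^2]}}}
#' where \eqn{\sigma} is the longitudinal/transverse anisotropy ratio
#' (default \eqn{\sigma_i/\sigma_e}).
#'
#' @param source Numeric length-3 (or n x 3 matrix) source position(s), mm.
#' @param electrode Numeric length-3 electrode position, mm.
#' @param sigma_e Extracellular conductivity, S/m.
#' @param sigma_ratio Anisotropy scalar multiplying the transverse gaps.
#' @return Weighting(s) in 1/mm (times 1/(S/m)); strictly positive.
#' @export
weight_parallel <- function(source, electrode, sigma_e = 0.2,
                            sigma_ratio = 1.01 / 0.2) {
  src <- to_matrix3(source)
  dx <- src[, 1] - electrode[1]
  dy <- src[, 2] - electrode[2]
  dz <- src[, 3] - electrode[3]
  r <- sqrt(dz^2 + sigma_ratio * (dx^2 + dy^2))
  if (any(r < 1e-12)) {
    stop("source and electrode coincide: point-source weighting is singular",
         call. = FALSE)
  }
  1 / (4 * pi * sigma_e * r)
}

#' Volume-conductor weighting, pennate fibre
#'
#' The parallel kernel expressed in the fibre-local frame of a fibre tilted
#' by `theta` degrees about the x-axis: source coordinates are fibre-local
#' (z along the fibre axis), and the electrode, given in the global frame,
#' is rotated into that frame. At `theta = 0` this reduces exactly to
#' [weight_parallel()]. Orientation convention (package-wide): positive
#' `theta` tilts the fibre's +z half away from the skin, the descending
#' course of a Tibialis Anterior fascicle from the superficial toward the
#' deep aponeurosis; the electrode pair sits on the +z side.
#'
#' @param source Fibre-local source position(s) (x, y, z), mm.
#' @param electrode Global electrode position, mm (relative to the NMJ).
#' @param theta Pennation angle, degrees in [0, 90].
#' @inheritParams weight_parallel
#' @return Weighting(s) in 1/mm; strictly positive.
#' @export
weight_pennate <- function(source, electrode, theta, sigma_e = 0.2,
                           sigma_ratio = 1.01 / 0.2) {
  if (theta < 0 || theta > 90) {
    stop("theta must lie in [0, 90] degrees", call. = FALSE)
  }
  weight_parallel(source, rotate_about_x(electrode, theta),
                  sigma_e = sigma_e, sigma_ratio = sigma_ratio)
}

# Rigid rotation about the x-axis by theta degrees (y toward skin, z along
# the line of traction): positive theta tilts the +z axis toward +y.
rotate_about_x <- function(v, theta) {
  th <- theta * pi / 180
  m <- to_matrix3(v)
  out <- cbind(m[, 1],
               cos(th) * m[, 2] + sin(th) * m[, 3],
               -sin(th) * m[, 2] + cos(th) * m[, 3])
  if (length(v) == 3L && is.null(dim(v))) as.numeric(out) else out
}

to_matrix3 <- function(v) {
  if (is.matrix(v)) {
    stopifnot(ncol(v) == 3L)
    v
  } else {
    stopifnot(length(v) == 3L)
    matrix(v, ncol = 3L)
  }
}

#' Single-fibre action potential at a differential electrode pair
#'
#' Synthesises the differential SFAP `phi0(t) - phi1(t)` by discretising the
#' fibre into axial steps of `dz_mm`, propagating two excitation waves from
#' the innervation zone toward the two fibre ends at the fibre's conduction
#' velocity, weighting every source point by the pennate volume-conductor
#' kernel, and summing (midpoint rule). Sources whose global position leaves
#' the muscle cylinder of radius `clip_radius` are dropped: a pennate fibre
#' terminates at the fascia.
#'
#' Two source formulations are available. `"progressive"` (default) applies
#' the transmembrane current as the distributional second axial derivative
#' of the intracellular potential profile, computed by moving both
#' derivatives onto the kernel (integration by parts): generation at the end
#' plate and extinction at the fibre ends are then charge-conserving, as in
#' the standard line-source models of this field. `"truncated"` switches
#' each source point's current waveform on abruptly and cuts it at the fibre
#' ends without compensation; the two forms agree for a fibre much longer
#' than the source, and differ by the (unphysical) birth and end transients
#' otherwise.
#'
#' @param fiber An [emg_fiber()].
#' @param electrodes An [electrode_pair()].
#' @param fs Sampling rate, Hz (>= 1000).
#' @param duration_ms Waveform length, ms. Must cover the slowest travel
#'   time plus the source support; `NULL` picks that minimum.
#' @param dz_mm Axial discretisation step, mm.
#' @param sigma_ratio Anisotropy ratio passed to the kernel;
#'   default \eqn{\sigma_i/\sigma_e} from the fibre's membrane parameters.
#' @param clip_radius Radius of the muscle cylinder used to clip pennate
#'   fibres, mm; `Inf` disables clipping (single-fibre studies).
#' @param source_model `"progressive"` (charge-conserving, default) or
#'   `"truncated"`; see Details.
#' @return A tibble of class `sfap_waveform` with columns `time_ms` and
#'   `voltage`; sampling metadata in attributes `fs`, `pennation`.
#' @examples
#' w <- sfap(emg_fiber(pennation = 10), electrode_pair_default())
#' head(w)
#' @export
sfap <- function(fiber, electrodes, fs = 1000, duration_ms = NULL,
                 dz_mm = 0.5, sigma_ratio = NULL, clip_radius = Inf,
                 source_model = c("progressive", "truncated")) {
  source_model <- match.arg(source_model)
  stopifnot(inherits(fiber, "emg_fiber"), inherits(electrodes, "electrode_pair"))
  if (fs < 1000) stop("fs must be at least 1000 Hz", call. = FALSE)
  p <- fiber$params
  if (is.null(sigma_ratio)) sigma_ratio <- p$sigma_i / p$sigma_e
  v <- p$velocity # m/s == mm/ms
  need_ms <- fiber$half_length / v + source_support_ms(p)
  if (is.null(duration_ms)) duration_ms <- need_ms
  if (duration_ms < need_ms) {
    stop(sprintf("duration %.1f ms truncates the SFAP: need >= %.1f ms (travel + source support)",
                 duration_ms, need_ms), call. = FALSE)
  }
  n <- max(2L, round(duration_ms * fs / 1000))
  t_ms <- (seq_len(n) - 1L) / fs * 1000

  src <- fiber_sources(fiber, dz_mm, clip_radius)
  if (nrow(src$local) == 0L) {
    stop("fibre clipped entirely outside the muscle cylinder", call. = FALSE)
  }
  phi <- function(contact) {
    e_loc <- rotate_about_x(contact - fiber$origin, fiber$pennation)
    if (source_model == "truncated") {
      w <- weight_parallel(src$local, e_loc,
                           sigma_e = p$sigma_e, sigma_ratio = sigma_ratio)
      timefun <- transmembrane_current
    } else {
      w <- kernel_d2z(src$local, e_loc,
                      sigma_e = p$sigma_e, sigma_ratio = sigma_ratio)
      timefun <- intracellular_pulse
    }
    # one source evaluation per (time, source point); delays in ms
    tt <- outer(t_ms, src$delay_ms, "-")
    im <- matrix(0, nrow = n, ncol = length(w))
    pos <- tt >= 0
    im[pos] <- timefun(tt[pos], p)
    as.numeric(im %*% w) * dz_mm
  }
  volt <- phi(electrodes$contact0) - phi(electrodes$contact1)
  new_sfap(t_ms, volt, fs = fs, pennation = fiber$pennation)
}

# Second derivative of the parallel weighting kernel along the fibre-local
# z axis: d^2/dz^2 (4 pi sigma_e sqrt(dz^2 + q))^-1 with
# q = sigma * (dx^2 + dy^2). Used by the progressive source model.
kernel_d2z <- function(source, electrode, sigma_e, sigma_ratio) {
  src <- to_matrix3(source)
  dx <- src[, 1] - electrode[1]
  dy <- src[, 2] - electrode[2]
  dz <- src[, 3] - electrode[3]
  q <- sigma_ratio * (dx^2 + dy^2)
  r2 <- dz^2 + q
  if (any(r2 < 1e-12)) {
    stop("source and electrode coincide: point-source weighting is singular",
         call. = FALSE)
  }
  (2 * dz^2 - q) / (4 * pi * sigma_e * r2^2.5)
}

# Midpoint discretisation of both half-fibres in the fibre-local frame,
# with travel delays and global-frame clipping against the muscle cylinder
# x^2 + y^2 <= clip_radius^2 (axis along z).
fiber_sources <- function(fiber, dz_mm, clip_radius = Inf) {
  n_half <- max(1L, ceiling(fiber$half_length / dz_mm))
  u <- (seq_len(n_half) - 0.5) * (fiber$half_length / n_half)
  u_all <- c(-rev(u), u)
  local <- cbind(0, 0, u_all)
  keep <- rep(TRUE, length(u_all))
  if (is.finite(clip_radius)) {
    glob <- rotate_about_x(local, -fiber$pennation)
    gx <- glob[, 1] + fiber$origin[1]
    gy <- glob[, 2] + fiber$origin[2]
    keep <- gx^2 + gy^2 <= clip_radius^2
  }
  list(local = local[keep, , drop = FALSE],
       delay_ms = abs(u_all[keep]) / fiber$params$velocity)
}

new_sfap <- function(time_ms, voltage, fs, pennation = NA_real_) {
  out <- tibble::tibble(time_ms = time_ms, voltage = voltage)
  class(out) <- c("sfap_waveform", class(out))
  attr(out, "fs") <- fs
  attr(out, "pennation") <- pennation
  out
}

#' Shape correlation of two sampled waveforms
#'
#' Pearson correlation of two equal-length waveforms; because the Pearson
#' coefficient is invariant to positive affine rescaling, this compares
#' shape, not amplitude.
#'
#' @param w1,w2 `sfap_waveform` tibbles (or anything with a `voltage`
#'   column), or plain numeric vectors; equal length, nonzero variance.
#' @return Correlation coefficient in [-1, 1].
#' @export
sfap_shape_correlation <- function(w1, w2) {
  x <- waveform_samples(w1)
  y <- waveform_samples(w2)
  if (length(x) != length(y)) {
    stop("waveforms must have equal length", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a zero-variance waveform", call. = FALSE)
  }
  stats::cor(x, y)
}

waveform_samples <- function(w) {
  if (is.numeric(w)) return(as.numeric(w))
  if (is.data.frame(w) && "voltage" %in% names(w)) return(w$voltage)
  stop("expected a numeric vector or a waveform with a 'voltage' column",
       call. = FALSE)
}
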