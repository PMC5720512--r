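#' Membrane source parameters
#'
#' Bundle of constants for the Rosenfalck intracellular action potential and
#' the transmembrane current it implies. Absolute voltages are in
#' "Rosenfalck units": the classical fit `A = 96`, `B = 90`, `lambda = 1`
#' reproduces the canonical waveform shape, but the absolute amplitude
#' scale of a simulated surface EMG is arbitrary, so only relative amplitude
#' comparisons are meaningful.
#'
#' @param A Action-potential amplitude scale (mV, against \eqn{(\lambda z)^3}).
#' @param B Resting membrane potential magnitude (mV).
#' @param lambda Spatial scaling factor (1/mm).
#' @param sigma_i Intracellular conductivity (S/m).
#' @param sigma_e Extracellular conductivity (S/m).
#' @param diameter Fibre diameter (micrometres).
#' @param velocity Conduction velocity (m/s, numerically equal to mm/ms).
#' @param velocity_window Allowed physiological window for `velocity` (m/s).
#'
#' @return An object of class `membrane_params` (named list).
#' @examples
#' membrane_params()                  # slow-fibre defaults
#' membrane_params_fast()             # fast-fibre diameter and velocity
#' @export
membrane_params <- function(A = 96, B = 90, lambda = 1,
                            sigma_i = 1.01, sigma_e = 0.2,
                            diameter = 35.46, velocity = 3.9,
                            velocity_window = c(1, 10)) {
  stopifnot(
    is.numeric(A), is.numeric(B), is.numeric(lambda),
    length(velocity_window) == 2L
  )
  vals <- c(A = A, B = B, lambda = lambda, sigma_i = sigma_i,
            sigma_e = sigma_e, diameter = diameter, velocity = velocity)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all membrane parameters must be finite and strictly positive",
         call. = FALSE)
  }
  if (velocity < velocity_window[1] || velocity > velocity_window[2]) {
    stop(sprintf("conduction velocity %.3g m/s outside physiological window [%g, %g]",
                 velocity, velocity_window[1], velocity_window[2]),
         call. = FALSE)
  }
  structure(
    list(A = A, B = B, lambda = lambda, sigma_i = sigma_i, sigma_e = sigma_e,
         diameter = diameter, velocity = velocity,
         velocity_window = velocity_window),
    class = "membrane_params"
  )
}

#' @rdname membrane_params
#' @param ... Overrides passed on to [membrane_params()].
#' @export
membrane_params_slow <- function(...) {
  args <- utils::modifyList(list(diameter = 35.46, velocity = 3.9), list(...))
  do.call(membrane_params, args)
}

#' @rdname membrane_params
#' @export
membrane_params_fast <- function(...) {
  args <- utils::modifyList(list(diameter = 50.68, velocity = 4.9), list(...))
  do.call(membrane_params, args)
}

#' @export
print.membrane_params <- function(x, ...) {
  cat("<membrane_params>\n")
  cat(sprintf("  A = %g mV, B = %g mV, lambda = %g /mm\n", x$A, x$B, x$lambda))
  cat(sprintf("  sigma_i = %g S/m, sigma_e = %g S/m\n", x$sigma_i, x$sigma_e))
  cat(sprintf("  diameter = %g um, velocity = %g m/s\n", x$diameter, x$velocity))
  invisible(x)
}

#' Rosenfalck intracellular action potential
#'
#' \deqn{V_m(z) = A (\lambda z)^3 e^{-\lambda z} - B}
#' defined on the travelled half-line `z >= 0`; tends to `-B` as `z`
#' grows (the membrane returns to rest).
#'
#' @param z Axial distance(s) behind the excitation front, mm; `z >= 0`.
#' @param p A [membrane_params()] object.
#' @return Membrane potential in mV, same length as `z`.
#' @examples
#' p <- membrane_params()
#' rosenfalck_vm(0, p)        # -B: resting potential at the front
#' rosenfalck_vm(3 / p$lambda, p)  # depolarisation peak at lambda*z = 3
#' @export
rosenfalck_vm <- function(z, p) {
  stopifnot(inherits(p, "membrane_params"))
  if (any(z < 0)) {
    stop("z must be non-negative: the intracellular waveform is defined on the travelled half-line",
         call. = FALSE)
  }
  u <- p$lambda * z
  p$A * u^3 * exp(-u) - p$B
}

#' Source scale constant
#'
#' The lumped scale \eqn{C = d^2 \sigma_i \pi / (4 v^2)} converting the second
#' spatial derivative of the intracellular potential into a line current
#' source: quadratic in fibre diameter, inverse-quadratic in conduction
#' velocity. Exposed as its own function so the scaling convention can be
#' overridden wholesale.
#'
#' @inheritParams rosenfalck_vm
#' @return Positive scalar.
#' @export
source_constant <- function(p) {
  stopifnot(inherits(p, "membrane_params"))
  p$diameter^2 * p$sigma_i * pi / (4 * p$velocity^2)
}

#' Transmembrane current waveform
#'
#' The current source driving the volume conductor, i.e. the second spatial
#' derivative of [rosenfalck_vm()] evaluated along the propagating wave
#' `z = v t` and scaled by [source_constant()] and `v^2`:
#' \deqn{I_m(t) = C A \lambda^2 (\lambda v t)\,(6 - 6 \lambda v t +
#'   \lambda^2 (v t)^2)\, e^{-\lambda v t}.}
#' The waveform is tri-phasic (sign pattern + - +, zero crossings of the
#' quadratic at \eqn{\lambda v t = 3 \pm \sqrt 3}) and integrates to zero
#' over its full support (charge balance).
#'
#' @param t Time(s) since the excitation passed the point, ms; `t >= 0`.
#' @inheritParams rosenfalck_vm
#' @return Current density in source units, same length as `t`.
#' @examples
#' p <- membrane_params()
#' transmembrane_current(0, p)  # 0: the leading factor vanishes
#' @export
transmembrane_current <- function(t, p) {
  stopifnot(inherits(p, "membrane_params"))
  if (any(t < 0)) {
    stop("t must be non-negative", call. = FALSE)
  }
  u <- p$lambda * p$velocity * t
  source_constant(p) * p$A * p$lambda^2 * u * (6 - 6 * u + u^2) * exp(-u)
}

# Support of the current source, ms: beyond lambda*v*t = 40 the waveform is
# < 1e-12 of its peak, so templates are truncated there.
source_support_ms <- function(p) 40 / (p$lambda * p$velocity)

# Travelling intracellular pulse above rest, scaled like the printed current
# source: C * A * (lambda*v*t)^3 * exp(-lambda*v*t) for t >= 0. Used by the
# charge-conserving ("progressive") synthesis, where the volume-conductor
# kernel is differentiated twice along the fibre instead of the source:
# integral K * Im == integral K'' * this pulse for an infinite fibre, and on
# a finite fibre the second form conserves charge through generation at the
# end plate and extinction at the fibre ends.
intracellular_pulse <- function(t, p) {
  u <- p$lambda * p$velocity * t
  source_constant(p) * p$A * u^3 * exp(-u)
}
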