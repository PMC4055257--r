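## RF pulse envelopes and the flip-angle-modulation (phase-encode) schedule.

#' Gyromagnetic ratio of the proton
#'
#' `2.675e8` rad s^-1 T^-1, the package-wide default for all flip-angle and
#' Bloch computations.
#' @export
GAMMA_1H <- 2.675e8

new_pulse <- function(shape, duration, n_samples, env_fun) {
  stopifnot(duration > 0, n_samples >= 2)
  times <- seq(0, duration, length.out = n_samples)
  # every shape below is constructed with analytic peak 1 at the center
  structure(list(shape = shape, duration = duration,
                 n_samples = as.integer(n_samples),
                 times = times, envelope = env_fun(times),
                 env_fun = env_fun),
            class = "rf_pulse")
}

#' @export
print.rf_pulse <- function(x, ...) {
  cat(sprintf("<rf_pulse> %s, %.3g ms, %d samples\n",
              x$shape, 1e3 * x$duration, x$n_samples))
  invisible(x)
}

#' Gaussian RF pulse envelope
#'
#' Unit-peak Gaussian centered at `duration/2` with full width at half maximum
#' `fwhm_fraction * duration`.
#'
#' @param duration Pulse length in seconds.
#' @param n_samples Number of envelope samples (>= 2).
#' @param fwhm_fraction FWHM as a fraction of the duration, in (0, 1].
#' @return An `rf_pulse` object.
#' @examples
#' p <- gauss_pulse(5e-3, 20)
#' @export
gauss_pulse <- function(duration, n_samples = 256L, fwhm_fraction = 0.5) {
  stopifnot(fwhm_fraction > 0, fwhm_fraction <= 1)
  fwhm <- fwhm_fraction * duration
  new_pulse("gauss", duration, n_samples,
            function(t) exp(-4 * log(2) * ((t - duration / 2) / fwhm)^2))
}

#' Truncated sinc RF pulse envelope
#'
#' Pure (unapodized) `sin(pi x)/(pi x)` envelope whose main-lobe frequency
#' `tbw / duration` sets the bandwidth-time product.
#'
#' @inheritParams gauss_pulse
#' @param tbw Target bandwidth-time product (> 0).
#' @return An `rf_pulse` object.
#' @export
sinc_pulse <- function(duration, n_samples = 256L, tbw = 10.5) {
  stopifnot(tbw > 0)
  f0 <- tbw / duration
  new_pulse("sinc", duration, n_samples, function(t) {
    x <- pi * f0 * (t - duration / 2)
    ifelse(abs(x) < 1e-12, 1, sin(x) / x)
  })
}

#' Hyperbolic-secant RF pulse envelope
#'
#' Amplitude-only `sech(beta (t - duration/2))` envelope; `beta` is set from
#' the analytic spectrum of sech (Fourier transform again a sech) so that the
#' spectral FWHM times the duration matches `tbw`.
#'
#' @inheritParams sinc_pulse
#' @return An `rf_pulse` object.
#' @export
sech_pulse <- function(duration, n_samples = 256L, tbw = 4.2) {
  stopifnot(tbw > 0)
  # FT of sech(beta t) is (pi/beta) sech(pi^2 f / beta); half max at
  # sech(x) = 1/2 -> x = acosh(2), so FWHM = 2 acosh(2) beta / pi^2.
  beta <- tbw * pi^2 / (2 * acosh(2) * duration)
  new_pulse("sech", duration, n_samples,
            function(t) 1 / cosh(beta * (t - duration / 2)))
}

#' Rectangular (hard) RF pulse envelope
#'
#' @inheritParams gauss_pulse
#' @return An `rf_pulse` object.
#' @export
rect_pulse <- function(duration, n_samples = 64L) {
  new_pulse("rect", duration, n_samples, function(t) rep(1, length(t)))
}

#' Bandwidth-time product of a pulse envelope
#'
#' Duration times the full width at half maximum of the magnitude spectrum of
#' the envelope, computed from a zero-padded discrete Fourier transform
#' (default 32x padding) with linear interpolation of the half-max crossings.
#' The product is invariant under amplitude scaling and under rescaling the
#' duration at fixed shape.
#'
#' @param pulse An `rf_pulse`.
#' @param pad Zero-padding factor (>= 16).
#' @return The dimensionless bandwidth-time product.
#' @export
bandwidth_time_product <- function(pulse, pad = 32L) {
  stopifnot(inherits(pulse, "rf_pulse"), pad >= 16)
  env <- pulse$envelope
  if (all(env == 0)) stop("degenerate all-zero envelope")
  n <- length(env)
  nfft <- pad * 2^ceiling(log2(n))
  spec <- Mod(stats::fft(c(env, rep(0, nfft - n))))
  df <- 1 / (nfft * pulse$duration / (n - 1))
  # center DC so the two half-max crossings can be walked outward from the
  # peak (plateau-like spectra may peak slightly off DC)
  half_n <- nfft %/% 2L
  spec <- c(spec[(half_n + 1L):nfft], spec[1:half_n])
  half <- max(spec) / 2
  k <- which.max(spec)
  above <- spec >= half
  right <- k
  while (right < length(spec) && above[right + 1L]) right <- right + 1L
  frac_r <- if (right < length(spec))
    (spec[right] - half) / (spec[right] - spec[right + 1L]) else 0
  left <- k
  while (left > 1L && above[left - 1L]) left <- left - 1L
  frac_l <- if (left > 1L)
    (spec[left] - half) / (spec[left] - spec[left - 1L]) else 0
  ((right + frac_r) - (left - frac_l)) * df * pulse$duration
}

#' Phase-encode scaling factor
#'
#' The per-repetition scaling applied to the transmit field,
#' `g_alpha = alpha - M/2 - 1/2`, which steps symmetrically about zero as
#' `alpha` runs from 1 to `M`.
#'
#' @param alpha Encode index, 1-based.
#' @param M Total number of phase encodes.
#' @return The dimensionless scale `g_alpha`.
#' @examples
#' phase_encode_scale(1, 64)   # -31.5
#' phase_encode_scale(64, 64)  # +31.5
#' @export
phase_encode_scale <- function(alpha, M) {
  stopifnot(M >= 1)
  if (any(alpha < 1 | alpha > M)) stop("encode index out of range 1..M")
  alpha - M / 2 - 1 / 2
}

envelope_integral <- function(pulse) {
  # trapezoidal integral of the unit-peak envelope, in seconds
  dt <- diff(pulse$times)
  sum((pulse$envelope[-1] + pulse$envelope[-pulse$n_samples]) / 2 * dt)
}

#' Calibrate the transmit amplitude for a target maximum flip angle
#'
#' Determines the amplitude scale `A` (tesla per unit envelope per unit map)
#' such that the on-resonance flip angle
#' `phi(alpha) = gamma * g_alpha * A * unit_field_peak * integral(envelope)`
#' reaches `+target_max_flip` at `alpha = M` (and `-target_max_flip` at
#' `alpha = 1`, by antisymmetry of `g_alpha`).
#'
#' @param pulse An `rf_pulse`.
#' @param M Number of phase encodes.
#' @param unit_field_peak Peak magnitude of the unit coil map, tesla.
#' @param gamma Gyromagnetic ratio, rad s^-1 T^-1.
#' @param target_max_flip Target flip angle at `alpha = M`, degrees (> 0).
#' @return An object of class `flip_calibration` with fields `gamma`,
#'   `target_max_flip`, `amplitude_scale`, plus the pulse and `M` used.
#' @seealso [flip_angle()], [calibrate_encoding()]
#' @export
calibrate_amplitude <- function(pulse, M, unit_field_peak, gamma = GAMMA_1H,
                                target_max_flip = 90) {
  stopifnot(inherits(pulse, "rf_pulse"), target_max_flip > 0,
            unit_field_peak > 0, gamma > 0)
  ie <- envelope_integral(pulse)
  if (ie <= 0) stop("envelope integrates to zero; cannot calibrate")
  g_max <- phase_encode_scale(M, M)
  A <- (target_max_flip * pi / 180) / (gamma * g_max * unit_field_peak * ie)
  structure(list(gamma = gamma, target_max_flip = target_max_flip,
                 amplitude_scale = A, pulse = pulse, M = M,
                 unit_field_peak = unit_field_peak, mode = "flip"),
            class = "flip_calibration")
}

#' @export
print.flip_calibration <- function(x, ...) {
  cat(sprintf("<flip_calibration> mode=%s, amplitude %.4g, gamma %.4g\n",
              x$mode, x$amplitude_scale, x$gamma))
  invisible(x)
}

#' Flip angle delivered at a phase-encode step
#'
#' Evaluates `phi(alpha)` in degrees for a calibration produced by
#' [calibrate_amplitude()]; at the peak-field voxel with full envelope
#' integration, `phi(M) = +target_max_flip` exactly.
#'
#' @param cal A `flip_calibration`.
#' @param alpha Encode index (vectorized).
#' @return Flip angle(s) in degrees.
#' @export
flip_angle <- function(cal, alpha) {
  stopifnot(inherits(cal, "flip_calibration"))
  g <- phase_encode_scale(alpha, cal$M)
  cal$gamma * g * cal$amplitude_scale * cal$unit_field_peak *
    envelope_integral(cal$pulse) * 180 / pi
}

#' Export a pulse as a two-column CSV (time s, amplitude T)
#'
#' @param pulse An `rf_pulse`.
#' @param file Path to write.
#' @param amplitude_scale Tesla multiplier for the unit envelope.
#' @export
write_pulse_csv <- function(pulse, file, amplitude_scale = 1) {
  utils::write.csv(data.frame(time_s = pulse$times,
                              amplitude_T = amplitude_scale * pulse$envelope),
                   file, row.names = FALSE)
}
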