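## Acquisition schedule: the full list of (encode alpha, sample time, coil
## angle) events that defines pseudo k-space.

#' Build the pseudo k-space acquisition schedule
#'
#' One repetition (TR) per phase encode `alpha = 1..M_encodes`; within each
#' TR the coil rotates at `omega_rot` while the shaped pulse plays, and
#' `samples_per_rotation` complex data points are taken at equally spaced
#' times `t_s = s * duration / samples_per_rotation`.  Each TR starts at the
#' angular offset `(alpha - 1) * delta_theta` with
#' `delta_theta = 360 / M_encodes` degrees in 2D and `360 / M_encodes^2` in
#' 3D, so the sample is uniformly "illuminated" across encodes.  The
#' per-encode field scale is `g_alpha = alpha - M/2 - 1/2`.
#'
#' In 3D the amplitude index is the outer loop: the start offset still
#' advances by `delta_theta = 360 / M_encodes^2` degrees after every TR, so
#' completing all `M_encodes` offsets for each of the `M_encodes` amplitudes
#' takes `M_encodes^2` repetitions and sweeps the full circle.
#'
#' @param M_encodes Number of amplitude phase encodes (>= 1).
#' @param samples_per_rotation Data points acquired per TR (>= 1).
#' @param omega_rot Coil angular frequency in rad s^-1.
#' @param pulse An `rf_pulse`; its duration is the TR's active window.
#' @param dims 2 or 3 (sets the offset rule and TR count).
#' @return An object of class `acq_schedule` with per-TR vectors `tr_g`
#'   and `tr_offset_deg` and the per-event table in `$events`
#'   (columns `alpha`, `g`, `sample`, `t`, `theta_deg`).
#' @examples
#' sch <- build_schedule(64, 64, 1256, gauss_pulse(5e-3), dims = 2)
#' nrow(sch$events)  # 4096
#' @export
build_schedule <- function(M_encodes, samples_per_rotation, omega_rot, pulse,
                           dims = 2) {
  stopifnot(M_encodes >= 1, samples_per_rotation >= 1, omega_rot > 0,
            inherits(pulse, "rf_pulse"), dims %in% c(2, 3))
  M <- as.integer(M_encodes); spr <- as.integer(samples_per_rotation)
  if (dims == 2) {
    dtheta <- 360 / M
    n_tr <- M
    tr_alpha <- seq_len(M)
  } else {
    dtheta <- 360 / M^2
    n_tr <- M^2
    tr_alpha <- rep(seq_len(M), each = M)
  }
  tr_offset <- (seq_len(n_tr) - 1) * dtheta
  tr_g <- phase_encode_scale(tr_alpha, M)
  alpha <- rep(tr_alpha, each = spr)
  s <- rep(seq_len(spr), times = n_tr)
  t <- s * pulse$duration / spr
  theta <- rep(tr_offset, each = spr) + omega_rot * t * 180 / pi
  events <- data.frame(alpha = alpha, g = rep(tr_g, each = spr),
                       sample = s, t = t, theta_deg = theta)
  structure(list(M_encodes = M, samples_per_rotation = spr,
                 omega_rot = omega_rot, pulse = pulse, dims = dims,
                 delta_theta = dtheta, n_tr = n_tr, tr_alpha = tr_alpha,
                 tr_g = tr_g, tr_offset_deg = tr_offset, events = events),
            class = "acq_schedule")
}

#' @export
print.acq_schedule <- function(x, ...) {
  cat(sprintf(paste0("<acq_schedule> %d TRs (%d amplitudes) x %d samples = ",
                     "%d events, omega %.4g rad/s, offset %.4g deg/TR\n"),
              x$n_tr, x$M_encodes, x$samples_per_rotation,
              nrow(x$events), x$omega_rot, x$delta_theta))
  invisible(x)
}
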