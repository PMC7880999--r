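#' Periodic 1D actuator trajectory
#'
#' Models the motion actuator used in moving-phantom experiments: a rigid,
#' in-plane, periodic displacement applied to the whole phantom. The motion is
#' one-dimensional in the sense that a single scalar phase drives a fixed
#' direction vector; the default amplitude (20, 7.5) mm corresponds to a
#' vertical stroke of +/-20 mm combined with an axial stroke of +/-7.5 mm.
#'
#' @param kind `"static"` or `"periodic_1d"`.
#' @param amplitude Half-stroke per axis, mm (length 2).
#' @param rpm Actuator cycles per minute (>= 0).
#' @param phase0 Phase at t = 0, radians.
#' @param waveform `"sinusoid"` (default) or `"triangle"`; the actuator
#'   waveform is a modelling choice, and the per-rotation travel depends only
#'   on stroke x frequency.
#' @return An object of class `motion_trajectory`.
#' @export
motion_trajectory <- function(kind = c("periodic_1d", "static"),
                              amplitude = c(20, 7.5), rpm = 0,
                              phase0 = 0,
                              waveform = c("sinusoid", "triangle")) {
  kind <- match.arg(kind)
  waveform <- match.arg(waveform)
  if (rpm < 0) stop("rpm must be >= 0")
  stopifnot(length(amplitude) == 2L, all(is.finite(amplitude)))
  if (kind == "static") {
    amplitude <- c(0, 0)
    rpm <- 0
  }
  structure(list(kind = kind, amplitude = as.numeric(amplitude),
                 rpm = rpm, phase0 = phase0, waveform = waveform),
            class = "motion_trajectory")
}

#' Phantom displacement at a time point
#'
#' For a periodic trajectory the displacement is
#' `amplitude * w(2*pi*rpm*t/60 + phase0)` with `w` the unit waveform
#' (sin for the sinusoid), applied jointly to both axes; a static trajectory
#' returns (0, 0).
#'
#' @param traj A [motion_trajectory()].
#' @param t Time(s), s. Vectorized.
#' @return For scalar `t` a length-2 mm vector; for vector `t` a
#'   `length(t) x 2` matrix.
#' @export
displacement_at <- function(traj, t) {
  stopifnot(all(is.finite(t)))
  if (traj$kind == "static" || traj$rpm == 0) {
    out <- cbind(numeric(length(t)), numeric(length(t)))
  } else {
    ph <- 2 * pi * traj$rpm * t / 60 + traj$phase0
    w <- switch(traj$waveform,
      sinusoid = sin(ph),
      triangle = {
        u <- (ph / (2 * pi)) %% 1
        ifelse(u < 0.25, 4 * u, ifelse(u < 0.75, 2 - 4 * u, 4 * u - 4))
      })
    out <- cbind(traj$amplitude[1] * w, traj$amplitude[2] * w)
  }
  if (length(t) == 1L) as.numeric(out[1, ]) else out
}

#' Travel length per gantry rotation
#'
#' Path length (mm) the phantom travels during one gantry rotation: the
#' combined peak-to-peak stroke is traversed twice per actuator cycle, so
#' travel per rotation = 2 * |stroke| * rpm * rotation_period / 60 with
#' |stroke| the Euclidean norm of the full stroke vector. With the default
#' (40, 15) mm stroke (|stroke| = 42.7 mm) and a 0.5 s rotation this gives
#' 3.6, 7.1 and 10.7 mm at 5, 10 and 15 rpm.
#'
#' @param traj A periodic [motion_trajectory()].
#' @param rotation_period Gantry rotation time, s.
#' @return Travel per rotation, mm.
#' @export
path_per_rotation <- function(traj, rotation_period = 0.5) {
  if (traj$kind == "static") return(0)
  stroke <- 2 * traj$amplitude
  2 * sqrt(sum(stroke^2)) * traj$rpm * rotation_period / 60
}

#' Actuator rate equivalent to a given travel per rotation
#'
#' Inverse of [path_per_rotation()]: experiment conditions are most naturally
#' parameterized by displacement per rotation (mm) rather than raw rpm, since
#' the travel depends only on stroke x frequency.
#'
#' @param mm_per_rot Desired travel per rotation, mm.
#' @param amplitude Half-stroke per axis, mm.
#' @inheritParams path_per_rotation
#' @return rpm value.
#' @export
rpm_for_travel <- function(mm_per_rot, amplitude = c(20, 7.5),
                           rotation_period = 0.5) {
  stopifnot(mm_per_rot >= 0)
  stroke <- 2 * amplitude
  if (mm_per_rot == 0) return(0)
  mm_per_rot * 60 / (2 * sqrt(sum(stroke^2)) * rotation_period)
}
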