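#' Fan-beam scan geometry
#'
#' Third-generation axial geometry: a point source rotating at
#' `source_to_iso` mm from the isocenter, an equiangular detector spanning
#' `fan_angle` degrees, `views_per_rotation` views per `rotation_period`
#' seconds. Angular sampling below roughly `pi * n_channels / 2` views per
#' rotation is allowed but triggers a warning (aliasing guard).
#'
#' @param source_to_iso Source-to-isocenter distance, mm.
#' @param fan_angle Full fan angle, degrees, in (0, 90).
#' @param n_channels Detector channels across the fan.
#' @param views_per_rotation Views acquired per rotation.
#' @param rotation_period Rotation time, s.
#' @param n_rotations Number of full rotations acquired.
#' @param start_angle Source angle of the first view, degrees.
#' @param direction Rotation direction, +1 (ccw) or -1.
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(source_to_iso = 600, fan_angle = 50,
                          n_channels = 736L, views_per_rotation = 1200L,
                          rotation_period = 0.5, n_rotations = 1L,
                          start_angle = 0, direction = 1L) {
  stopifnot(source_to_iso > 0, fan_angle > 0, fan_angle < 90,
            n_channels >= 2L, views_per_rotation >= 4L,
            rotation_period > 0, n_rotations >= 1L,
            direction %in% c(-1L, 1L))
  if (views_per_rotation < ceiling(pi * n_channels / 2)) {
    warning("views_per_rotation below ~pi*n_channels/2; angular undersampling")
  }
  structure(list(source_to_iso = source_to_iso, fan_angle = fan_angle,
                 n_channels = as.integer(n_channels),
                 views_per_rotation = as.integer(views_per_rotation),
                 rotation_period = rotation_period,
                 n_rotations = as.integer(n_rotations),
                 start_angle = start_angle, direction = as.integer(direction)),
            class = "scan_geometry")
}

# channel (fan) angles gamma, degrees, centred on the central ray
channel_angles <- function(geometry) {
  n <- geometry$n_channels
  ((seq_len(n) - (n + 1) / 2) / n) * geometry$fan_angle
}

# per-view source angles beta (degrees, unwrapped, monotone) and times (s)
view_schedule <- function(geometry, t0 = 0) {
  nv <- geometry$views_per_rotation * geometry$n_rotations
  dbeta <- 360 / geometry$views_per_rotation * geometry$direction
  dt <- geometry$rotation_period / geometry$views_per_rotation
  list(beta = geometry$start_angle + (seq_len(nv) - 1) * dbeta,
       time = t0 + (seq_len(nv) - 1) * dt)
}

fan_sinogram <- function(values, view_angles, view_times, geometry) {
  stopifnot(is.matrix(values), nrow(values) == length(view_angles),
            length(view_angles) == length(view_times))
  structure(list(values = values, view_angles = view_angles,
                 view_times = view_times, geometry = geometry),
            class = "fan_sinogram")
}

parallel_sinogram <- function(values, angles, s, view_times,
                              rotation_period) {
  stopifnot(is.matrix(values), nrow(values) == length(angles),
            ncol(values) == length(s),
            length(view_times) == length(angles))
  structure(list(values = values, angles = angles, s = s,
                 view_times = view_times, rotation_period = rotation_period),
            class = "parallel_sinogram")
}

#' @export
print.fan_sinogram <- function(x, ...) {
  cat(sprintf("<fan_sinogram %d views x %d channels, beta [%.1f, %.1f] deg>\n",
              nrow(x$values), ncol(x$values),
              min(x$view_angles), max(x$view_angles)))
  invisible(x)
}

#' @export
print.parallel_sinogram <- function(x, ...) {
  cat(sprintf("<parallel_sinogram %d views x %d bins, theta [%.1f, %.1f] deg, s [%.1f, %.1f] mm>\n",
              nrow(x$values), ncol(x$values), min(x$angles), max(x$angles),
              min(x$s), max(x$s)))
  invisible(x)
}

# Exact chord length of the ray (point p0, unit dir d) through a disk.
# Vectorized over rays: p0 fixed, dirs nx2.
disk_chords <- function(p0, dirs, center, radius) {
  ux <- center[1] - p0[1]
  uy <- center[2] - p0[2]
  talong <- dirs[, 1] * ux + dirs[, 2] * uy
  l2 <- (ux^2 + uy^2) - talong^2
  h2 <- radius^2 - l2
  ifelse(h2 > 0, 2 * sqrt(pmax(h2, 0)), 0)
}

#' Analytic fan-beam forward projection of a moving phantom
#'
#' Computes exact monochromatic line integrals (chord length times attenuation)
#' through the analytic phantom, displacing it rigidly by
#' `displacement_at(traj, t(view))` for each view; motion is frozen within a
#' view. Primitives must be pairwise disjoint or fully nested and the
#' background must be air (-1000 HU, zero attenuation) for the line integrals
#' to be finite.
#'
#' @param phantom A [phantom_model()].
#' @param geometry A [scan_geometry()].
#' @param traj A [motion_trajectory()]; default static.
#' @param t0 Acquisition time of the first view, s.
#' @param mu_water Water attenuation used for the HU -> mu conversion, 1/mm.
#' @return A `fan_sinogram` of line integrals (unitless, mu * mm).
#' @export
forward_project_fan <- function(phantom, geometry,
                                traj = motion_trajectory("static"),
                                t0 = 0, mu_water = 0.019) {
  if (abs(phantom$background_value + 1000) > 1e-6) {
    stop("analytic projection requires a -1000 HU (air) background")
  }
  parent <- phantom_parents(phantom)
  prims <- phantom$primitives
  mu_of <- function(hu) mu_from_hu(hu, mu_water)
  # effective contrast of each primitive over what lies beneath it
  dmu <- vapply(seq_along(prims), function(i) {
    under <- if (parent[i] == 0L) phantom$background_value else prims[[parent[i]]]$value
    mu_of(prims[[i]]$value) - mu_of(under)
  }, numeric(1))

  sched <- view_schedule(geometry, t0)
  gam <- deg2rad(channel_angles(geometry))
  R <- geometry$source_to_iso
  nv <- length(sched$beta)
  vals <- matrix(0, nv, geometry$n_channels)
  disp <- displacement_at(traj, sched$time)
  if (is.null(dim(disp))) disp <- matrix(disp, 1)
  cosg <- cos(gam); sing <- sin(gam)
  for (v in seq_len(nv)) {
    b <- deg2rad(sched$beta[v])
    p0 <- R * c(sin(b), -cos(b))
    # central direction towards isocenter, rotated by each channel angle
    d0 <- c(-sin(b), cos(b))
    dirs <- cbind(d0[1] * cosg - d0[2] * sing,
                  d0[1] * sing + d0[2] * cosg)
    acc <- numeric(geometry$n_channels)
    for (i in seq_along(prims)) {
      p <- prims[[i]]
      ctr <- p$center + disp[v, ]
      ch <- disk_chords(p0, dirs, ctr, p$outer_radius)
      if (p$inner_radius > 0) {
        ch <- ch - disk_chords(p0, dirs, ctr, p$inner_radius)
      }
      acc <- acc + dmu[i] * ch
    }
    vals[v, ] <- acc
  }
  fan_sinogram(vals, sched$beta, sched$time, geometry)
}

#' Rebin a fan-beam sinogram to parallel geometry
#'
#' Standard fan-to-parallel rebinning: a fan ray at source angle `beta` and
#' channel angle `gamma` is the parallel ray at `theta = beta + gamma`,
#' `s = -R * sin(gamma)` (sign fixed by the ray-normal convention
#' `n(theta) = (cos theta, sin theta)`). Values are interpolated bilinearly in
#' `(beta, gamma)`; each parallel view carries the acquisition time of its
#' central contributing fan view (`beta = theta`). The output `theta` axis is
#' unwrapped (monotone over rotations) and trimmed by half the fan angle on
#' each side so every target ray is fully covered.
#'
#' @param fan A `fan_sinogram` covering at least 180 degrees + fan angle.
#' @param n_s Number of radial bins (default: number of channels).
#' @return A `parallel_sinogram`.
#' @export
rebin_fan_to_parallel <- function(fan, n_s = NULL) {
  geom <- fan$geometry
  if (is.null(n_s)) n_s <- geom$n_channels
  beta <- fan$view_angles
  dbeta <- beta[2] - beta[1]
  span <- abs(beta[length(beta)] - beta[1])
  if (span < 180 + geom$fan_angle - 1e-9) {
    stop(sprintf("fan coverage %.1f deg < required %.1f deg (180 + fan angle)",
                 span, 180 + geom$fan_angle))
  }
  R <- geom$source_to_iso
  gmax <- deg2rad(geom$fan_angle / 2)
  smax <- R * sin(gmax)
  s <- seq(-smax, smax, length.out = n_s)
  gam_deg <- channel_angles(geom)          # uniform, ascending
  dgam <- gam_deg[2] - gam_deg[1]
  # per-bin channel angle and fractional channel index
  gam_s <- -asin(s / R)                    # radians
  gidx <- (rad2deg(gam_s) - gam_deg[1]) / dgam + 1
  gidx <- pmin(pmax(gidx, 1), geom$n_channels)
  g0 <- pmin(floor(gidx), geom$n_channels - 1L)
  gw <- gidx - g0

  # theta grid: same pitch as beta, trimmed by fan/2 each side
  half <- geom$fan_angle / 2
  if (dbeta > 0) {
    th <- beta[beta >= beta[1] + half & beta <= beta[length(beta)] - half]
  } else {
    th <- beta[beta <= beta[1] - half & beta >= beta[length(beta)] + half]
  }
  nth <- length(th)
  vals <- matrix(0, nth, n_s)
  nvf <- length(beta)
  for (j in seq_len(n_s)) {
    bq <- th - rad2deg(gam_s[j])           # required fan source angles
    bidx <- (bq - beta[1]) / dbeta + 1
    b0 <- pmin(pmax(floor(bidx), 1L), nvf - 1L)
    bw <- pmin(pmax(bidx - b0, 0), 1)
    c0 <- g0[j]; cw <- gw[j]
    v00 <- fan$values[cbind(b0, c0)]
    v01 <- fan$values[cbind(b0, c0 + 1L)]
    v10 <- fan$values[cbind(b0 + 1L, c0)]
    v11 <- fan$values[cbind(b0 + 1L, c0 + 1L)]
    vals[, j] <- (1 - bw) * ((1 - cw) * v00 + cw * v01) +
      bw * ((1 - cw) * v10 + cw * v11)
  }
  # time of the central contributing fan view (beta = theta)
  tidx <- (th - beta[1]) / dbeta + 1
  t0i <- pmin(pmax(floor(tidx), 1L), nvf - 1L)
  tw <- pmin(pmax(tidx - t0i, 0), 1)
  vt <- (1 - tw) * fan$view_times[t0i] + tw * fan$view_times[t0i + 1L]
  parallel_sinogram(vals, th, s, vt, geom$rotation_period)
}
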