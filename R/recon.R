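#' Ramp-filter a parallel sinogram
#'
#' Convolves each view with the discrete band-limited Ram-Lak kernel
#' (h(0) = 1/(4*ds^2), h(n) = -1/(pi*n*ds)^2 for odd n, 0 for even n),
#' optionally apodized with a Shepp-Logan or Hann window. Views are
#' zero-padded to at least twice their length (next power of two) so circular
#' convolution does not wrap. The result is pre-scaled by the radial bin
#' width, so backprojection only needs the angular weight.
#'
#' @param sino A `parallel_sinogram` with uniform radial sampling.
#' @param window `"none"` (pure Ram-Lak), `"shepp_logan"` or `"hann"`.
#' @return A filtered `parallel_sinogram`.
#' @export
ramp_filter <- function(sino, window = c("none", "shepp_logan", "hann")) {
  window <- match.arg(window)
  ns <- ncol(sino$values)
  ds <- sino$s[2] - sino$s[1]
  npad <- 2^ceiling(log2(2 * ns))
  h <- numeric(npad)
  h[1] <- 1 / (4 * ds^2)
  n_pos <- seq_len(npad / 2)
  odd <- n_pos[n_pos %% 2 == 1L]
  h[odd + 1L] <- -1 / (pi * odd * ds)^2
  h[npad - odd + 1L] <- -1 / (pi * odd * ds)^2   # wrap-around negative lags
  H <- Re(stats::fft(h))
  fr <- pmin(0:(npad - 1), npad - (0:(npad - 1))) / (npad / 2)  # |f|/Nyquist
  w <- switch(window,
    none = rep(1, npad),
    shepp_logan = ifelse(fr > 0, sin(pi * fr / 2) / (pi * fr / 2), 1),
    hann = 0.5 * (1 + cos(pi * fr)))
  H <- H * w
  pad <- matrix(0, npad, nrow(sino$values))
  pad[seq_len(ns), ] <- t(sino$values)
  Q <- Re(stats::mvfft(stats::mvfft(pad) * H, inverse = TRUE)) / npad
  out <- sino
  out$values <- t(Q[seq_len(ns), , drop = FALSE]) * ds
  out
}

# number of views spanning 180 degrees on the (uniform) theta axis
views_per_180 <- function(sino) {
  dth <- abs(sino$angles[2] - sino$angles[1])
  round(180 / dth)
}

# indices of the n consecutive views starting nearest `from` degrees
view_window <- function(sino, from, n) {
  dth <- sino$angles[2] - sino$angles[1]
  i0 <- round((from - sino$angles[1]) / dth) + 1
  if (i0 < 1 || i0 + n - 1 > length(sino$angles)) {
    stop(sprintf(paste0("sinogram covers [%.1f, %.1f] deg but views ",
                        "[%.1f, %.1f] deg are required"),
                 min(sino$angles), max(sino$angles),
                 from, from + (n - 1) * dth))
  }
  seq.int(i0, i0 + n - 1L)
}

# acquisition time at parallel angle theta (linear interpolation)
time_at_angle <- function(sino, theta) {
  stats::approx(sino$angles, sino$view_times, xout = theta, rule = 2)$y
}

#' Backproject a filtered parallel sinogram
#'
#' Pixel-driven backprojection with linear interpolation along the radial
#' axis. Each selected view adds `weight * interp(q_theta, x . n(theta))` to
#' every pixel; the sum is scaled by `pi / n180` (views per 180 degrees) so a
#' complete half scan with unit weights reconstructs the attenuation map,
#' which is then converted to HU. When a motion vector field and a target
#' angle are supplied, each view samples the detector at the pixel's material
#' position `X + alpha(theta) * D(X)` — the motion-compensated form; with a
#' zero field this reduces bit-identically to plain FBP (shared code path).
#'
#' @param filtered A ramp-filtered `parallel_sinogram`.
#' @param grid An [image_grid()].
#' @param views Integer indices of the views to use.
#' @param weights Per-view weights (recycled if length 1).
#' @param mvf Optional [mvf] (dense displacement field) for motion
#'   compensation.
#' @param theta_c Target angle (degrees) for the linear-in-angle motion model;
#'   required with `mvf`.
#' @param mu_water Water attenuation, 1/mm, for the HU conversion.
#' @return A [ct_image()] in HU.
#' @export
backproject <- function(filtered, grid, views, weights = 1,
                        mvf = NULL, theta_c = NULL, mu_water = 0.019) {
  if (length(views) == 0L) stop("empty view subset")
  weights <- rep_len(weights, length(views))
  co <- grid_coords(grid)
  X <- rep(co$x, each = grid$ny)
  Y <- rep(co$y, times = grid$nx)
  if (!is.null(mvf)) {
    if (is.null(theta_c)) stop("theta_c is required with a motion field")
    g <- mvf$grid
    if (g$nx != grid$nx || g$ny != grid$ny ||
        !isTRUE(all.equal(g$spacing, grid$spacing)) ||
        !isTRUE(all.equal(g$origin, grid$origin))) {
      stop("motion field grid does not match the reconstruction grid")
    }
    DX <- as.numeric(mvf$dx)
    DY <- as.numeric(mvf$dy)
  } else {
    DX <- 0
    DY <- 0
  }
  s0 <- filtered$s[1]
  ds <- filtered$s[2] - filtered$s[1]
  ns <- length(filtered$s)
  acc <- numeric(grid$ny * grid$nx)
  for (k in seq_along(views)) {
    v <- views[k]
    th <- filtered$angles[v]
    a <- if (is.null(mvf)) 0 else alpha_for_view(th, theta_c)
    ct <- cos(deg2rad(th)); st <- sin(deg2rad(th))
    sv <- (X + a * DX) * ct + (Y + a * DY) * st
    fi <- (sv - s0) / ds + 1
    i0 <- pmin.int(pmax.int(floor(fi), 1), ns - 1L)
    fw <- pmin.int(pmax.int(fi - i0, 0), 1)
    q <- filtered$values[v, ]
    acc <- acc + weights[k] * ((1 - fw) * q[i0] + fw * q[i0 + 1L])
  }
  mu <- acc * pi / views_per_180(filtered)
  dim(mu) <- c(grid$ny, grid$nx)
  ang <- range(filtered$angles[views])
  ct_image(hu_from_mu(mu, mu_water), grid,
           time_center = mean(filtered$view_times[views]),
           angular_range = ang)
}

#' Half-scan filtered backprojection
#'
#' Reconstructs from exactly 180 degrees of parallel views centred on
#' `theta_c` with unit weights (a parallel half scan is complete, so no
#' short-scan weighting is needed after rebinning). The image's
#' `time_center` is the acquisition time at `theta_c` — the middle of the raw
#' data used.
#'
#' @param sino A `parallel_sinogram` covering `[theta_c - 90, theta_c + 90)`.
#' @param grid An [image_grid()].
#' @param theta_c Central view angle, degrees (on the sinogram's unwrapped
#'   axis).
#' @param window Ramp apodization, see [ramp_filter()].
#' @param mu_water Water attenuation, 1/mm.
#' @param filtered Optional pre-filtered sinogram (to reuse across calls);
#'   must come from `ramp_filter(sino, window)`.
#' @return A [ct_image()] in HU.
#' @export
fbp_half <- function(sino, grid, theta_c, window = "none", mu_water = 0.019,
                     filtered = NULL) {
  n180 <- views_per_180(sino)
  idx <- view_window(sino, theta_c - 90, n180)
  if (is.null(filtered)) filtered <- ramp_filter(sino, window)
  img <- backproject(filtered, grid, idx, mu_water = mu_water)
  img$meta$time_center <- time_at_angle(sino, theta_c)
  img$meta$label <- "fbp_half"
  img
}

#' Conjugate partial-angle reconstruction pair
#'
#' Splits the half-scan view window centred at `theta_c` into a leading and a
#' trailing segment of `segment_length` degrees, centred at `theta_c - 90` and
#' `theta_c + 90`, and backprojects each with the same filter and per-view
#' weights as [fbp_half()]. The two PAR images are conjugate — in parallel
#' geometry they sample the same ray lines half a rotation apart — and are
#' kept as raw partial sums (incomplete images), not normalized to a full
#' reconstruction. The segment length defaults to the fan angle of the
#' geometry that produced the sinogram (heuristic choice for heart-induced
#' motion).
#'
#' @inheritParams fbp_half
#' @param segment_length Angular length of each PAR segment, degrees.
#' @param window Ramp apodization; Hann by default to stabilize registration.
#' @return An object of class `par_pair` with elements `before`, `after`
#'   (both [ct_image()]), `target_time`, `theta_c`, `segment_length`.
#' @export
reconstruct_par_pair <- function(sino, grid, theta_c, segment_length = 50,
                                 window = "hann", mu_water = 0.019,
                                 filtered = NULL) {
  if (segment_length <= 0) stop("segment_length must be positive")
  n180 <- views_per_180(sino)
  dth <- abs(sino$angles[2] - sino$angles[1])
  nL <- max(2L, round(segment_length / dth))
  if (nL > n180) stop("segment_length exceeds the half-scan window")
  half <- view_window(sino, theta_c - 90 - segment_length / 2,
                      n180 + nL)
  if (is.null(filtered)) filtered <- ramp_filter(sino, window)
  seg_before <- half[seq_len(nL)]
  seg_after <- half[seq.int(length(half) - nL + 1L, length(half))]
  before <- backproject(filtered, grid, seg_before, mu_water = mu_water)
  after <- backproject(filtered, grid, seg_after, mu_water = mu_water)
  before$meta$label <- "par_before"
  after$meta$label <- "par_after"
  structure(list(before = before, after = after,
                 target_time = time_at_angle(sino, theta_c),
                 theta_c = theta_c, segment_length = segment_length),
            class = "par_pair")
}

#' @export
print.par_pair <- function(x, ...) {
  cat(sprintf("<par_pair: theta_c=%.1f deg, L=%.1f deg, dt=%.4f s>\n",
              x$theta_c, x$segment_length,
              x$after$meta$time_center - x$before$meta$time_center))
  invisible(x)
}

# 1-D Gaussian blur operator (n x n) with edge renormalization: each output
# row is a truncated (4 sigma), clipped, renormalized kernel, so a constant
# input is reproduced exactly.
blur_operator <- function(n, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  off <- (-r):r
  w <- exp(-off^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + off
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- w[ok] / sum(w[ok])
  }
  K
}

gaussian_blur <- function(values, sigma) {
  Ky <- blur_operator(nrow(values), sigma)
  Kx <- blur_operator(ncol(values), sigma)
  Ky %*% values %*% t(Kx)
}

#' Band-pass filter an image (difference of Gaussians)
#'
#' `G(sigma_fine) * img - G(sigma_coarse) * img`: discards non-structural
#' low-frequency content such as limited-angle shading while preserving
#' vessel- and airway-scale edges; the PAR images are band-passed before
#' registration so the similarity metric sees structure, not shading.
#'
#' @param img A [ct_image()].
#' @param sigma_fine,sigma_coarse Gaussian scales in pixels,
#'   `0 < sigma_fine < sigma_coarse`.
#' @return A [ct_image()] (zero-mean apart from edge effects).
#' @export
bandpass <- function(img, sigma_fine = 1, sigma_coarse = 8) {
  stopifnot(sigma_fine > 0, sigma_fine < sigma_coarse)
  out <- img
  out$values <- gaussian_blur(img$values, sigma_fine) -
    gaussian_blur(img$values, sigma_coarse)
  out$meta$label <- paste0(img$meta$label, "_bp")
  out
}
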