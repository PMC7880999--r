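#' B-spline control grid for free-form deformation
#'
#' Uniform cubic tensor-product B-spline lattice covering an image grid plus
#' at least one control interval of margin on every side (cubic support), with
#' one 2-vector displacement coefficient (mm) per control point.
#'
#' @param grid The [image_grid()] the deformation acts on.
#' @param spacing Control-point spacing, mm (both axes).
#' @param coef Optional coefficient array `ncy x ncx x 2` (mm); zeros if
#'   omitted.
#' @return An object of class `bspline_control_grid`.
#' @export
bspline_control_grid <- function(grid, spacing = 24, coef = NULL) {
  stopifnot(spacing > 0)
  co <- grid_coords(grid)
  mk <- function(lo, hi) {
    x0 <- lo - spacing                       # one-interval margin
    nc <- floor((hi - x0) / spacing) + 3L    # indices floor(u)-1 .. floor(u)+2
    list(x0 = x0, nc = as.integer(nc))
  }
  ax <- mk(min(co$x), max(co$x))
  ay <- mk(min(co$y), max(co$y))
  if (is.null(coef)) coef <- array(0, c(ay$nc, ax$nc, 2))
  stopifnot(identical(dim(coef), c(ay$nc, ax$nc, 2L)) ||
              identical(dim(coef), as.integer(c(ay$nc, ax$nc, 2))))
  structure(list(spacing = spacing, x0 = ax$x0, y0 = ay$x0,
                 ncx = ax$nc, ncy = ay$nc, coef = coef, grid = grid),
            class = "bspline_control_grid")
}

# cubic B-spline basis values for fractional position t in [0, 1)
bspline_weights <- function(t) {
  cbind((1 - t)^3 / 6,
        (3 * t^3 - 6 * t^2 + 4) / 6,
        (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
        t^3 / 6)
}

# dense basis matrix: length(x) rows, nc cols, 4 nonzeros per row
bspline_basis_matrix <- function(x, x0, h, nc, clamp = FALSE) {
  u <- (x - x0) / h
  i <- floor(u)
  if (clamp) {
    i <- pmin(pmax(i, 1), nc - 3L)
  } else if (any(i < 1 | i > nc - 3L)) {
    stop("point outside B-spline grid extent")
  }
  w <- bspline_weights(u - i)
  B <- matrix(0, length(x), nc)
  for (k in 0:3) B[cbind(seq_along(x), i + k)] <- w[, k + 1]
  B
}

#' Evaluate an FFD at arbitrary points
#'
#' Standard free-form deformation: the displacement at a point is the
#' tensor-product cubic B-spline interpolation of the control-point
#' coefficients, `D(p) = sum_kl B3(u) B3(v) c_kl`.
#'
#' @param ctrl A [bspline_control_grid()].
#' @param points `n x 2` matrix of (x, y) positions, mm, inside the grid
#'   extent.
#' @return `n x 2` matrix of displacements, mm.
#' @export
ffd_displacement <- function(ctrl, points) {
  points <- rbind(points)
  h <- ctrl$spacing
  ux <- (points[, 1] - ctrl$x0) / h
  uy <- (points[, 2] - ctrl$y0) / h
  ix <- floor(ux); iy <- floor(uy)
  if (any(ix < 1 | ix > ctrl$ncx - 3L | iy < 1 | iy > ctrl$ncy - 3L)) {
    stop("point outside B-spline grid extent")
  }
  wx <- bspline_weights(ux - ix)
  wy <- bspline_weights(uy - iy)
  out <- matrix(0, nrow(points), 2)
  for (a in 0:3) {
    for (b in 0:3) {
      w <- wy[, a + 1] * wx[, b + 1]
      idx <- cbind(iy + a, ix + b)
      out[, 1] <- out[, 1] + w * ctrl$coef[, , 1][idx]
      out[, 2] <- out[, 2] + w * ctrl$coef[, , 2][idx]
    }
  }
  out
}

#' Dense motion vector field
#'
#' A per-pixel 2-vector displacement (mm) on an image grid, by convention the
#' forward displacement of material points from the BEFORE partial-angle
#' image's time to the AFTER image's time (one half rotation later); the
#' reconstruction target time sits midway, at scale factor 0.
#'
#' @param dx,dy `ny x nx` matrices of x/y displacements, mm.
#' @param grid The [image_grid()].
#' @param control Optional source [bspline_control_grid()].
#' @return An object of class `mvf`.
#' @export
mvf <- function(dx, dy, grid, control = NULL) {
  stopifnot(is.matrix(dx), is.matrix(dy),
            all(dim(dx) == c(grid$ny, grid$nx)),
            all(dim(dy) == c(grid$ny, grid$nx)),
            all(is.finite(dx)), all(is.finite(dy)))
  structure(list(dx = dx, dy = dy, grid = grid, control = control),
            class = "mvf")
}

#' Zero (identity) motion field on a grid
#' @param grid An [image_grid()].
#' @return An [mvf] with all-zero displacements.
#' @export
zero_mvf <- function(grid) {
  z <- matrix(0, grid$ny, grid$nx)
  mvf(z, z, grid)
}

#' @export
print.mvf <- function(x, ...) {
  cat(sprintf("<mvf %dx%d, |D| max %.3f mm>\n", x$grid$ny, x$grid$nx,
              max(sqrt(x$dx^2 + x$dy^2))))
  invisible(x)
}

# dense field from a control grid, via separable basis matrices
mvf_from_control <- function(ctrl, grid = ctrl$grid) {
  co <- grid_coords(grid)
  Bx <- bspline_basis_matrix(co$x, ctrl$x0, ctrl$spacing, ctrl$ncx)
  By <- bspline_basis_matrix(co$y, ctrl$y0, ctrl$spacing, ctrl$ncy)
  mvf(By %*% ctrl$coef[, , 1] %*% t(Bx),
      By %*% ctrl$coef[, , 2] %*% t(Bx),
      grid, control = ctrl)
}

#' Linear-in-angle motion scale for a view
#'
#' Under the linear motion model the displacement at a view is a scalar
#' multiple of the full before-to-after MVF:
#' `alpha = wrap(theta - theta_c) / 180`, so the target view gets 0 and the
#' two PAR centres (at `theta_c +/- 90`) get the half-displacement endpoints
#' -1/2 and +1/2.
#'
#' @param theta View angle, degrees (vectorized).
#' @param theta_c Target angle, degrees.
#' @return Scale factor(s) in \[-0.5, 0.5\] for half-scan views.
#' @export
alpha_for_view <- function(theta, theta_c) wrap_deg(theta - theta_c) / 180

#' Scale a motion field
#'
#' Pointwise multiplication `alpha * D`; used to interpolate the
#' before-to-after field to an individual view's time.
#'
#' @param field An [mvf].
#' @param alpha Scalar factor.
#' @return The scaled [mvf].
#' @export
scale_mvf <- function(field, alpha) {
  mvf(alpha * field$dx, alpha * field$dy, field$grid, control = field$control)
}

# bilinear sample of a ny x nx raster at physical positions (px, py)
bilinear_sample <- function(values, grid, px, py, fill = 0) {
  fj <- (px - grid$origin[1]) / grid$spacing + 1
  fi <- (py - grid$origin[2]) / grid$spacing + 1
  nx <- ncol(values); ny <- nrow(values)
  inside <- fj >= 1 & fj <= nx & fi >= 1 & fi <= ny
  j0 <- pmin.int(pmax.int(floor(fj), 1), nx - 1L)
  i0 <- pmin.int(pmax.int(floor(fi), 1), ny - 1L)
  wj <- pmin.int(pmax.int(fj - j0, 0), 1)
  wi <- pmin.int(pmax.int(fi - i0, 0), 1)
  idx <- function(i, j) values[i + (j - 1L) * ny]
  out <- (1 - wi) * ((1 - wj) * idx(i0, j0) + wj * idx(i0, j0 + 1L)) +
    wi * ((1 - wj) * idx(i0 + 1L, j0) + wj * idx(i0 + 1L, j0 + 1L))
  out[!inside] <- fill
  out
}

#' Warp an image by a motion field
#'
#' Pull (default): `out(X) = img(X + D(X))` with bilinear sampling — the
#' output pixel fetches the input value at its displaced material position;
#' under this convention a uniform field `(dx, 0)` translates image content by
#' `-dx`. Push scatters each input pixel to its displaced position
#' (nearest-neighbour accumulation) and is intended for visualization only.
#'
#' @param img A [ct_image()].
#' @param field An [mvf] on the same grid.
#' @param direction `"pull"` or `"push"`.
#' @param fill Value for samples outside the grid (HU).
#' @return A [ct_image()].
#' @export
warp_image <- function(img, field, direction = c("pull", "push"),
                       fill = -1000) {
  direction <- match.arg(direction)
  grid <- img$grid
  co <- grid_coords(grid)
  X <- rep(co$x, each = grid$ny)
  Y <- rep(co$y, times = grid$nx)
  if (direction == "pull") {
    v <- bilinear_sample(img$values, grid, X + as.numeric(field$dx),
                         Y + as.numeric(field$dy), fill = fill)
    out <- matrix(v, grid$ny, grid$nx)
  } else {
    fj <- round((X + as.numeric(field$dx) - grid$origin[1]) / grid$spacing) + 1
    fi <- round((Y + as.numeric(field$dy) - grid$origin[2]) / grid$spacing) + 1
    ok <- fj >= 1 & fj <= grid$nx & fi >= 1 & fi <= grid$ny
    out <- matrix(fill, grid$ny, grid$nx)
    out[cbind(fi[ok], fj[ok])] <- img$values[ok]
  }
  ct_image(out, grid, time_center = img$meta$time_center,
           angular_range = img$meta$angular_range,
           label = paste0(img$meta$label, "_warp"))
}
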