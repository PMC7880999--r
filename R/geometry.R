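#' Reconstruction grid
#'
#' Defines the raster on which images are reconstructed. Pixel centres map to
#' physical coordinates as `x_j = origin[1] + (j-1) * spacing`,
#' `y_i = origin[2] + (i-1) * spacing`; image matrices are `ny x nx` with
#' element `[i, j]` at `(x_j, y_i)` (y increases with row index). By default
#' the grid is centred on the isocenter.
#'
#' @param nx,ny Number of pixels along x and y.
#' @param spacing Pixel spacing in mm (isotropic). The default 360 mm display
#'   field of view at 512 pixels gives 0.703 mm.
#' @param origin Physical coordinates (mm) of the centre of pixel `[1, 1]`;
#'   `NULL` centres the grid on the isocenter.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(nx = 512L, ny = nx, spacing = 360 / 512, origin = NULL) {
  stopifnot(nx >= 1L, ny >= 1L, spacing > 0)
  if (is.null(origin)) {
    origin <- c(-spacing * (nx - 1) / 2, -spacing * (ny - 1) / 2)
  }
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny),
         spacing = spacing, origin = as.numeric(origin)),
    class = "image_grid"
  )
}

#' Physical pixel-centre coordinates of a grid
#'
#' @param grid An [image_grid()].
#' @return A list with vectors `x` (length nx) and `y` (length ny) in mm.
#' @export
grid_coords <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$nx) - 1) * grid$spacing,
       y = grid$origin[2] + (seq_len(grid$ny) - 1) * grid$spacing)
}

#' CT image on a grid
#'
#' A reconstructed (or rasterized) image in Hounsfield units together with its
#' grid and acquisition metadata.
#'
#' @param values `ny x nx` numeric matrix of CT values (HU).
#' @param grid The [image_grid()] the raster lives on.
#' @param time_center Acquisition time (s) the image represents, or `NA`.
#' @param angular_range Length-2 numeric, degrees, the angular span of views
#'   used (ordered), or `NULL`.
#' @param label Free-text label.
#' @return An object of class `ct_image`.
#' @export
ct_image <- function(values, grid, time_center = NA_real_,
                     angular_range = NULL, label = "") {
  stopifnot(is.matrix(values), nrow(values) == grid$ny, ncol(values) == grid$nx)
  if (!is.null(angular_range)) {
    stopifnot(length(angular_range) == 2L, angular_range[1] <= angular_range[2])
  }
  structure(
    list(values = values, grid = grid,
         meta = list(time_center = time_center,
                     angular_range = angular_range, label = label)),
    class = "ct_image"
  )
}

#' @export
print.ct_image <- function(x, ...) {
  cat(sprintf("<ct_image %dx%d, %.3f mm/px, HU range [%.1f, %.1f]%s>\n",
              x$grid$ny, x$grid$nx, x$grid$spacing,
              min(x$values), max(x$values),
              if (nzchar(x$meta$label)) paste0(", ", x$meta$label) else ""))
  invisible(x)
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid %dx%d @ %.4f mm, origin (%.2f, %.2f) mm>\n",
              x$nx, x$ny, x$spacing, x$origin[1], x$origin[2]))
  invisible(x)
}

# HU <-> linear attenuation (1/mm). mu_water defaults to 0.019/mm (~70 keV).
#' Convert Hounsfield units to linear attenuation
#' @param hu CT values (HU).
#' @param mu_water Attenuation of water in 1/mm.
#' @return Attenuation coefficients, 1/mm.
#' @export
mu_from_hu <- function(hu, mu_water = 0.019) mu_water * (1 + hu / 1000)

#' Convert linear attenuation to Hounsfield units
#' @param mu Attenuation coefficients, 1/mm.
#' @inheritParams mu_from_hu
#' @return CT values, HU.
#' @export
hu_from_mu <- function(mu, mu_water = 0.019) 1000 * (mu / mu_water - 1)

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# wrap an angle difference into [-180, 180)
wrap_deg <- function(d) ((d + 180) %% 360) - 180
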