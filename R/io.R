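# Raw little-endian float32 + JSON sidecar I/O. `path` is the stem: data go
# to <stem>.raw (column-major), metadata to <stem>.json.

write_raw_f32 <- function(values, path) {
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(values), con, size = 4L, endian = "little")
}

read_raw_f32 <- function(path, n) {
  con <- file(paste0(path, ".raw"), "rb")
  on.exit(close(con))
  readBin(con, what = "numeric", n = n, size = 4L, endian = "little")
}

#' Write / read a parallel sinogram as raw float32 + JSON sidecar
#'
#' @param sino A `parallel_sinogram`.
#' @param path File stem (writes `<path>.raw` and `<path>.json`).
#' @return `write_sinogram` returns `path` invisibly; `read_sinogram` the
#'   sinogram.
#' @export
write_sinogram <- function(sino, path) {
  write_raw_f32(sino$values, path)
  jsonlite::write_json(
    list(type = "parallel_sinogram", shape = dim(sino$values),
         angles = sino$angles, s = sino$s, view_times = sino$view_times,
         rotation_period = sino$rotation_period),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  stopifnot(identical(meta$type, "parallel_sinogram"))
  vals <- matrix(read_raw_f32(path, prod(meta$shape)),
                 meta$shape[1], meta$shape[2])
  parallel_sinogram(vals, meta$angles, meta$s, meta$view_times,
                    meta$rotation_period)
}

#' Write / read an image as raw float32 + JSON sidecar
#'
#' @param img A [ct_image()].
#' @param path File stem (writes `<path>.raw` and `<path>.json`).
#' @return `write_image` returns `path` invisibly; `read_image` the image.
#' @export
write_image <- function(img, path) {
  write_raw_f32(img$values, path)
  jsonlite::write_json(
    list(type = "ct_image", shape = dim(img$values),
         spacing = img$grid$spacing, origin = img$grid$origin,
         time_center = img$meta$time_center,
         angular_range = img$meta$angular_range, label = img$meta$label),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  stopifnot(identical(meta$type, "ct_image"))
  vals <- matrix(read_raw_f32(path, prod(meta$shape)),
                 meta$shape[1], meta$shape[2])
  grid <- image_grid(nx = meta$shape[2], ny = meta$shape[1],
                     spacing = meta$spacing, origin = meta$origin)
  ar <- meta$angular_range
  if (length(ar) != 2L) ar <- NULL
  ct_image(vals, grid,
           time_center = if (length(meta$time_center) != 1L) NA_real_ else meta$time_center,
           angular_range = ar,
           label = if (is.null(meta$label)) "" else meta$label)
}
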