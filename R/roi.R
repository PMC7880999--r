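#' Rectangular region of interest
#'
#' Axis-aligned rectangle in physical mm coordinates, converted to a pixel
#' mask by centre inclusion (a pixel belongs to the ROI when its centre lies
#' inside the rectangle) — the boxed-ROI convention of phantom evaluations.
#'
#' @param label ROI label.
#' @param x0,y0,x1,y1 Rectangle corners, mm (`x0 < x1`, `y0 < y1`).
#' @return An object of class `roi_rect`.
#' @export
roi_rect <- function(label, x0, y0, x1, y1) {
  stopifnot(x0 < x1, y0 < y1)
  structure(list(label = label, x0 = x0, y0 = y0, x1 = x1, y1 = y1),
            class = "roi_rect")
}

#' Pixel mask of an ROI on a grid
#'
#' @param roi An [roi_rect()] or a logical `ny x nx` matrix (used as-is).
#' @param grid An [image_grid()].
#' @return Logical `ny x nx` matrix. Warns when the mask has fewer than 25
#'   pixels (kernel-density stability guard).
#' @export
roi_mask <- function(roi, grid) {
  if (is.matrix(roi) && is.logical(roi)) {
    stopifnot(all(dim(roi) == c(grid$ny, grid$nx)))
    m <- roi
  } else {
    co <- grid_coords(grid)
    inx <- co$x >= roi$x0 & co$x <= roi$x1
    iny <- co$y >= roi$y0 & co$y <= roi$y1
    m <- outer(iny, inx, "&")
  }
  if (sum(m) == 0L) stop("empty ROI")
  if (sum(m) < 25L) warning("ROI has fewer than 25 pixels; KDE may be unstable")
  m
}

#' Read ROI rectangles from a JSON file
#'
#' Expects a JSON array of objects with fields `label, x0, y0, x1, y1` (mm).
#'
#' @param path JSON file path.
#' @return List of [roi_rect()].
#' @export
read_rois <- function(path) {
  df <- jsonlite::fromJSON(path)
  lapply(seq_len(nrow(df)),
         function(i) roi_rect(df$label[i], df$x0[i], df$y0[i],
                              df$x1[i], df$y1[i]))
}

#' Evaluate artifact metrics on a set of ROIs
#'
#' Computes the Parzen-density threshold, entropy, positivity and normalized
#' positivity for each ROI and for the union of all ROIs (the pooled pixel
#' multiset), each region with its own automatically chosen threshold.
#'
#' @param img A [ct_image()].
#' @param rois List of [roi_rect()] (or logical masks).
#' @param bandwidth KDE bandwidth, HU; `NULL` for Silverman's rule per
#'   region.
#' @return A data.frame with one row per ROI plus a final `"union"` row;
#'   columns `roi, n, bandwidth, entropy, threshold, positivity, np`.
#' @export
evaluate_rois <- function(img, rois, bandwidth = NULL) {
  stopifnot(length(rois) >= 1L)
  vals <- lapply(rois, function(r) img$values[roi_mask(r, img$grid)])
  labels <- vapply(seq_along(rois), function(i) {
    r <- rois[[i]]
    if (inherits(r, "roi_rect")) r$label else paste0("roi", i)
  }, character(1))
  if (length(rois) > 1L) {
    vals <- c(vals, list(unlist(vals)))
    labels <- c(labels, "union")
  }
  rows <- lapply(seq_along(vals), function(i) {
    v <- vals[[i]]
    b <- if (is.null(bandwidth)) silverman_bandwidth(v) else bandwidth
    d <- parzen_density(v, b)
    p <- d$p[d$p > 0]
    tt <- d$h[which.max(d$p)]
    pos <- positivity(v, tt)
    data.frame(roi = labels[i], n = length(v), bandwidth = b,
               entropy = -sum(p * log(p)), threshold = tt,
               positivity = pos, np = pos / length(v))
  })
  do.call(rbind, rows)
}
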