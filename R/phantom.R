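#' Analytic phantom model
#'
#' A phantom is a z-ordered list of circular primitives (disks and annuli)
#' painted over a uniform background: later primitives overwrite earlier ones.
#' Disks and annuli emulate the air columns and polycarbonate airway tubes of a
#' commercial lung phantom; cross-sections are in-plane circles.
#'
#' @param primitives List of primitives, each a list with fields
#'   `shape` ("disk" or "annulus"), `center` (length-2, mm), `outer_radius`
#'   (mm), `inner_radius` (mm, 0 for a disk), `value` (HU).
#' @param background_value Background CT value (HU); air is -1000.
#' @param fov_radius Scan field-of-view radius (mm); all primitives must fit
#'   inside it.
#' @return An object of class `phantom_model`.
#' @export
phantom_model <- function(primitives, background_value = -1000, fov_radius = 180) {
  stopifnot(is.list(primitives), length(primitives) >= 1L)
  for (p in primitives) {
    stopifnot(p$shape %in% c("disk", "annulus"),
              length(p$center) == 2L,
              is.finite(p$value))
    ir <- if (is.null(p$inner_radius)) 0 else p$inner_radius
    if (!(p$outer_radius > ir && ir >= 0)) {
      stop("primitive radii must satisfy outer_radius > inner_radius >= 0")
    }
    if (sqrt(sum(p$center^2)) + p$outer_radius > fov_radius + 1e-9) {
      stop("primitive extends outside the scan field of view")
    }
  }
  primitives <- lapply(primitives, function(p) {
    p$inner_radius <- if (is.null(p$inner_radius)) 0 else p$inner_radius
    p
  })
  structure(list(primitives = primitives,
                 background_value = background_value,
                 fov_radius = fov_radius),
            class = "phantom_model")
}

#' @export
print.phantom_model <- function(x, ...) {
  cat(sprintf("<phantom_model: %d primitives on %g HU background, FOV r=%g mm>\n",
              length(x$primitives), x$background_value, x$fov_radius))
  invisible(x)
}

disk_prim <- function(center, radius, value) {
  list(shape = "disk", center = as.numeric(center),
       outer_radius = radius, inner_radius = 0, value = value)
}

annulus_prim <- function(center, outer_radius, inner_radius, value) {
  list(shape = "annulus", center = as.numeric(center),
       outer_radius = outer_radius, inner_radius = inner_radius, value = value)
}

#' Build a phantom from a specification
#'
#' Either constructs a phantom from an explicit primitive list (z-ordered,
#' later on top) or instantiates the `"copd_like"` preset: a soft-tissue body
#' disk enclosing a foam lung disk that carries air columns of graded radii
#' and polycarbonate airway tubes (annuli with air lumina) whose wall
#' thicknesses span 0.5-3 mm. The preset emulates the layout of a
#' commercial COPD lung phantom; it is a synthetic stand-in, not a replica.
#'
#' @param spec Either the string `"copd_like"` or a list with fields
#'   `primitives` (see [phantom_model()]) and optionally `background_value`
#'   and `fov_radius`.
#' @return A [phantom_model()].
#' @export
build_phantom <- function(spec = "copd_like") {
  if (is.character(spec) && length(spec) == 1L) {
    if (spec != "copd_like") stop("unknown phantom preset: ", spec)
    return(copd_like_phantom())
  }
  stopifnot(is.list(spec), !is.null(spec$primitives))
  phantom_model(spec$primitives,
                background_value = if (is.null(spec$background_value)) -1000 else spec$background_value,
                fov_radius = if (is.null(spec$fov_radius)) 180 else spec$fov_radius)
}

# Preset: body disk (0 HU) r=110, lung foam disk (-800 HU) r=95,
# 6 air columns (radii 1.5..6 mm) on a 55 mm ring, 6 airway tubes
# (polycarbonate +100 HU walls 0.5..3 mm, air lumen) on a 30 mm ring.
copd_like_phantom <- function() {
  prims <- list(
    disk_prim(c(0, 0), 110, 0),
    disk_prim(c(0, 0), 95, -800)
  )
  col_r <- c(1.5, 2, 3, 4, 5, 6)
  for (k in seq_along(col_r)) {
    ang <- deg2rad(60 * (k - 1) + 15)
    prims[[length(prims) + 1L]] <-
      disk_prim(55 * c(cos(ang), sin(ang)), col_r[k], -1000)
  }
  wall <- c(0.5, 1, 1.5, 2, 2.5, 3)
  lumen <- c(2, 2.5, 3, 3.5, 4, 4.5)
  for (k in seq_along(wall)) {
    ang <- deg2rad(60 * (k - 1) - 15)
    ctr <- 30 * c(cos(ang), sin(ang))
    prims[[length(prims) + 1L]] <-
      annulus_prim(ctr, lumen[k] + wall[k], lumen[k], 100)
    prims[[length(prims) + 1L]] <-
      disk_prim(ctr, lumen[k], -1000)
  }
  phantom_model(prims, background_value = -1000, fov_radius = 180)
}

#' Rasterize a phantom onto an image grid
#'
#' Paints primitives in z-order (later on top) after applying a rigid
#' displacement to every primitive. With `subsample > 1` each pixel is sampled
#' on a `subsample x subsample` sub-grid and averaged (anti-aliasing), so
#' boundary pixels take intermediate values.
#'
#' @param phantom A [phantom_model()].
#' @param grid An [image_grid()].
#' @param displacement Rigid displacement of the whole phantom, mm (x, y).
#' @param subsample Anti-aliasing factor (1 = pixel-centre sampling).
#' @return A [ct_image()] in HU.
#' @export
rasterize <- function(phantom, grid, displacement = c(0, 0), subsample = 3L) {
  subsample <- as.integer(subsample)
  stopifnot(subsample >= 1L)
  co <- grid_coords(grid)
  # sub-pixel offsets centred in the pixel
  offs <- (seq_len(subsample) - (subsample + 1) / 2) / subsample * grid$spacing
  acc <- matrix(0, grid$ny, grid$nx)
  for (oy in offs) {
    for (ox in offs) {
      xs <- co$x + ox
      ys <- co$y + oy
      img <- matrix(phantom$background_value, grid$ny, grid$nx)
      for (p in phantom$primitives) {
        cx <- p$center[1] + displacement[1]
        cy <- p$center[2] + displacement[2]
        d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
        inside <- d2 <= p$outer_radius^2
        if (p$inner_radius > 0) inside <- inside & d2 >= p$inner_radius^2
        img[inside] <- p$value
      }
      acc <- acc + img
    }
  }
  ct_image(acc / subsample^2, grid, label = "phantom")
}

# For each primitive, index of the topmost earlier primitive whose region
# fully contains it (0 = background). Primitives must be pairwise disjoint or
# nested; partial overlap is an error because paint precedence has no analytic
# line-integral form.
phantom_parents <- function(phantom) {
  prims <- phantom$primitives
  n <- length(prims)
  parent <- integer(n)
  for (i in seq_len(n)) {
    pi_ <- prims[[i]]
    parent[i] <- 0L
    for (j in seq_len(i - 1L)) {
      pj <- prims[[j]]
      d <- sqrt(sum((pi_$center - pj$center)^2))
      # containment of i's bounding disk in j's region
      contained <-
        if (pj$inner_radius > 0) {
          d - pi_$outer_radius >= pj$inner_radius - 1e-9 &&
            d + pi_$outer_radius <= pj$outer_radius + 1e-9
        } else {
          d + pi_$outer_radius <= pj$outer_radius + 1e-9
        }
      disjoint <- d >= pi_$outer_radius + pj$outer_radius - 1e-9 ||
        (pj$inner_radius > 0 && d + pi_$outer_radius <= pj$inner_radius + 1e-9) ||
        (pi_$inner_radius > 0 && d + pj$outer_radius <= pi_$inner_radius + 1e-9)
      if (contained) {
        parent[i] <- j
      } else if (!disjoint) {
        stop(sprintf(paste0("primitives %d and %d partially overlap; analytic ",
                            "projection requires disjoint or nested primitives"),
                     j, i))
      }
    }
  }
  parent
}
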