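# Shared fixtures, computed once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_cache <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

# small but well-sampled geometry for reconstruction tests
fx_geom <- function() scan_geometry()   # 736 channels, 1200 views: default scanner scale

fx_grid <- function() image_grid(128L, spacing = 360 / 128)

fx_water_disk <- function(radius = 100) {
  phantom_model(list(list(shape = "disk", center = c(0, 0),
                          outer_radius = radius, inner_radius = 0, value = 0)))
}

# static water-disk parallel sinogram (small geometry)
fx_disk_sino <- function() {
  fx_cache("disk_sino", {
    rebin_fan_to_parallel(forward_project_fan(fx_water_disk(), fx_geom()))
  })
}

# static copd-like phantom parallel sinogram (small geometry)
fx_copd_sino <- function() {
  fx_cache("copd_sino", {
    rebin_fan_to_parallel(forward_project_fan(build_phantom("copd_like"),
                                              fx_geom()))
  })
}

# central view angle of a sinogram's coverage
fx_theta_c <- function(sino) sino$angles[round(length(sino$angles) / 2)]

# smooth blob image for registration tests (deterministic)
fx_blob_image <- function(n = 128L, spacing = 2) {
  fx_cache(paste0("blobs", n), {
    grid <- image_grid(n, spacing = spacing)
    co <- grid_coords(grid)
    set.seed(42)
    img <- matrix(0, n, n)
    for (k in 1:12) {
      c0 <- stats::runif(2, -0.6, 0.6) * n * spacing / 2
      a <- stats::runif(1, 50, 300)
      s <- stats::runif(1, 4, 12)
      img <- img + a * exp(-outer((co$y - c0[2])^2, (co$x - c0[1])^2, "+") /
                             (2 * s^2))
    }
    ct_image(img, grid, label = "blobs")
  })
}

# translate an image by (dx, dy) mm via bilinear resampling
fx_translate_image <- function(img, dx, dy) {
  grid <- img$grid
  co <- grid_coords(grid)
  X <- rep(co$x, each = grid$ny)
  Y <- rep(co$y, times = grid$nx)
  v <- parmoco:::bilinear_sample(img$values, grid, X - dx, Y - dy, fill = 0)
  ct_image(matrix(v, grid$ny, grid$nx), grid, label = img$meta$label)
}
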