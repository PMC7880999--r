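test_that("ramp filter is linear, kills DC, and zero-pads correctly", {
  sino <- fx_disk_sino()
  # zero view stays zero
  z <- sino
  z$values[] <- 0
  expect_true(all(ramp_filter(z)$values == 0))

  # a DC-constant stretch integrates to ~0 after the ramp (the filter has
  # zero DC gain; only padding tail leakage remains)
  ns <- length(sino$s)
  dc <- sino
  dc$values[] <- 0
  dc$values[, (ns %/% 4):(3 * ns %/% 4)] <- 1
  for (w in c("none", "shepp_logan", "hann")) {
    fdc <- ramp_filter(dc, w)
    in_energy <- sum(dc$values[1, ]^2)
    expect_lt(abs(sum(fdc$values[1, ])), 1e-3 * in_energy)
  }

  # linearity
  s2 <- sino
  s2$values <- 3.5 * sino$values
  expect_equal(ramp_filter(s2)$values, 3.5 * ramp_filter(sino)$values,
               tolerance = 1e-12)
})

test_that("backprojection geometry behaves on degenerate inputs", {
  sino <- fx_disk_sino()
  grid <- fx_grid()
  z <- ramp_filter(sino)
  z$values[] <- 0
  img <- backproject(z, grid, views = 1:parmoco:::views_per_180(sino))
  expect_true(all(mu_from_hu(img$values) == 0))
  expect_error(backproject(z, grid, views = integer(0)), "empty")

  # single view of an impulse: a constant ridge along the ray direction
  one <- sino
  one$values[] <- 0
  v <- 200L
  jc <- which.min(abs(one$s))
  one$values[v, jc] <- 1
  ridge <- backproject(one, grid, views = v)
  mu <- mu_from_hu(ridge$values)
  th <- parmoco:::deg2rad(one$angles[v])
  co <- grid_coords(grid)
  svals <- outer(sin(th) * co$y, cos(th) * co$x, "+")
  on_ray <- abs(svals - one$s[jc]) < 0.25 * (one$s[2] - one$s[1])
  expect_gt(min(mu[on_ray]), 0.5 * max(mu))
  off_ray <- abs(svals - one$s[jc]) > 5 * (one$s[2] - one$s[1])
  expect_lt(max(abs(mu[off_ray])), 0.05 * max(mu))
})

test_that("half-scan FBP reconstructs the analytic disk", {
  sino <- fx_disk_sino()
  grid <- fx_grid()
  thc <- fx_theta_c(sino)
  img <- fbp_half(sino, grid, thc)
  co <- grid_coords(grid)
  r <- sqrt(outer(co$y^2, co$x^2, "+"))
  expect_lt(abs(mean(img$values[r < 90])), 10)

  # FBP oracle: matches the rasterized phantom off a 2-pixel edge band
  truth <- rasterize(fx_water_disk(100), grid)
  off_edge <- abs(r - 100) > 2 * grid$spacing & r < 165
  rmse <- sqrt(mean((img$values[off_edge] - truth$values[off_edge])^2))
  expect_lt(rmse, 15)

  # conjugate completeness: theta_c and theta_c + 180 agree for static data
  geom2 <- scan_geometry(n_channels = 256L, views_per_rotation = 720L,
                         n_rotations = 2L)
  sino2 <- rebin_fan_to_parallel(forward_project_fan(fx_water_disk(100),
                                                     geom2))
  thc2 <- fx_theta_c(sino2)
  ia <- fbp_half(sino2, grid, thc2)
  ib <- fbp_half(sino2, grid, thc2 + 180)
  expect_lt(max(abs(ia$values - ib$values)[r < 150]), 10)

  # linearity in the sinogram
  s3 <- sino
  s3$values <- 2 * sino$values
  img3 <- fbp_half(s3, grid, thc)
  expect_equal(mu_from_hu(img3$values), 2 * mu_from_hu(img$values),
               tolerance = 1e-9)

  # coverage gap errors
  expect_error(fbp_half(sino, grid, min(sino$angles) + 10), "covers")
})

test_that("motion raises the interior variability of a half-scan image", {
  geom <- scan_geometry(n_channels = 256L, views_per_rotation = 720L)
  grid <- image_grid(128L, spacing = 2)
  ph <- phantom_model(list(list(shape = "disk", center = c(0, 0),
                                outer_radius = 60, inner_radius = 0,
                                value = 0)))
  sino0 <- rebin_fan_to_parallel(forward_project_fan(ph, geom))
  traj <- motion_trajectory("periodic_1d", amplitude = c(20, 7.5), rpm = 15)
  sino1 <- rebin_fan_to_parallel(forward_project_fan(ph, geom, traj))
  thc <- fx_theta_c(sino0)
  i0 <- fbp_half(sino0, grid, thc)
  i1 <- fbp_half(sino1, grid, thc)
  co <- grid_coords(grid)
  r <- sqrt(outer(co$y^2, co$x^2, "+"))
  expect_gt(stats::sd(i1$values[r < 55]), stats::sd(i0$values[r < 55]))
})

test_that("conjugate PAR pair: timing, static conjugacy, partition of views", {
  sino <- fx_copd_sino()
  grid <- fx_grid()
  thc <- fx_theta_c(sino)
  pars <- reconstruct_par_pair(sino, grid, thc, segment_length = 50)

  # the two PARs are half a rotation apart, within one view duration
  dt_view <- diff(sino$view_times[1:2])
  expect_equal(pars$after$meta$time_center - pars$before$meta$time_center,
               sino$rotation_period / 2, tolerance = 2 * dt_view)
  # angular ranges centred at theta_c -/+ 90
  expect_equal(mean(pars$before$meta$angular_range), thc - 90, tolerance = 1)
  expect_equal(mean(pars$after$meta$angular_range), thc + 90, tolerance = 1)

  # static-object conjugacy: before ~ after within 2% of dynamic range
  dr <- diff(range(pars$before$values))
  expect_lt(max(abs(pars$before$values - pars$after$values)), 0.02 * dr)

  # partition of views: before + after + middle = the same-window partial
  # sum, in the linear attenuation domain, to 1e-10
  filt <- ramp_filter(sino, "hann")
  dth <- sino$angles[2] - sino$angles[1]
  n180 <- round(180 / dth)
  nL <- round(50 / dth)
  full <- parmoco:::view_window(sino, thc - 90 - 25, n180 + nL)
  segb <- full[seq_len(nL)]
  sega <- full[seq.int(length(full) - nL + 1L, length(full))]
  mid <- full[seq.int(nL + 1L, length(full) - nL)]
  bp <- function(ix) mu_from_hu(backproject(filt, grid, ix)$values)
  resid <- max(abs(bp(segb) + bp(sega) + bp(mid) - bp(full)))
  expect_lt(resid, 1e-10)

  expect_error(reconstruct_par_pair(sino, grid, thc, segment_length = -5),
               "positive")
})

test_that("rigid registration of band-passed PARs recovers the inter-PAR shift", {
  geom <- scan_geometry(n_channels = 256L, views_per_rotation = 720L)
  grid <- image_grid(128L, spacing = 2)
  ph <- build_phantom("copd_like")
  traj <- motion_trajectory("periodic_1d", amplitude = c(20, 7.5), rpm = 10)
  sino <- rebin_fan_to_parallel(forward_project_fan(ph, geom, traj))
  thc <- fx_theta_c(sino)
  pars <- reconstruct_par_pair(sino, grid, thc)
  delta <- displacement_at(traj, pars$after$meta$time_center) -
    displacement_at(traj, pars$before$meta$time_center)
  bpb <- bandpass(pars$before)
  bpa <- bandpass(pars$after)
  # rigid fit: single-level FFD with very coarse control grid acts rigidly
  fld <- register_ffd(bpb, bpa,
                      registration_params(levels = 1L, control_spacing = 260))
  smask <- abs(bpb$values) > 0.25 * max(abs(bpb$values))
  est <- c(mean(fld$dx[smask]), mean(fld$dy[smask]))
  expect_lt(sqrt(sum((est - delta)^2)), 0.5)
})

test_that("band-pass filtering removes shading and keeps structure", {
  grid <- image_grid(128L, spacing = 2)
  const <- ct_image(matrix(37, 128, 128), grid)
  expect_lt(max(abs(bandpass(const)$values)), 1e-9)

  # isolated impulse: centre-positive, surround-negative, near-zero sum
  imp <- matrix(0, 128, 128)
  imp[64, 64] <- 1
  bimp <- bandpass(ct_image(imp, grid))$values
  expect_gt(bimp[64, 64], 0)
  expect_lt(min(bimp[54:74, 54:74]), 0)
  expect_lt(abs(sum(bimp)), 1e-6)

  # low-frequency shading attenuated > 10x more than a fine-scale edge
  co <- grid_coords(grid)
  shade <- ct_image(matrix(sin(2 * pi * co$x / 600), 128, 128,
                           byrow = TRUE), grid)      # period 300 px >> sigma_c
  edge <- ct_image(matrix(sin(2 * pi * co$x / 12), 128, 128,
                          byrow = TRUE), grid)       # ~6 px half-period
  gain <- function(img) {
    ctr <- 33:96                                     # avoid boundary clipping
    max(abs(bandpass(img)$values[ctr, ctr])) / max(abs(img$values[ctr, ctr]))
  }
  expect_gt(gain(edge), 10 * gain(shade))

  expect_error(bandpass(const, sigma_fine = 8, sigma_coarse = 2))
})
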