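test_that("build_phantom constructs explicit models and the copd_like preset", {
  ph <- build_phantom(list(primitives = list(
    list(shape = "disk", center = c(0, 0), outer_radius = 100,
         inner_radius = 0, value = 0))))
  expect_length(ph$primitives, 1L)
  expect_equal(ph$background_value, -1000)

  preset <- build_phantom("copd_like")
  expect_gte(length(preset$primitives), 13L)
  for (p in preset$primitives) {
    expect_lte(sqrt(sum(p$center^2)) + p$outer_radius, 180)
  }
  # wall thicknesses of the airway tubes span at least 0.5-3 mm
  walls <- vapply(Filter(function(p) p$shape == "annulus", preset$primitives),
                  function(p) p$outer_radius - p$inner_radius, numeric(1))
  expect_gte(length(walls), 6L)
  expect_lte(min(walls), 0.5 + 1e-9)
  expect_gte(max(walls), 3 - 1e-9)
  # >= 6 air columns with distinct radii
  cols <- Filter(function(p) p$shape == "disk" && p$value <= -999 &&
                   p$outer_radius < 50, preset$primitives)
  radii <- vapply(cols, function(p) p$outer_radius, numeric(1))
  expect_gte(length(unique(radii)), 6L)

  expect_error(build_phantom("unknown_thing"), "preset")
  expect_error(phantom_model(list(list(shape = "disk", center = c(0, 0),
                                       outer_radius = 1, inner_radius = 2,
                                       value = 0))), "radii")
  expect_error(phantom_model(list(list(shape = "disk", center = c(300, 0),
                                       outer_radius = 10, inner_radius = 0,
                                       value = 0))), "field of view")
})

test_that("rasterized annulus wall carries its nominal CT value", {
  grid <- image_grid(256L, spacing = 0.1)   # fine grid around a small tube
  ph <- phantom_model(list(list(shape = "annulus", center = c(0, 0),
                                outer_radius = 5, inner_radius = 4,
                                value = 100)))
  img <- rasterize(ph, grid)
  co <- grid_coords(grid)
  r <- sqrt(outer(co$y^2, co$x^2, "+"))
  wall <- r > 4.2 & r < 4.8                  # strictly interior to the wall
  expect_equal(mean(img$values[wall]), 100, tolerance = 1e-6)
  lumen <- r < 3.8
  expect_equal(mean(img$values[lumen]), -1000, tolerance = 1e-6)
})

test_that("rasterize paints, translates and anti-aliases", {
  grid <- image_grid(128L, spacing = 2)
  ph <- fx_water_disk(50)
  img <- rasterize(ph, grid, subsample = 1L)
  co <- grid_coords(grid)
  r <- sqrt(outer(co$y^2, co$x^2, "+"))
  expect_true(all(img$values[r < 48] == 0))
  expect_true(all(img$values[r > 52] == -1000))

  shifted <- rasterize(ph, grid, displacement = c(10, 0), subsample = 1L)
  rs <- sqrt(outer(co$y^2, (co$x - 10)^2, "+"))
  expect_true(all(shifted$values[rs < 48] == 0))
  expect_true(all(shifted$values[rs > 52] == -1000))

  aa <- rasterize(ph, grid, subsample = 3L)
  edge <- abs(r - 50) < 1
  expect_true(any(aa$values[edge] > -1000 & aa$values[edge] < 0))
})

test_that("displacement_at follows the actuator model", {
  expect_equal(displacement_at(motion_trajectory("static"), 1.23), c(0, 0))
  traj <- motion_trajectory("periodic_1d", amplitude = c(20, 7.5), rpm = 5)
  expect_equal(displacement_at(traj, 0), c(0, 0))
  # quarter cycle at 5 rpm is 3 s: sinusoid extremum = the full amplitude
  expect_equal(displacement_at(traj, 3), c(20, 7.5), tolerance = 1e-12)
  expect_error(motion_trajectory("periodic_1d", rpm = -1), "rpm")

  # periodicity to 1e-12, and componentwise bound by the amplitude
  traj2 <- motion_trajectory("periodic_1d", amplitude = c(20, 7.5),
                             rpm = 12, phase0 = 0.7)
  ts <- seq(-5, 5, length.out = 101)
  d1 <- displacement_at(traj2, ts)
  d2 <- displacement_at(traj2, ts + 60 / 12)
  expect_equal(d1, d2, tolerance = 1e-12)
  expect_true(all(abs(d1[, 1]) <= 20 + 1e-12))
  expect_true(all(abs(d1[, 2]) <= 7.5 + 1e-12))
})

test_that("path_per_rotation reproduces the stroke-times-frequency conversion", {
  expect_equal(path_per_rotation(motion_trajectory("static")), 0)
  mk <- function(r) motion_trajectory("periodic_1d", amplitude = c(20, 7.5),
                                      rpm = r)
  # combined 40 x 15 mm stroke, 0.5 s rotation
  expect_equal(round(path_per_rotation(mk(5), 0.5), 1), 3.6)
  expect_equal(round(path_per_rotation(mk(10), 0.5), 1), 7.1)
  expect_equal(round(path_per_rotation(mk(15), 0.5), 1), 10.7)
  # linear in rpm
  p1 <- path_per_rotation(mk(1), 0.5)
  for (r in c(2, 7, 13)) {
    expect_equal(path_per_rotation(mk(r), 0.5), r * p1, tolerance = 1e-12)
  }
  # rpm_for_travel inverts it
  expect_equal(path_per_rotation(mk(rpm_for_travel(7.1)), 0.5), 7.1,
               tolerance = 1e-12)
})

test_that("fan projector matches closed-form chord integrals", {
  geom <- fx_geom()
  mu <- mu_from_hu(0)
  fan <- forward_project_fan(fx_water_disk(100), geom)
  # central channels of the first view straddle the diameter: both ~ 2*R*mu
  mid <- c(368L, 369L)
  expect_equal(fan$values[1, mid], rep(2 * 100 * mu, 2), tolerance = 1e-3)
  # rotational symmetry of a centred disk: all views identical
  expect_lt(max(abs(sweep(fan$values, 2, fan$values[1, ]))), 1e-9)

  # annulus: chord difference of outer and inner circles at each ray
  ann <- phantom_model(list(list(shape = "annulus", center = c(0, 0),
                                 outer_radius = 80, inner_radius = 40,
                                 value = 100)))
  fan2 <- forward_project_fan(ann, geom)
  gam <- parmoco:::deg2rad(parmoco:::channel_angles(geom))
  d <- abs(geom$source_to_iso * sin(gam))
  mu_a <- mu_from_hu(100)
  chord <- function(r) ifelse(d < r, 2 * sqrt(pmax(r^2 - d^2, 0)), 0)
  expect_equal(fan2$values[1, ], mu_a * (chord(80) - chord(40)),
               tolerance = 1e-9)

  # overlap without nesting is rejected
  bad <- phantom_model(list(
    list(shape = "disk", center = c(0, 0), outer_radius = 50,
         inner_radius = 0, value = 0),
    list(shape = "disk", center = c(40, 0), outer_radius = 50,
         inner_radius = 0, value = 100)))
  expect_error(forward_project_fan(bad, geom), "overlap")
})

test_that("rebinning reproduces the parallel Radon transform of a disk", {
  sino <- fx_disk_sino()
  mu <- mu_from_hu(0)
  pf <- 2 * mu * sqrt(pmax(100^2 - sino$s^2, 0))
  err <- abs(sweep(sino$values, 2, pf))
  expect_lt(max(err) / max(pf), 0.01)

  # conjugacy p(theta, s) = p(theta + 180, -s) for a static phantom
  sino2 <- fx_copd_sino()
  n180 <- round(180 / (sino2$angles[2] - sino2$angles[1]))
  m <- nrow(sino2$values) - n180
  a <- sino2$values[1:m, ]
  b <- sino2$values[(1 + n180):(m + n180), rev(seq_len(ncol(sino2$values)))]
  expect_lt(max(abs(a - b)) / max(sino2$values), 0.01)

  # mass conservation: total line integral constant over theta
  ds <- sino$s[2] - sino$s[1]
  mass <- rowSums(sino$values) * ds
  expect_lt(diff(range(mass)) / mean(mass), 0.005)

  # zero sinogram rebins to zero
  geom <- fx_geom()
  fan0 <- parmoco:::fan_sinogram(
    matrix(0, geom$views_per_rotation, geom$n_channels),
    parmoco:::view_schedule(geom)$beta, parmoco:::view_schedule(geom)$time,
    geom)
  expect_true(all(rebin_fan_to_parallel(fan0)$values == 0))

  # insufficient coverage errors with the angular requirement
  geom_short <- scan_geometry(n_channels = 64L, views_per_rotation = 240L)
  fan_short <- forward_project_fan(fx_water_disk(50), geom_short)
  fan_short$values <- fan_short$values[1:60, ]
  fan_short$view_angles <- fan_short$view_angles[1:60]
  fan_short$view_times <- fan_short$view_times[1:60]
  expect_error(rebin_fan_to_parallel(fan_short), "coverage")
})

test_that("projection of a displaced disk shifts the parallel peak as d.n(theta)", {
  geom <- fx_geom()
  ph <- phantom_model(list(list(shape = "disk", center = c(30, -20),
                                outer_radius = 20, inner_radius = 0,
                                value = 0)))
  sino <- rebin_fan_to_parallel(forward_project_fan(ph, geom))
  ds <- sino$s[2] - sino$s[1]
  for (v in seq(1, nrow(sino$values), by = 37)) {
    th <- parmoco:::deg2rad(sino$angles[v])
    expected_s <- 30 * cos(th) + (-20) * sin(th)
    peak_s <- sino$s[which.max(sino$values[v, ])]
    expect_lt(abs(peak_s - expected_s), ds + 1e-9)
  }
})

test_that("view times are uniform and carried through rebinning", {
  geom <- fx_geom()
  fan <- forward_project_fan(fx_water_disk(50), geom)
  dt <- diff(fan$view_times)
  expect_equal(dt, rep(geom$rotation_period / geom$views_per_rotation,
                       length(dt)), tolerance = 1e-12)
  sino <- rebin_fan_to_parallel(fan)
  expect_true(all(diff(sino$view_times) > 0))
  # parallel view at theta has the time of the fan view with beta = theta
  i <- 100L
  expect_equal(sino$view_times[i],
               stats::approx(fan$view_angles, fan$view_times,
                             xout = sino$angles[i])$y,
               tolerance = 1e-9)
})
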