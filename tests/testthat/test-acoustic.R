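test_that("element layout is deterministic and fits the published aperture", {
  geo <- make_array_geometry()
  expect_equal(geo$n_elements, 256L)
  expect_equal(geo$focal_length_mm, 120)
  # all centers on the shell (distance to focus = focal length)
  d <- sqrt(rowSums(geo$centers_mm^2))
  expect_equal(d, rep(120, 256), tolerance = 1e-12)
  # radial extent within the 13-cm aperture
  expect_lte(max(sqrt(rowSums(geo$centers_mm[, 1:2]^2))), 65)
  # normals unit length and aimed at the focus
  expect_equal(rowSums(geo$normals^2), rep(1, 256), tolerance = 1e-12)
  # same seed twice: identical layout; different seed: different
  expect_identical(make_array_geometry(seed = 7), make_array_geometry(seed = 7))
  expect_false(identical(make_array_geometry(seed = 7)$centers_mm,
                         make_array_geometry(seed = 8)$centers_mm))
  # n = 1: single on-axis element
  one <- make_array_geometry(n_elements = 1)
  expect_equal(one$centers_mm[1, ], c(0, 0, -120))
})

test_that("on-axis field of a disc matches the closed-form piston solution", {
  geo <- make_array_geometry(1, 120, 130, element_radius_mm = 4)
  med <- water_medium()
  a <- 4e-3; u0 <- 0.05; f <- 1.2
  z_mm <- seq(4, 4 * 120, length.out = 40)           # z in [a, 4F]
  pts <- cbind(0, 0, -120 + z_mm)
  p <- Mod(element_field(geo, 1, pts, f, med, u0_m_s = u0))
  k <- 2 * pi * f * 1e6 / med$sound_speed_m_s
  z <- z_mm * 1e-3
  closed <- 2 * med$density_kg_m3 * med$sound_speed_m_s * u0 *
    abs(sin(k / 2 * (sqrt(z^2 + a^2) - z)))
  keep <- closed > 0.05 * max(closed)  # relative error undefined at nulls
  expect_lt(max(abs(p - closed)[keep] / closed[keep]), 0.01)
})

test_that("fields are linear, superpose exactly, and vanish when off", {
  geo <- tiny_geometry(8)
  med <- water_medium()
  pts <- rbind(c(0, 0, 0), c(3, -2, 5), c(-10, 4, -20))
  # zero amplitude -> zero field
  off <- drive_vector(rep(0, 8), rep(0, 8), 1.2)
  expect_equal(array_field(geo, off, pts, med), complex(3))
  # doubling u0 doubles |p|
  p1 <- element_field(geo, 3, pts, 1.2, med, u0_m_s = 1)
  p2 <- element_field(geo, 3, pts, 1.2, med, u0_m_s = 2)
  expect_equal(p2, 2 * p1, tolerance = 1e-12)
  # single-active-element drive reproduces element_field
  solo <- drive_vector(as.numeric(1:8 == 3), rep(0, 8), 1.2)
  expect_equal(array_field(geo, solo, pts, med), p1, tolerance = 1e-12)
  # superposition: array = sum of per-element fields
  set.seed(42)
  ph <- runif(8, -pi, pi)
  drv <- drive_vector(rep(1, 8), ph, 1.2)
  total <- array_field(geo, drv, pts, med)
  parts <- Reduce(`+`, lapply(1:8, function(e) {
    exp(1i * ph[e]) * element_field(geo, e, pts, 1.2, med)
  }))
  expect_equal(total, parts, tolerance = 1e-10)
})

test_that("patch distances are symmetric under point/source exchange", {
  # reciprocity of the propagator: a single patch radiating to a point
  # gives the same |p| as the swapped pair
  geo <- make_array_geometry(1, 120, 130, element_radius_mm = 0.05)
  med <- water_medium()
  a <- c(0, 0, -120)   # the (tiny) element's location
  b <- c(7, -3, 12)
  p_ab <- element_field(geo, 1, matrix(b, ncol = 3), 1.2, med,
                        patch_spacing_mm = 1)
  geo2 <- geo
  geo2$centers_mm[1, ] <- b
  geo2$normals[1, ] <- (a - b) / sqrt(sum((a - b)^2))
  p_ba <- element_field(geo2, 1, matrix(a, ncol = 3), 1.2, med,
                        patch_spacing_mm = 1)
  expect_equal(Mod(p_ab), Mod(p_ba), tolerance = 1e-4)
})

test_that("steering phases vanish at the natural focus and wrap correctly", {
  geo <- make_array_geometry()
  med <- water_medium()
  ph0 <- steering_phases(geo, c(0, 0, 0), 1.2, med)
  expect_equal(ph0, rep(0, 256), tolerance = 1e-10)
  ph <- steering_phases(geo, c(10, -5, 3), 1.2, med)
  expect_true(all(ph > -pi & ph <= pi))
})

test_that("steering relocates the field maximum to the target grid cell", {
  geo <- make_array_geometry()
  med <- water_medium()
  for (target in list(c(5, 0, 0), c(0, -8, 0), c(10, 5, 0), c(15, 0, 0))) {
    drv <- steering_drive(geo, target, 1.2, med)
    g <- sim_grid(target - 5, 1, c(11L, 11L, 11L))   # 1-mm search grid
    p <- array_field(geo, drv, grid_points(g), med, patch_spacing_mm = 0.5)
    loc <- grid_points(g)[which.max(Mod(p)), ]
    expect_lte(max(abs(loc - target)), 1)  # within one grid cell
  }
})

test_that("heat deposition scales with power and peaks at the steered focus", {
  geo <- make_array_geometry()
  med <- phantom_medium()
  g <- sim_grid(c(-2, -6, -4), 1, c(9L, 9L, 9L))  # box around (2, -2, 0)
  drv <- steering_drive(geo, c(2, -2, 0), 1.2, med)
  expect_equal(heat_deposition(geo, drv, g, med, 0),
               array(0, g$dims))
  q1 <- heat_deposition(geo, drv, g, med, 40, element_model = "far_field")
  q2 <- heat_deposition(geo, drv, g, med, 80, element_model = "far_field")
  expect_equal(q2, 2 * q1, tolerance = 1e-10)
  loc <- grid_points(g)[which.max(q1), ]
  expect_lte(max(abs(loc - c(2, -2, 0))), 1)
})

test_that("hydrophone capture has the right burst support and averaging gain", {
  geo <- make_array_geometry()
  # 40 cycles at 1.2 MHz: 33.33-us support
  rec <- hydrophone_record(geo, 10, c(0, 0, 0), frequency_mhz = 1.2,
                           cycles = 40, prf_hz = 40, averages = 64,
                           noise_sd = 0)
  expect_equal(rec$burst_duration_s, 40 / 1.2e6, tolerance = 1e-12)
  support <- range(rec$time_s[abs(rec$waveform_pa) > 0])
  expect_lte(support[2], 40 / 1.2e6 * (1 + 1e-6))
  # noiseless: average equals a single clean burst exactly
  expect_identical(rec$waveform_pa, rec$clean_pa)
  expect_gt(rec$summary_amplitude_pa, 0)

  # Monte-Carlo: 64 averages cut the noise sd by ~1/8 (within 20%)
  sd_resid <- vapply(1:200, function(s) {
    r <- hydrophone_record(geo, 10, c(0, 0, 0), averages = 64,
                           noise_sd = 100, seed = s)
    stats::sd(r$waveform_pa - r$clean_pa)
  }, numeric(1))
  expect_lt(abs(mean(sd_resid) - 100 / 8), 0.2 * (100 / 8))
})
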