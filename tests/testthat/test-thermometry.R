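test_that("PRFS map converts wrapped phase differences to temperature", {
  su <- aligned_setup()
  hot <- temperature_field(array(30, su$grid$dims), su$grid, 1)
  ref <- synthesize_frame(su$phantom, NULL, su$stack, su$seq)
  fr <- synthesize_frame(su$phantom, hot, su$stack, su$seq)
  m <- prfs_delta_t(fr, ref)
  # dPhi = -1.605 rad at TE 20 ms, B0 3 T -> +10.0 degC
  expect_equal(m$delta_t_c[21, 21], 10, tolerance = 1e-9)
  # identical frames: zero everywhere
  m0 <- prfs_delta_t(ref, ref)
  expect_equal(max(abs(m0$delta_t_c)), 0)
  # TE mismatch is an error
  sq2 <- su$seq; sq2$te_ms <- 16
  fr2 <- synthesize_frame(su$phantom, hot, su$stack, sq2)
  expect_error(prfs_delta_t(fr2, ref), "TE mismatch")
  # geometry mismatch is an error
  fr3 <- synthesize_frame(su$phantom, hot,
                          stack_geometry(center_mm = c(5, 0, 0)), su$seq)
  expect_error(prfs_delta_t(fr3, ref), "geometry")
})

test_that("PRFS round trip is the identity within 0.1 degC up to 15 degC", {
  su <- aligned_setup()
  for (amp in c(5, 10, 15, -10)) {
    bump <- gaussian_delta_t(su$grid, amp = amp)
    ref <- synthesize_frame(su$phantom, NULL, su$stack, su$seq)
    fr <- synthesize_frame(su$phantom, bump$field, su$stack, su$seq)
    m <- prfs_delta_t(fr, ref)
    expect_lt(max(abs(m$delta_t_c - bump$delta[, , 1])), 0.1)
  }
})

test_that("low-magnitude pixels are flagged invalid, not zeroed", {
  su <- aligned_setup()
  ph <- su$phantom
  ph$pd[1:10, , ] <- 0.001  # nearly signal-free stripe
  ref <- synthesize_frame(ph, NULL, su$stack, su$seq)
  fr <- synthesize_frame(ph, NULL, su$stack, su$seq)
  m <- prfs_delta_t(fr, ref)
  expect_false(any(m$valid[1:10, ]))
  expect_true(all(is.na(m$delta_t_c[1:10, ])))
  expect_true(all(m$valid[15:41, ]))
})

test_that("drift correction removes uniform drift exactly and is idempotent", {
  su <- aligned_setup()
  bump <- gaussian_delta_t(su$grid, amp = 10)
  roi <- matrix(FALSE, 41, 41); roi[1:8, 1:41] <- TRUE  # x <= -13 mm strip
  ref <- synthesize_frame(su$phantom, NULL, su$stack, su$seq)
  drift_rad <- rad_per_degc(20) * 0.5          # 0.5 degC-equivalent drift
  fr <- synthesize_frame(su$phantom, bump$field, su$stack, su$seq,
                         drift_phase_rad = drift_rad)
  m <- prfs_delta_t(fr, ref)
  mc <- drift_correct(m, roi)
  # corrected ROI mean is zero to machine precision
  expect_lt(abs(mean(mc$delta_t_c[roi & mc$valid])), 1e-12)
  # idempotent
  mc2 <- drift_correct(mc, roi)
  expect_equal(mc2$delta_t_c, mc$delta_t_c, tolerance = 1e-12)
  # hot spot (disjoint from the ROI, centered at 0) perturbed < 0.05 degC
  truth_peak <- max(bump$delta)
  expect_lt(abs(max(mc$delta_t_c, na.rm = TRUE) - truth_peak), 0.05)
  # zero drift: map unchanged up to the (tiny) ROI tail mean
  fr0 <- synthesize_frame(su$phantom, bump$field, su$stack, su$seq)
  m0 <- prfs_delta_t(fr0, ref)
  mc0 <- drift_correct(m0, roi)
  expect_lt(max(abs(mc0$delta_t_c - m0$delta_t_c), na.rm = TRUE), 0.05)
  # empty ROI errors
  expect_error(drift_correct(m, matrix(FALSE, 41, 41)), "empty drift ROI")
})

test_that("circular phase-domain drift ROI handles multi-radian drift", {
  su <- aligned_setup()
  bump <- gaussian_delta_t(su$grid, amp = 10)
  roi <- matrix(FALSE, 41, 41); roi[1:8, ] <- TRUE
  ref <- synthesize_frame(su$phantom, NULL, su$stack, su$seq)
  fr <- synthesize_frame(su$phantom, bump$field, su$stack, su$seq,
                         drift_phase_rad = 4.7)  # > pi: would alias in-map
  m <- prfs_delta_t(fr, ref, drift_roi = roi)
  expect_lt(max(abs(m$delta_t_c - bump$delta[, , 1])), 0.1)
})

test_that("two-echo T2 maps recover decay times and mask degeneracy", {
  # S1/S2 = e over TE 40/180 gives T2 = 140 ms
  s1 <- matrix(exp(1), 2, 2); s2 <- matrix(1, 2, 2)
  m <- t2_map(s1, s2, 40, 180)
  expect_equal(m$t2_ms, matrix(140, 2, 2))
  # S1 = S2: invalid pixel, no error
  s1[1, 1] <- 1
  m2 <- t2_map(s1, s2, 40, 180)
  expect_false(m2$valid[1, 1])
  expect_true(is.na(m2$t2_ms[1, 1]))
  # synthetic marrow: known T2 map recovered within 1% (noiseless)
  half <- 20
  grid <- sim_grid(c(-half, -half, -5), 1, c(41L, 41L, 11L))
  bp <- bone_phantom(grid, baseline_temp_c = 20)
  sq <- sequence_params(fov_mm = 41, matrix_recon = 41,
                        slice_thickness_mm = 5, te_ms = c(40, 180),
                        tr_ms = 2400, dynamic_time_s = 9.7)
  fr <- synthesize_frame(bp, NULL, stack_geometry(), sq)
  rec <- t2_map(fr)
  marrow <- matrix(sqrt(outer(grid_axes(grid)[[1]]^2,
                              grid_axes(grid)[[2]]^2, "+")) <= 8, 41, 41)
  expect_lt(max(abs(rec$t2_ms[marrow] - 120) / 120), 0.01)
})

test_that("T2 change converts to temperature via the fat calibration slope", {
  t2 <- matrix(c(220, 120), 1, 2)
  t2ref <- matrix(120, 1, 2)
  m <- t2_to_temp(t2, t2ref, slope_ms_per_c = 20)
  expect_equal(m$delta_t_c, matrix(c(5, 0), 1, 2))  # 100 ms / 20 ms/degC
})

test_that("injected T2-temperature slope is recovered within 5% at SNR 50", {
  half <- 15
  grid <- sim_grid(c(-half, -half, -4), 1, c(31L, 31L, 9L))
  bp <- bone_phantom(grid, r_marrow_mm = 8, r_cortical_mm = 12,
                     marrow_slope_ms_per_c = 20, baseline_temp_c = 20)
  sq <- sequence_params(fov_mm = 31, matrix_recon = 31,
                        slice_thickness_mm = 5, te_ms = c(40, 180),
                        tr_ms = 2400, dynamic_time_s = 9.7)
  st <- stack_geometry()
  # marrow magnitude ~ exp(-40/120) = 0.72; SNR 50 on that signal
  noise <- 0.72 / 50
  ref <- synthesize_frame(bp, NULL, st, sq, noise_sd = noise, seed = 100)
  t2_ref <- t2_map(ref)
  marrow <- matrix(sqrt(outer(grid_axes(grid)[[1]]^2,
                              grid_axes(grid)[[2]]^2, "+")) <= 6, 31, 31)
  dts <- seq(1, 5, by = 1)   # simulated heat-up, known temperatures
  mean_dt2 <- vapply(seq_along(dts), function(i) {
    hot <- temperature_field(array(20 + dts[i], grid$dims), grid, i)
    fr <- synthesize_frame(bp, hot, st, sq, noise_sd = noise, seed = 200 + i)
    rec <- t2_map(fr)
    sel <- marrow & rec$valid & t2_ref$valid
    mean(rec$t2_ms[sel] - t2_ref$t2_ms[sel])
  }, numeric(1))
  slope_hat <- stats::coef(stats::lm(mean_dt2 ~ dts))[["dts"]]
  expect_lt(abs(slope_hat - 20) / 20, 0.05)
})

test_that("max projection is per-pixel, commutative and monotone", {
  mk <- function(v, valid = TRUE) {
    sonasim:::new_temperature_map(matrix(v, 2, 2),
                                  matrix(valid, 2, 2), 0, 0)
  }
  a <- mk(c(1, 5, 2, 0)); b <- mk(c(3, 1, 2, -1))
  expect_equal(max_projection(list(a))$delta_t_c, a$delta_t_c)  # identity
  ab <- max_projection(list(a, b))
  expect_equal(ab$delta_t_c, matrix(c(3, 5, 2, 0), 2, 2))
  # order-independent
  expect_equal(max_projection(list(b, a))$delta_t_c, ab$delta_t_c)
  # disjoint hot spots in different dynamics both survive
  h1 <- mk(c(9, 0, 0, 0)); h2 <- mk(c(0, 0, 0, 9))
  both <- max_projection(list(h1, h2))
  expect_equal(both$delta_t_c[1, 1], 9)
  expect_equal(both$delta_t_c[2, 2], 9)
  # monotone: adding a dynamic never decreases any pixel
  more <- max_projection(list(a, b, mk(c(-5, -5, -5, -5))))
  expect_true(all(more$delta_t_c >= ab$delta_t_c))
  # invalid pixels ignored, not treated as zero
  c1 <- mk(c(-3, -3, -3, -3))
  c2 <- sonasim:::new_temperature_map(matrix(0, 2, 2), matrix(FALSE, 2, 2), 0, 0)
  mc <- max_projection(list(c1, c2))
  expect_equal(mc$delta_t_c, matrix(-3, 2, 2))
})
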