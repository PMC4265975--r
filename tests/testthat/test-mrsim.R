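test_that("sequence and stack constructors enforce their invariants", {
  expect_error(sequence_params(fov_mm = 200, matrix_recon = 224,
                               slice_thickness_mm = 7, te_ms = 40, tr_ms = 30,
                               dynamic_time_s = 0.59), "te_ms")
  sq <- sequence_params(fov_mm = 200, matrix_recon = 224,
                        slice_thickness_mm = 7, te_ms = 20, tr_ms = 30,
                        dynamic_time_s = 0.59)
  expect_equal(sq$pixel_mm, 200 / 224)
  expect_error(stack_geometry(axes = matrix(c(1, 0, 0, 1, 1, 0, 0, 0, 1),
                                            3, byrow = TRUE)), "orthonormal")
  # left-handed triads rejected
  expect_error(stack_geometry(axes = diag(c(1, 1, -1))), "right-handed")
})

test_that("synthesized phase encodes PRFS temperature in water only", {
  su <- aligned_setup()
  # closed form: 2*pi*gamma*B0*alpha*TE * dT = -1.605 rad at dT = 10 degC
  expect_equal(rad_per_degc(20) * 10, -1.60503, tolerance = 1e-4)
  hot <- temperature_field(array(30, su$grid$dims), su$grid, 1)  # +10 degC
  fr <- synthesize_frame(su$phantom, hot, su$stack, su$seq)
  expect_equal(fr$phase_rad[21, 21], -1.60503, tolerance = 1e-4)
  # dT = 0, drift = 0: zero phase wherever there is water signal
  fr0 <- synthesize_frame(su$phantom, NULL, su$stack, su$seq)
  expect_equal(max(abs(fr0$phase_rad)), 0)
  # fat (water_fraction ~ 0) carries no PRFS phase but does change T2
  bp <- bone_phantom(su$grid, marrow_slope_ms_per_c = 20, baseline_temp_c = 20)
  sq2 <- sequence_params(fov_mm = 41, matrix_recon = 41,
                         slice_thickness_mm = 5, te_ms = c(40, 180),
                         tr_ms = 2400, dynamic_time_s = 9.7)
  hot5 <- temperature_field(array(25, su$grid$dims), su$grid, 1)  # +5 degC
  frb <- synthesize_frame(bp, hot5, su$stack, sq2)
  fr0b <- synthesize_frame(bp, NULL, su$stack, sq2)
  # marrow center: phase ~ 0 despite heating (only 5% water)
  expect_lt(abs(frb$phase_rad[21, 21]), 0.1 * abs(rad_per_degc(40) * 5))
  # marrow T2 rose by slope * dT = 100 ms: check via the two-echo ratio
  t2_hot <- t2_map(frb)$t2_ms[21, 21]
  t2_ref <- t2_map(fr0b)$t2_ms[21, 21]
  expect_equal(t2_hot - t2_ref, 100, tolerance = 1e-6)
  # slice far outside the phantom: frame of zeros, not an error
  far <- stack_geometry(center_mm = c(0, 0, 500))
  fr_far <- synthesize_frame(su$phantom, NULL, far, su$seq)
  expect_equal(max(fr_far$magnitude[[1]]), 0)
})

test_that("noiseless synthesis is deterministic; phase stays in (-pi, pi]", {
  su <- aligned_setup()
  hot <- gaussian_delta_t(su$grid, amp = 25)$field  # forces phase wrapping
  f1 <- synthesize_frame(su$phantom, hot, su$stack, su$seq)
  f2 <- synthesize_frame(su$phantom, hot, su$stack, su$seq)
  expect_identical(f1, f2)
  expect_true(all(f1$phase_rad > -pi & f1$phase_rad <= pi))
  # seeded noise is reproducible
  n1 <- synthesize_frame(su$phantom, hot, su$stack, su$seq, noise_sd = 0.02,
                         seed = 5)
  n2 <- synthesize_frame(su$phantom, hot, su$stack, su$seq, noise_sd = 0.02,
                         seed = 5)
  expect_identical(n1, n2)
})

test_that("stream semantics: FIFO, queue length, multiple subscribers", {
  su <- aligned_setup(n_xy = 21L, n_z = 5L)
  sc <- VirtualScanner$new(su$phantom, su$seq, su$stack, noise_sd = 0)
  expect_error(sc$query_new_image("nope"), "subscribed")
  h1 <- sc$subscribe()
  h2 <- sc$subscribe()
  dt <- su$seq$dynamic_time_s
  sc$advance(3.2 * dt)  # three frames produced
  # both subscribers receive every frame, oldest first
  d1 <- c(sc$query_new_image(h1)$dynamic, sc$query_new_image(h1)$dynamic,
          sc$query_new_image(h1)$dynamic)
  expect_equal(d1, 0:2)
  expect_null(sc$query_new_image(h1))  # empty queue -> NULL, non-blocking
  expect_equal(sc$queue_length(h2), 3)
  expect_equal(sc$query_new_image(h2)$dynamic, 0L)
  # continuous querying keeps the queue at length <= 1
  qlen <- integer(0)
  for (i in 1:6) {
    sc$advance(dt)
    qlen <- c(qlen, sc$queue_length(h1))
    sc$query_new_image(h1)
  }
  expect_true(all(qlen <= 1))
  # unsubscribe stops delivery
  sc$unsubscribe(h2)
  expect_error(sc$query_new_image(h2), "subscribed")
})

test_that("timestamps advance by the dynamic time; pause/resume has no gaps", {
  su <- aligned_setup(n_xy = 21L, n_z = 5L)
  sc <- VirtualScanner$new(su$phantom, su$seq, su$stack)
  h <- sc$subscribe()
  dt <- su$seq$dynamic_time_s
  sc$advance(5.5 * dt)
  ts <- c(); dyn <- c()
  while (!is.null(fr <- sc$query_new_image(h))) {
    ts <- c(ts, fr$acq_time_s); dyn <- c(dyn, fr$dynamic)
  }
  expect_equal(diff(ts), rep(dt, length(ts) - 1), tolerance = 1e-12)
  last_dyn <- tail(dyn, 1)
  sc$pause_scan()
  sc$pause_scan()              # pausing twice is a no-op
  sc$advance(10)               # no frames while paused
  expect_equal(sc$queue_length(h), 0)
  sc$resume_scan()
  sc$advance(1.5 * dt)
  fr <- sc$query_new_image(h)
  expect_equal(fr$dynamic, last_dyn + 1L)  # numbering continues gap-free
})

test_that("stack repositioning takes effect next frame and shifts content", {
  su <- aligned_setup()
  bump <- gaussian_delta_t(su$grid, amp = 10, sigma_mm = 3)
  sc <- VirtualScanner$new(su$phantom, su$seq, su$stack,
                           temp_provider = function(t) bump$field,
                           drift_rad_per_dynamic = 0)
  h <- sc$subscribe()
  dt <- su$seq$dynamic_time_s
  sc$advance(dt)
  f0 <- sc$query_new_image(h)
  # identity update: identical frames
  sc$set_stack_geometry(su$stack)
  sc$advance(dt)
  f0b <- sc$query_new_image(h)
  expect_equal(f0b$phase_rad, f0$phase_rad)
  # +10 mm LR shift relocates the hot spot by 10 pixels (1-mm pixels)
  sc$set_stack_geometry(stack_geometry(center_mm = c(10, 0, 0)))
  sc$advance(dt)
  f1 <- sc$query_new_image(h)
  i0 <- which(f0$phase_rad == min(f0$phase_rad), arr.ind = TRUE)
  i1 <- which(f1$phase_rad == min(f1$phase_rad), arr.ind = TRUE)
  expect_equal(as.integer(i1[1, 1] - i0[1, 1]), -10L)  # content moves opposite
  expect_equal(as.integer(i1[1, 2]), as.integer(i0[1, 2]))
})

test_that("volumetric acquisition orders frames by type, stack, slice", {
  su <- aligned_setup(n_xy = 21L, n_z = 11L)
  stacks <- list(stack_geometry(n_slices = 3L, slice_spacing_mm = 2),
                 stack_geometry(center_mm = c(0, 0, 2), n_slices = 3L,
                                slice_spacing_mm = 2))
  sc <- VirtualScanner$new(su$phantom, su$seq, stacks,
                           image_types = c("T1W", "T2W"))
  h <- sc$subscribe()
  vol <- sc$acquire_volume(h)
  expect_length(vol, 12)  # 2 types x 2 stacks x 3 slices
  key <- data.frame(type = vapply(vol, `[[`, character(1), "image_type"),
                    stack = vapply(vol, `[[`, integer(1), "stack_id"),
                    slice = vapply(vol, `[[`, integer(1), "slice"))
  expect_false(is.unsorted(key$type))
  for (ty in unique(key$type)) {
    sub <- key[key$type == ty, ]
    expect_false(is.unsorted(sub$stack))
    for (st in unique(sub$stack)) {
      expect_equal(sub$slice[sub$stack == st], 1:3)
    }
  }
  # stable under repeated acquisition
  vol2 <- sc$acquire_volume(h)
  expect_equal(lapply(vol2, `[[`, "slice"), lapply(vol, `[[`, "slice"))
  # single slice: singleton
  sc1 <- VirtualScanner$new(su$phantom, su$seq, stack_geometry())
  h1 <- sc1$subscribe()
  expect_length(sc1$acquire_volume(h1), 1)
})
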