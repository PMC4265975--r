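test_that("exposure builders validate physics parameters and carry attributes", {
  tr <- line_trajectory(c(-9, 0, 0), c(9, 0, 0), 2, 25)
  expect_equal(nrow(tr$points), 10)          # 18 mm at 2-mm steps, inclusive
  expect_equal(tr$interval_ms, 25)

  cmd <- build_continuous_exposure(80, 1.2, tr, 8)
  expect_s3_class(cmd, "hifu_command")
  expect_equal(cmd$kind, "continuous_exposure")
  expect_equal(cmd$attributes$acoustic_power_w, 80)
  expect_equal(cmd$attributes$duration_s, 8)

  static <- build_continuous_exposure(10, 1.2, NULL, 5)
  expect_null(static$attributes$trajectory)

  expect_error(build_continuous_exposure(0, 1.2, NULL, 5), "acoustic_power_w")
  expect_error(build_continuous_exposure(10, 1.2, NULL, 0), "duration_s")
  expect_warning(build_continuous_exposure(10, 3, NULL, 5), "band")
})

test_that("pulsed exposure burst arithmetic matches direct enumeration", {
  duty <- 40 / 1.2e6 * 40
  cmd <- build_pulsed_exposure(50, 1.2, duty, prf_hz = 40,
                               cycles_per_burst = 40, duration_s = 1.8)
  # 40 cycles at 1.2 MHz
  expect_equal(burst_duration_s(cmd), 40 / 1.2e6, tolerance = 1e-12)
  expect_equal(burst_duration_s(cmd) * 1e6, 33.3333, tolerance = 1e-4)
  # direct enumeration (integer ms): bursts start every 25 ms before 1800 ms
  expect_equal(n_bursts(cmd), sum((0:200) * 25L < 1800L))
  expect_equal(n_bursts(cmd), 72L)
  expect_error(build_pulsed_exposure(50, 1.2, 1.2, 40, 40, duration_s = 1),
               "duty_cycle")
  # duty 1 is the continuous limit and is allowed
  expect_silent(build_pulsed_exposure(50, 1.2, 1, 40, 40, duration_s = 1))
})

test_that("move commands respect mechanical limits and name the axis", {
  ok <- build_move(c(-37.5, 0, 0))
  expect_equal(ok$attributes$position_mm, c(-37.5, 0, 0))
  expect_silent(build_move(c(0, 0, 0), 0, 0))  # no-op move is valid
  expect_error(build_move(c(0, 150, 0)), "position_mm\\[y\\]")
  expect_error(build_move(c(0, 0, 0), rot_lr_deg = 45), "rot_lr_deg")
})

test_that("pause and rnd builders cover their degenerate cases", {
  expect_equal(build_pause(2)$attributes$duration_s, 2)
  expect_true(build_pause(wait_for_previous = TRUE)$attributes$wait_for_previous)
  expect_equal(build_pause(0)$attributes$duration_s, 0)
  expect_error(build_pause(), "duration_s")

  m <- single_element_mask(7, 256)
  cmd <- build_rnd(m)
  expect_equal(sum(cmd$attributes$active_mask), 1)
  expect_null(cmd$attributes$phases_rad)
  full <- build_rnd(rep(TRUE, 256), phases_rad = rep(0, 256))
  expect_equal(full$attributes$phases_rad, rep(0, 256))
  expect_error(build_rnd(rep(TRUE, 255)), "active_mask")
  expect_error(build_rnd(rep(TRUE, 256), amplitudes = rep(2, 256)),
               "amplitudes")
})

test_that("protocol assembly reindexes, validates ordering, and is idempotent", {
  cmds <- list(build_pause(1, time_index_s = 0),
               build_continuous_exposure(10, 1.2, NULL, 5, time_index_s = 1),
               build_pause(Inf, time_index_s = 6))
  p <- assemble_protocol("Protocol_1", cmds)
  expect_equal(vapply(p$commands, `[[`, integer(1), "index"), 0:2)
  p2 <- assemble_protocol(p$identifier, p)
  expect_identical(p, p2)
  # builders never mutate inputs: originals keep NA index
  expect_true(is.na(cmds[[1]]$index))
  # equal inputs compare equal
  expect_identical(demo_protocol(), demo_protocol())

  expect_error(assemble_protocol("", cmds), "identifier")
  expect_error(assemble_protocol("P", list()), "commands")
  bad <- list(build_pause(1, time_index_s = 5), build_pause(1, time_index_s = 2))
  expect_error(assemble_protocol("P", bad), "non-decreasing")
})

test_that("modifications validate positions and attributes against the target", {
  p <- demo_protocol()
  m <- build_modification("Mod_1", "Protocol_1",
                          edits = list(list(position = 1, attribute =
                                              "acoustic_power_w", value = 20)),
                          protocol = p)
  p2 <- apply_modification(p, m)
  expect_equal(p2$commands[[2]]$attributes$acoustic_power_w, 20)
  expect_equal(p$commands[[2]]$attributes$acoustic_power_w, 10)  # pure

  expect_error(build_modification("M", "Protocol_1",
                                  edits = list(list(position = 1,
                                                    attribute = "nonexistent",
                                                    value = 1)),
                                  protocol = p), "no attribute")
  expect_error(build_modification("M", "Protocol_1", goto_position = 9,
                                  protocol = p), "goto_position")
  expect_error(apply_modification(p, build_modification("M", "Other")),
               "targets protocol")
})

test_that("five-step fixture protocols match their published shape", {
  hp <- hydrophone_protocol(3, 256)
  expect_equal(length(hp$commands), 5)
  expect_equal(vapply(hp$commands, `[[`, character(1), "kind"),
               c("rnd", "rnd", "pulsed_exposure", "pause", "pause"))
  expect_equal(hp$commands[[3]]$attributes$duration_s, 1.8)

  pat <- generate_hifu_pattern()
  lp <- hifu_letter_protocol(pat, 1)
  expect_equal(vapply(lp$commands, `[[`, character(1), "kind"),
               c("move_transducer", "pause", "continuous_exposure",
                 "pause", "pause"))
  expect_equal(lp$commands[[2]]$attributes$duration_s, 2)
  expect_equal(lp$commands[[3]]$attributes$acoustic_power_w, 80)
  expect_equal(nrow(lp$commands[[3]]$attributes$trajectory$points), 10)
})

test_that("JSON serialization round-trips protocols and modifications", {
  pat <- generate_hifu_pattern()
  for (p in list(hydrophone_protocol(5, 256), hifu_letter_protocol(pat, 4),
                 demo_protocol())) {
    expect_equal(hifu_from_json(hifu_to_json(p)), p)
  }
  m <- build_modification("Mod_1", "HIFU_Pattern",
                          edits = list(list(position = 2L,
                                            attribute = "trajectory",
                                            value = segment_trajectory(pat, 5))),
                          goto_position = 2L)
  expect_equal(hifu_from_json(hifu_to_json(m)), m)

  # file round trip
  path <- tempfile(fileext = ".json")
  write_hifu_json(demo_protocol(), path)
  expect_equal(read_hifu_json(path), demo_protocol())
})

test_that("hand-written minimal JSON parses; malformed JSON reports a path", {
  txt <- '{"schema": "sonasim-protocol/1", "identifier": "Hand",
           "commands": [
             {"index": 0, "time_index_s": 0, "kind": "pause",
              "attributes": {"duration_s": 2, "wait_for_previous": false}},
             {"index": 1, "time_index_s": 0, "kind": "continuous_exposure",
              "attributes": {"acoustic_power_w": 80, "frequency_mhz": 1.2,
                             "trajectory": null, "duration_s": 8}}]}'
  p <- hifu_from_json(txt)
  expect_equal(p$identifier, "Hand")
  expect_equal(p$commands[[2]]$attributes$acoustic_power_w, 80)

  expect_error(hifu_from_json('{"schema": "sonasim-protocol/1"'), "parse error")
  expect_error(hifu_from_json('{"schema": "bogus/9"}'), "schema")
  expect_error(hifu_from_json('{"schema": "sonasim-protocol/1",
    "identifier": "X", "commands": [{"index": 0, "time_index_s": 0,
    "kind": "teleport", "attributes": {}}]}'), "commands\\[0\\]")
})
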