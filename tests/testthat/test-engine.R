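test_that("execute/advance dispatches commands at their boundaries", {
  eng <- HifuEngine$new(n_elements = 16)
  expect_equal(eng$query_status()$protocol_state, "idle")
  expect_equal(eng$query_status()$forward_power_w, 0)

  eng$execute_protocol(demo_protocol(power = 10, dur = 5))
  expect_error(eng$execute_protocol(demo_protocol()), "busy")

  expect_length(eng$advance_clock(0), 0)  # dt = 0 emits nothing

  ev <- eng$advance_clock(1)  # crosses the 1-s pause boundary
  types <- vapply(ev, `[[`, character(1), "type")
  expect_true("command_finished" %in% types)   # pause done
  expect_true("exposure_on" %in% types)        # exposure starts at t = 1

  s <- eng$query_status()
  expect_true(s$ultrasound_on)
  expect_equal(s$forward_power_w, 10)
  expect_equal(s$reflected_power_w, 0.2)       # 2% reflected fraction
  expect_lte(s$reflected_power_w, s$forward_power_w)
  expect_equal(s$current_time_index_s, 1)

  eng$advance_clock(5)                         # exposure ends at t = 6
  s2 <- eng$query_status()
  expect_false(s2$ultrasound_on)
  expect_equal(s2$forward_power_w, 0)
  expect_equal(s2$protocol_state, "running")   # idling at the Inf pause
  expect_equal(s2$current_command_position, 3L)
})

test_that("exposure on/off status matches the 1.8-s pulsed protocol timing", {
  eng <- HifuEngine$new(n_elements = 8)
  eng$execute_protocol(hydrophone_protocol(2, 8))
  eng$advance_clock(0.9)
  expect_true(eng$query_status()$ultrasound_on)   # mid-exposure
  eng$advance_clock(0.9)                          # t = 1.8
  expect_false(eng$query_status()$ultrasound_on)  # off after 1.8 s
  # pulsed forward power is duty-cycle averaged
  eng2 <- HifuEngine$new(n_elements = 8)
  eng2$execute_protocol(hydrophone_protocol(2, 8))
  eng2$advance_clock(0.9)
  duty <- 40 / 1.2e6 * 40
  expect_equal(eng2$query_status()$forward_power_w, 50 * duty)
})

test_that("transducer motion runs at finite speed with moving status", {
  eng <- HifuEngine$new(move_speed_mm_s = 5, n_elements = 8)
  eng$execute_protocol(assemble_protocol("Move", list(
    build_move(c(10, 0, 0)), build_pause(Inf))))
  eng$advance_clock(1)
  s <- eng$query_status()
  expect_true(s$transducer_moving)
  expect_equal(s$transducer_position_mm, c(5, 0, 0))  # halfway at 5 mm/s
  eng$advance_clock(1.5)
  s2 <- eng$query_status()
  expect_false(s2$transducer_moving)
  expect_equal(s2$transducer_position_mm, c(10, 0, 0))
  types <- vapply(eng$event_log(), `[[`, character(1), "type")
  expect_true(all(c("move_started", "move_finished") %in% types))
})

test_that("live modification changes emitted power and goto restarts", {
  eng <- HifuEngine$new(n_elements = 8)
  eng$execute_protocol(demo_protocol(power = 10, dur = 5))
  eng$advance_clock(2)  # mid-exposure
  expect_equal(eng$query_status()$forward_power_w, 10)
  eng$execute_modification(build_modification(
    "UpdateExposure", "Protocol_1",
    edits = list(list(position = 1, attribute = "acoustic_power_w",
                      value = 20))))
  expect_equal(eng$query_status()$forward_power_w, 20)  # next tick sees 20

  # goto rebases the target's time index to "now" and restarts
  eng$execute_modification(build_modification(
    "Restart", "Protocol_1", goto_position = 0L))
  eng$advance_clock(0.5)
  s <- eng$query_status()
  expect_equal(s$current_command_position, 0L)  # back in the initial pause
  expect_false(s$ultrasound_on)
  eng$advance_clock(1)
  expect_true(eng$query_status()$ultrasound_on)  # exposure re-entered

  expect_error(eng$execute_modification(build_modification("X", "Nope")),
               "unknown target")
  expect_error(eng$execute_modification(build_modification(
    "X", "Protocol_1", goto_position = 42L)), "goto")
  expect_error(eng$execute_modification(build_modification(
    "X", "Protocol_1",
    edits = list(list(position = 1, attribute = "kind", value = "pause")))),
    "kind")
})

test_that("modification application is atomic across a snapshot", {
  eng <- HifuEngine$new(n_elements = 8)
  eng$execute_protocol(demo_protocol(power = 10, dur = 5))
  eng$advance_clock(2)
  # an invalid edit in a two-edit modification must leave both untouched
  expect_error(eng$execute_modification(build_modification(
    "Bad", "Protocol_1",
    edits = list(list(position = 1, attribute = "acoustic_power_w", value = 20),
                 list(position = 1, attribute = "bogus", value = 1)))))
  expect_equal(eng$query_status()$forward_power_w, 10)
})

test_that("identical inputs give identical event logs (determinism)", {
  run_once <- function() {
    eng <- HifuEngine$new(n_elements = 8)
    eng$execute_protocol(hydrophone_protocol(1, 8))
    for (i in 1:25) {
      eng$advance_clock(0.1)
      eng$query_status()
    }
    eng$execute_modification(build_modification(
      "Next", "Hydrophone_Scan",
      edits = list(list(position = 1, attribute = "active_mask",
                        value = single_element_mask(2, 8))),
      goto_position = 0L))
    for (i in 1:25) eng$advance_clock(0.1)
    eng$event_log()
  }
  expect_identical(run_once(), run_once())
})

test_that("status tracks exposure intervals of the modified protocol", {
  # ultrasound_on must equal membership of the clock in an exposure window
  eng <- HifuEngine$new(n_elements = 8)
  eng$execute_protocol(demo_protocol(power = 10, dur = 5))  # exposure [1, 6)
  on <- logical(0)
  for (i in 1:70) {
    eng$advance_clock(0.1)
    on <- c(on, eng$query_status()$ultrasound_on)
  }
  t <- (1:70) * 0.1
  expect_equal(on, t >= 1 & t < 6, tolerance = 0)
  # event times never decrease
  times <- vapply(eng$event_log(), `[[`, numeric(1), "time")
  expect_true(all(diff(times) >= 0))
})
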