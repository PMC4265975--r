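ENGINE_EPS <- 1e-9

#' Protocol execution engine (virtual MR-HIFU device)
#'
#' Executes one treatment protocol at a time on a simulated device clock,
#' applies modifications in real time, and answers status queries. The
#' simulated clock ([advance_clock()][HifuEngine]) is the primary time base,
#' which makes every run exactly reproducible: identical (protocol,
#' modification schedule, clock steps) yield identical event logs.
#'
#' Commands are dispatched in index order; command `i` starts at
#' `max(end of command i-1, time_index + offset)` where the offset rebases
#' protocol time to the engine clock (it is reset by a goto modification, so
#' "go to step 1" replays the protocol from "now"). Transducer motion runs
#' at a finite configured speed so the moving/idle indicator is meaningful.
#'
#' @section Events:
#' The log records `command_started`, `command_finished`, `exposure_on`,
#' `exposure_off`, `move_started`, `move_finished`, `modification_applied`
#' and (for synchronization audits) `status_query`, each with a `time` and a
#' `detail` record. Event times are non-decreasing.
#'
#' @export
HifuEngine <- R6::R6Class("HifuEngine",
  public = list(
    #' @field config engine configuration (speeds, reflected-power fraction).
    config = NULL,

    #' @description Create an engine.
    #' @param move_speed_mm_s mechanical translation speed (mm/s).
    #' @param rot_speed_deg_s rotation speed (deg/s).
    #' @param reflected_fraction reflected power as a fraction of forward.
    #' @param n_elements transducer element count.
    initialize = function(move_speed_mm_s = 5, rot_speed_deg_s = 10,
                          reflected_fraction = 0.02,
                          n_elements = SONASIM_N_ELEMENTS) {
      self$config <- list(move_speed_mm_s = move_speed_mm_s,
                          rot_speed_deg_s = rot_speed_deg_s,
                          reflected_fraction = reflected_fraction,
                          n_elements = as.integer(n_elements))
      private$mask <- rep(TRUE, n_elements)
      invisible(self)
    },

    #' @description Start executing a protocol. Only one protocol can run at
    #'   a time; a second concurrent execute is a busy error.
    #' @param protocol a `hifu_protocol`.
    execute_protocol = function(protocol) {
      stopifnot(inherits(protocol, "hifu_protocol"))
      if (private$state == "running") {
        stop("engine busy: only one protocol can be executed at a time",
             call. = FALSE)
      }
      private$protocol <- assemble_protocol(protocol$identifier, protocol)
      private$state <- "running"
      private$start_time <- private$time
      private$offset <- private$time
      private$pos <- -1L
      private$active <- FALSE
      invisible(self)
    },

    #' @description Apply a modification to the currently loaded protocol.
    #'   Edits are atomic; with `goto_position` set, execution resumes at
    #'   that command with its time index rebased to the current clock.
    #' @param mod a `hifu_modification`.
    execute_modification = function(mod) {
      stopifnot(inherits(mod, "hifu_modification"))
      if (is.null(private$protocol)) {
        stop("no protocol loaded", call. = FALSE)
      }
      if (!identical(mod$target_protocol, private$protocol$identifier)) {
        stop(sprintf("unknown target protocol '%s' (loaded: '%s')",
                     mod$target_protocol, private$protocol$identifier),
             call. = FALSE)
      }
      for (e in mod$edits) {
        if (identical(e$attribute, "kind")) {
          stop("modifications may adjust parameters only; changing a command's kind is not allowed",
               call. = FALSE)
        }
      }
      # all-or-nothing: apply to a copy, then swap
      private$protocol <- apply_modification(private$protocol, mod)
      private$log_event("modification_applied",
                        list(identifier = mod$identifier,
                             n_edits = length(mod$edits),
                             goto_position = mod$goto_position))
      if (private$active) {
        # re-derive the active command's end from its (possibly edited) attrs
        cmd <- private$protocol$commands[[private$pos + 1L]]
        private$cmd_end <- private$cmd_start + private$cmd_duration(cmd)
      }
      if (!is.null(mod$goto_position)) {
        n <- length(private$protocol$commands)
        if (mod$goto_position < 0L || mod$goto_position >= n) {
          stop(sprintf("goto position %d does not exist (0..%d)",
                       mod$goto_position, n - 1L), call. = FALSE)
        }
        if (private$active) private$interrupt_current()
        tgt <- private$protocol$commands[[mod$goto_position + 1L]]
        private$offset <- private$time - tgt$time_index_s
        private$pos <- mod$goto_position - 1L
        private$active <- FALSE
        private$state <- "running"
      }
      invisible(self)
    },

    #' @description Query device status. A pure read of the engine state at
    #'   the current clock; never blocks execution.
    #' @return A `status_snapshot` list: `transducer_position_mm`,
    #'   `rotation_deg`, `forward_power_w`, `reflected_power_w`,
    #'   `ultrasound_on`, `transducer_moving`, `current_time_index_s`,
    #'   `current_command_position`, `protocol_state`.
    query_status = function() {
      on <- private$ultrasound_on()
      fwd <- 0
      if (on) {
        at <- private$current_cmd()$attributes
        fwd <- at$acoustic_power_w
        if (!is.null(at$duty_cycle)) fwd <- fwd * at$duty_cycle
      }
      snap <- structure(list(
        transducer_position_mm = private$position_at(private$time),
        rotation_deg = private$angles_at(private$time),
        forward_power_w = fwd,
        reflected_power_w = fwd * self$config$reflected_fraction,
        ultrasound_on = on,
        transducer_moving = private$moving(),
        current_time_index_s =
          if (private$state %in% c("running", "finished"))
            private$time - private$start_time else NA_real_,
        current_command_position =
          if (private$state == "running" && private$pos >= 0L)
            private$pos else NA_integer_,
        protocol_state = private$state), class = "status_snapshot")
      private$log_event("status_query", list(ultrasound_on = on))
      snap
    },

    #' @description Advance the simulated clock, dispatching command
    #'   boundaries in order. Deterministic; `dt = 0` emits nothing.
    #' @param dt seconds to advance (>= 0).
    #' @return Invisibly, the events emitted during this call.
    advance_clock = function(dt) {
      check_scalar_number(dt, "dt", nonneg = TRUE)
      if (dt == 0) return(invisible(list()))  # zero advance emits nothing
      t_target <- private$time + dt
      n0 <- length(private$events)
      repeat {
        if (private$state != "running") break
        nxt <- private$next_boundary()
        if (nxt > t_target + ENGINE_EPS) break
        private$time <- max(private$time, nxt)
        private$process_boundary()
      }
      private$time <- max(private$time, t_target)
      invisible(private$events[seq_len(length(private$events) - n0) + n0])
    },

    #' @description Current engine clock (s).
    now = function() private$time,

    #' @description Full event log (list of events with `time`, `type`,
    #'   `detail`), in emission order.
    #' @param include_queries keep `status_query` events (default TRUE).
    event_log = function(include_queries = TRUE) {
      ev <- private$events
      if (!include_queries) {
        ev <- Filter(function(e) e$type != "status_query", ev)
      }
      ev
    },

    #' @description Current drive configuration for the acoustic/thermal
    #'   simulators: transducer position, element mask and overrides, and the
    #'   active exposure (if any) with its trajectory and elapsed time.
    query_drive = function() {
      on <- private$ultrasound_on()
      at <- if (on) private$current_cmd()$attributes else NULL
      list(ultrasound_on = on,
           acoustic_power_w = if (on) at$acoustic_power_w else 0,
           frequency_mhz = if (on) at$frequency_mhz else NA_real_,
           duty_cycle = if (on) at$duty_cycle %||% 1 else NA_real_,
           trajectory = if (on) at$trajectory else NULL,
           exposure_elapsed_s = if (on) private$time - private$cmd_start
                                else NA_real_,
           transducer_position_mm = private$position_at(private$time),
           active_mask = private$mask,
           phases_rad = private$phase_over,
           amplitudes = private$amp_over,
           command_position = if (on) private$pos else NA_integer_)
    },

    #' @description Discard state and return to idle with the clock at 0.
    reset = function() {
      private$protocol <- NULL; private$state <- "idle"
      private$time <- 0; private$start_time <- NA_real_
      private$pos <- -1L; private$active <- FALSE
      private$events <- list()
      private$posn <- c(0, 0, 0); private$ang <- c(0, 0)
      private$mask <- rep(TRUE, self$config$n_elements)
      private$phase_over <- NULL; private$amp_over <- NULL
      invisible(self)
    }
  ),

  private = list(
    protocol = NULL, state = "idle", time = 0, start_time = NA_real_,
    offset = 0, pos = -1L, active = FALSE,
    cmd_start = NA_real_, cmd_end = NA_real_,
    posn = c(0, 0, 0), ang = c(0, 0),
    move_from = NULL, move_to = NULL, move_ang_from = NULL, move_ang_to = NULL,
    mask = NULL, phase_over = NULL, amp_over = NULL,
    events = list(),

    log_event = function(type, detail = list()) {
      private$events[[length(private$events) + 1L]] <-
        list(time = private$time, type = type, detail = detail)
    },

    current_cmd = function() private$protocol$commands[[private$pos + 1L]],

    cmd_duration = function(cmd) {
      at <- cmd$attributes
      switch(cmd$kind,
        continuous_exposure = ,
        pulsed_exposure = at$duration_s,
        move_transducer = {
          dist <- sqrt(sum((at$position_mm - private$posn)^2))
          adist <- max(abs(c(at$rot_lr_deg, at$rot_hf_deg) - private$ang))
          max(dist / self$config$move_speed_mm_s,
              adist / self$config$rot_speed_deg_s)
        },
        pause = at$duration_s,
        rnd = 0)
    },

    next_boundary = function() {
      if (private$active) return(private$cmd_end)
      nxt <- private$pos + 1L
      if (nxt >= length(private$protocol$commands)) return(Inf)
      cmd <- private$protocol$commands[[nxt + 1L]]
      max(private$time, cmd$time_index_s + private$offset)
    },

    process_boundary = function() {
      if (private$active) {
        private$finish_current()
      } else {
        private$start_next()
      }
    },

    start_next = function() {
      private$pos <- private$pos + 1L
      cmd <- private$current_cmd()
      private$cmd_start <- private$time
      private$cmd_end <- private$time + private$cmd_duration(cmd)
      private$active <- TRUE
      private$log_event("command_started",
                        list(position = private$pos, kind = cmd$kind))
      at <- cmd$attributes
      if (cmd$kind %in% c("continuous_exposure", "pulsed_exposure")) {
        private$log_event("exposure_on", list(
          position = private$pos, kind = cmd$kind,
          acoustic_power_w = at$acoustic_power_w,
          frequency_mhz = at$frequency_mhz,
          duty_cycle = at$duty_cycle %||% 1,
          trajectory = at$trajectory,
          transducer_position_mm = private$posn,
          active_mask = private$mask,
          phases_rad = private$phase_over,
          amplitudes = private$amp_over))
      } else if (cmd$kind == "move_transducer") {
        private$move_from <- private$posn
        private$move_to <- at$position_mm
        private$move_ang_from <- private$ang
        private$move_ang_to <- c(at$rot_lr_deg, at$rot_hf_deg)
        private$log_event("move_started",
                          list(from_mm = private$posn, to_mm = at$position_mm))
      } else if (cmd$kind == "rnd") {
        private$mask <- at$active_mask
        if (!is.null(at$phases_rad)) private$phase_over <- at$phases_rad
        if (!is.null(at$amplitudes)) private$amp_over <- at$amplitudes
      }
    },

    finish_current = function(interrupted = FALSE) {
      cmd <- private$current_cmd()
      if (cmd$kind %in% c("continuous_exposure", "pulsed_exposure")) {
        private$log_event("exposure_off",
                          list(position = private$pos,
                               interrupted = interrupted))
      } else if (cmd$kind == "move_transducer") {
        if (!interrupted) {
          private$posn <- private$move_to
          private$ang <- private$move_ang_to
        } else {
          private$posn <- private$position_at(private$time)
          private$ang <- private$angles_at(private$time)
        }
        private$move_from <- NULL
        private$log_event("move_finished", list(position_mm = private$posn))
      }
      private$log_event("command_finished",
                        list(position = private$pos, kind = cmd$kind,
                             interrupted = interrupted))
      private$active <- FALSE
      if (!interrupted &&
          private$pos + 1L >= length(private$protocol$commands)) {
        private$state <- "finished"
      }
    },

    interrupt_current = function() private$finish_current(interrupted = TRUE),

    ultrasound_on = function() {
      private$state == "running" && private$active &&
        private$current_cmd()$kind %in% c("continuous_exposure",
                                          "pulsed_exposure")
    },

    moving = function() {
      private$state == "running" && private$active &&
        private$current_cmd()$kind == "move_transducer"
    },

    position_at = function(t) {
      if (!private$moving() || is.null(private$move_from)) return(private$posn)
      dur <- private$cmd_end - private$cmd_start
      f <- if (dur <= 0) 1 else min(1, (t - private$cmd_start) / dur)
      private$move_from + f * (private$move_to - private$move_from)
    },

    angles_at = function(t) {
      if (!private$moving() || is.null(private$move_ang_from)) return(private$ang)
      dur <- private$cmd_end - private$cmd_start
      f <- if (dur <= 0) 1 else min(1, (t - private$cmd_start) / dur)
      private$move_ang_from + f * (private$move_ang_to - private$move_ang_from)
    }
  )
)

#' @export
print.status_snapshot <- function(x, ...) {
  cat(sprintf(
    "<status: %s | pos (%.1f, %.1f, %.1f) mm | US %s | fwd %.3g W | t=%.3g s>\n",
    x$protocol_state, x$transducer_position_mm[1], x$transducer_position_mm[2],
    x$transducer_position_mm[3], ifelse(x$ultrasound_on, "on", "off"),
    x$forward_power_w, x$current_time_index_s))
  invisible(x)
}
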