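#' Focal-point trajectory for electronic steering
#'
#' A trajectory is a series of focal-point offsets from the transducer's
#' natural focus, visited cyclically during an exposure with a fixed dwell
#' time (`interval_ms`) at each point. An 8-s exposure over a 10-point,
#' 25-ms trajectory therefore makes 32 full passes along the path.
#'
#' @param points numeric matrix, one row per point, columns (x, y, z) in mm
#'   in the device frame (offsets from the natural focus).
#' @param interval_ms dwell time per point in milliseconds (> 0).
#' @return An object of class `focus_trajectory`.
#' @export
#' @examples
#' tr <- focus_trajectory(cbind(seq(-9, 9, by = 2), 0, 0), 25)
#' nrow(tr$points)  # 10
focus_trajectory <- function(points, interval_ms) {
  points <- as_points_matrix(points, "points")
  if (nrow(points) < 1L) stop_validation("points", "must be non-empty")
  if (!all(is.finite(points))) stop_validation("points", "offsets must be finite")
  check_scalar_number(interval_ms, "interval_ms", positive = TRUE)
  structure(list(points = points, interval_ms = as.numeric(interval_ms)),
            class = "focus_trajectory")
}

as_points_matrix <- function(x, field) {
  if (is.null(dim(x))) {
    if (length(x) %% 3L != 0L) stop_validation(field, "needs (x, y, z) triplets")
    x <- matrix(as.numeric(x), ncol = 3L, byrow = TRUE)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop_validation(field, "must have 3 columns (x, y, z)")
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' Straight-line steering trajectory
#'
#' Samples the segment from `from` to `to` at `step_mm` spacing, endpoints
#' inclusive: an 18-mm line at 2-mm steps yields 10 points.
#'
#' @param from,to 3-vectors (mm, device frame).
#' @param step_mm spacing between consecutive points (mm).
#' @param interval_ms dwell time per point (ms).
#' @return A [focus_trajectory()].
#' @export
line_trajectory <- function(from, to, step_mm = 2, interval_ms = 25) {
  from <- as.numeric(from); to <- as.numeric(to)
  len <- sqrt(sum((to - from)^2))
  n <- max(2L, as.integer(round(len / step_mm)) + 1L)
  frac <- seq(0, 1, length.out = n)
  pts <- cbind(from[1] + frac * (to[1] - from[1]),
               from[2] + frac * (to[2] - from[2]),
               from[3] + frac * (to[3] - from[3]))
  focus_trajectory(pts, interval_ms)
}

COMMAND_KINDS <- c("continuous_exposure", "pulsed_exposure", "move_transducer",
                   "pause", "rnd")

new_command <- function(kind, time_index_s, attributes, index = NA_integer_) {
  check_scalar_number(time_index_s, "time_index_s", nonneg = TRUE)
  structure(list(index = as.integer(index),
                 time_index_s = as.numeric(time_index_s),
                 kind = kind,
                 attributes = attributes),
            class = "hifu_command")
}

#' @export
print.hifu_command <- function(x, ...) {
  cat(sprintf("<command %s: kind=%s t=%.3gs>\n",
              ifelse(is.na(x$index), "?", x$index), x$kind, x$time_index_s))
  invisible(x)
}

check_frequency <- function(frequency_mhz) {
  check_scalar_number(frequency_mhz, "frequency_mhz", positive = TRUE)
  if (frequency_mhz < 1.0 || frequency_mhz > 1.5) {
    warning(sprintf(
      "frequency %.3g MHz is outside the transducer's 1.0-1.5 MHz band",
      frequency_mhz), call. = FALSE)
  }
  invisible(frequency_mhz)
}

check_trajectory <- function(trajectory) {
  if (!is.null(trajectory) && !inherits(trajectory, "focus_trajectory")) {
    stop_validation("trajectory", "must be a focus_trajectory or NULL")
  }
  invisible(trajectory)
}

#' Build a continuous ultrasound exposure command
#'
#' Starts a continuous exposure at `time_index_s` with a given acoustic power
#' and frequency, optionally steering the focal point along a trajectory.
#' The exposure runs for `duration_s` (use `Inf` for an open-ended exposure
#' stopped later by a modification).
#'
#' @param acoustic_power_w total acoustic power (W, > 0).
#' @param frequency_mhz driving frequency (MHz); a warning is issued outside
#'   the device's 1.0-1.5 MHz band.
#' @param trajectory [focus_trajectory()] or `NULL` for a static focus.
#' @param duration_s exposure duration (s, > 0; may be `Inf`).
#' @param time_index_s scheduled start time within the protocol (s, >= 0).
#' @return A `hifu_command` of kind `continuous_exposure`.
#' @export
build_continuous_exposure <- function(acoustic_power_w, frequency_mhz,
                                      trajectory = NULL, duration_s,
                                      time_index_s = 0) {
  check_scalar_number(acoustic_power_w, "acoustic_power_w", positive = TRUE)
  check_frequency(frequency_mhz)
  check_trajectory(trajectory)
  check_scalar_number(duration_s, "duration_s", positive = TRUE, finite = FALSE)
  new_command("continuous_exposure", time_index_s,
              list(acoustic_power_w = as.numeric(acoustic_power_w),
                   frequency_mhz = as.numeric(frequency_mhz),
                   trajectory = trajectory,
                   duration_s = as.numeric(duration_s)))
}

#' Build a pulsed ultrasound exposure command
#'
#' Pulsed drive with a controllable duty cycle: bursts of
#' `cycles_per_burst` cycles repeat at `prf_hz`. The implied burst duration
#' is `cycles_per_burst / frequency` (33.33 us for 40 cycles at 1.2 MHz).
#' Each burst may be synchronized to an external trigger.
#'
#' @inheritParams build_continuous_exposure
#' @param duty_cycle on-fraction per repetition period, in (0, 1].
#' @param prf_hz pulse repetition frequency (Hz, > 0).
#' @param cycles_per_burst cycles per burst (positive integer).
#' @param external_trigger logical flag carried as metadata.
#' @return A `hifu_command` of kind `pulsed_exposure`.
#' @export
build_pulsed_exposure <- function(acoustic_power_w, frequency_mhz, duty_cycle,
                                  prf_hz, cycles_per_burst, trajectory = NULL,
                                  duration_s, time_index_s = 0,
                                  external_trigger = FALSE) {
  check_scalar_number(acoustic_power_w, "acoustic_power_w", positive = TRUE)
  check_frequency(frequency_mhz)
  check_scalar_number(duty_cycle, "duty_cycle", positive = TRUE)
  if (duty_cycle > 1) stop_validation("duty_cycle", "must be in (0, 1]")
  check_scalar_number(prf_hz, "prf_hz", positive = TRUE)
  check_scalar_number(cycles_per_burst, "cycles_per_burst", positive = TRUE)
  check_trajectory(trajectory)
  check_scalar_number(duration_s, "duration_s", positive = TRUE, finite = FALSE)
  new_command("pulsed_exposure", time_index_s,
              list(acoustic_power_w = as.numeric(acoustic_power_w),
                   frequency_mhz = as.numeric(frequency_mhz),
                   duty_cycle = as.numeric(duty_cycle),
                   prf_hz = as.numeric(prf_hz),
                   cycles_per_burst = as.integer(cycles_per_burst),
                   external_trigger = isTRUE(external_trigger),
                   trajectory = trajectory,
                   duration_s = as.numeric(duration_s)))
}

#' Burst duration and burst schedule of a pulsed exposure
#'
#' `burst_duration_s()` returns `cycles_per_burst / frequency`;
#' `n_bursts()` counts the bursts scheduled within the exposure duration
#' (one per repetition period, `floor(duration * prf)`).
#'
#' @param command a `pulsed_exposure` command.
#' @return A scalar (seconds, or a count).
#' @export
burst_duration_s <- function(command) {
  stopifnot(inherits(command, "hifu_command"),
            command$kind == "pulsed_exposure")
  command$attributes$cycles_per_burst / (command$attributes$frequency_mhz * 1e6)
}

#' @rdname burst_duration_s
#' @export
n_bursts <- function(command) {
  stopifnot(inherits(command, "hifu_command"),
            command$kind == "pulsed_exposure")
  as.integer(floor(command$attributes$duration_s * command$attributes$prf_hz +
                     1e-9))
}

#' Build a transducer movement command
#'
#' Moves the transducer with 5 degrees of freedom: 3D Cartesian position plus
#' rotations about the left-right and head-foot axes. Targets outside the
#' configured mechanical limits are rejected, naming the violated axis.
#'
#' @param position_mm target position, 3-vector (mm, device frame).
#' @param rot_lr_deg,rot_hf_deg rotation angles (degrees).
#' @param time_index_s scheduled start time (s).
#' @param limits mechanical limits: list with `translation_mm` (scalar,
#'   per-axis absolute bound) and `rotation_deg` (scalar bound per angle).
#' @return A `hifu_command` of kind `move_transducer`.
#' @export
build_move <- function(position_mm, rot_lr_deg = 0, rot_hf_deg = 0,
                       time_index_s = 0, limits = move_limits()) {
  position_mm <- as.numeric(position_mm)
  if (length(position_mm) != 3L || any(!is.finite(position_mm))) {
    stop_validation("position_mm", "must be a finite 3-vector")
  }
  ax <- c("x", "y", "z")
  bad <- which(abs(position_mm) > limits$translation_mm)
  if (length(bad)) {
    stop_validation(paste0("position_mm[", ax[bad[1]], "]"),
                    sprintf("|%.3g| mm exceeds the %.3g mm travel limit",
                            position_mm[bad[1]], limits$translation_mm))
  }
  for (nm in c("rot_lr_deg", "rot_hf_deg")) {
    v <- get(nm)
    check_scalar_number(v, nm)
    if (abs(v) > limits$rotation_deg) {
      stop_validation(nm, sprintf("|%.3g| deg exceeds the %.3g deg limit",
                                  v, limits$rotation_deg))
    }
  }
  new_command("move_transducer", time_index_s,
              list(position_mm = position_mm,
                   rot_lr_deg = as.numeric(rot_lr_deg),
                   rot_hf_deg = as.numeric(rot_hf_deg)))
}

#' Mechanical limits for transducer positioning
#'
#' The hardware travel range is not public; defaults are a 100-mm per-axis
#' translation range and +/-30 degrees per rotation angle, both configurable.
#'
#' @param translation_mm absolute per-axis translation bound (mm).
#' @param rotation_deg absolute bound per rotation angle (degrees).
#' @export
move_limits <- function(translation_mm = 100, rotation_deg = 30) {
  list(translation_mm = translation_mm, rotation_deg = rotation_deg)
}

#' Build a pause command
#'
#' Defines a non-operational state: either a fixed duration (possibly `Inf`,
#' used for "remain inactive" steps that end only via a modification), or
#' waiting for the completion of the previous command.
#'
#' @param duration_s pause duration (s, >= 0, may be `Inf`); ignored when
#'   `wait_for_previous` is `TRUE`.
#' @param wait_for_previous wait for the previous command to finish instead
#'   of pausing for a fixed time.
#' @param time_index_s scheduled start time (s).
#' @return A `hifu_command` of kind `pause`.
#' @export
build_pause <- function(duration_s = NULL, wait_for_previous = FALSE,
                        time_index_s = 0) {
  if (isTRUE(wait_for_previous)) {
    duration_s <- 0
  } else {
    if (is.null(duration_s)) {
      stop_validation("duration_s", "required unless wait_for_previous = TRUE")
    }
    check_scalar_number(duration_s, "duration_s", nonneg = TRUE, finite = FALSE)
  }
  new_command("pause", time_index_s,
              list(duration_s = as.numeric(duration_s),
                   wait_for_previous = isTRUE(wait_for_previous)))
}

#' Build a low-level R&D command
#'
#' Element-level control of the phased array: selects active/inactive
#' elements and optionally applies per-element phase and amplitude
#' overrides. Omitted phases/amplitudes mean "leave unchanged".
#'
#' @param active_mask logical vector of length `n_elements`.
#' @param phases_rad per-element phase overrides (radians) or `NULL`.
#' @param amplitudes per-element amplitude fractions in `[0, 1]` or `NULL`.
#' @param time_index_s scheduled start time (s).
#' @param n_elements expected array size (default 256).
#' @return A `hifu_command` of kind `rnd`.
#' @export
build_rnd <- function(active_mask, phases_rad = NULL, amplitudes = NULL,
                      time_index_s = 0, n_elements = SONASIM_N_ELEMENTS) {
  active_mask <- as.logical(active_mask)
  if (length(active_mask) != n_elements || anyNA(active_mask)) {
    stop_validation("active_mask",
                    sprintf("must be %d booleans (got length %d)",
                            n_elements, length(active_mask)))
  }
  if (!is.null(phases_rad)) {
    phases_rad <- as.numeric(phases_rad)
    if (length(phases_rad) != n_elements || any(!is.finite(phases_rad))) {
      stop_validation("phases_rad",
                      sprintf("must be %d finite values", n_elements))
    }
  }
  if (!is.null(amplitudes)) {
    amplitudes <- as.numeric(amplitudes)
    if (length(amplitudes) != n_elements || any(!is.finite(amplitudes)) ||
        any(amplitudes < 0 | amplitudes > 1)) {
      stop_validation("amplitudes",
                      sprintf("must be %d values in [0, 1]", n_elements))
    }
  }
  new_command("rnd", time_index_s,
              list(active_mask = active_mask,
                   phases_rad = phases_rad,
                   amplitudes = amplitudes))
}

#' Assemble commands into a treatment protocol
#'
#' A treatment protocol is an ordered, time-indexed series of commands — a
#' mini-program executed by the engine. Commands are re-indexed `0..n-1`
#' preserving order; time indices must be non-decreasing with order.
#' Assembly is idempotent and never mutates its inputs.
#'
#' @param identifier non-empty user identifier, e.g. `"Protocol_1"`.
#' @param commands list of `hifu_command` objects (or a `hifu_protocol`,
#'   whose commands are re-assembled).
#' @return An object of class `hifu_protocol`.
#' @export
assemble_protocol <- function(identifier, commands) {
  if (inherits(commands, "hifu_protocol")) commands <- commands$commands
  if (!is.character(identifier) || length(identifier) != 1L ||
      !nzchar(identifier)) {
    stop_validation("identifier", "must be a non-empty string")
  }
  if (!is.list(commands) || length(commands) == 0L) {
    stop_validation("commands", "must be a non-empty list of commands")
  }
  ok <- vapply(commands, inherits, logical(1), what = "hifu_command")
  if (!all(ok)) {
    stop_validation("commands",
                    sprintf("element %d is not a hifu_command", which(!ok)[1]))
  }
  t_idx <- vapply(commands, function(c) c$time_index_s, numeric(1))
  if (any(diff(t_idx) < 0)) {
    i <- which(diff(t_idx) < 0)[1]
    stop_validation("commands", sprintf(
      "time indices must be non-decreasing: command %d (t=%.4g s) precedes command %d (t=%.4g s)",
      i - 1L, t_idx[i], i, t_idx[i + 1L]))
  }
  commands <- lapply(seq_along(commands), function(i) {
    cmd <- commands[[i]]
    cmd$index <- i - 1L
    cmd
  })
  structure(list(identifier = identifier, commands = commands),
            class = "hifu_protocol")
}

#' @export
print.hifu_protocol <- function(x, ...) {
  cat(sprintf("<treatment protocol '%s': %d commands>\n",
              x$identifier, length(x$commands)))
  for (cmd in x$commands) {
    cat(sprintf("  [%d] t=%-8.4g %s\n", cmd$index, cmd$time_index_s, cmd$kind))
  }
  invisible(x)
}

#' Build a protocol modification
#'
#' A modification targets a loaded protocol by identifier and adjusts
#' parameters of existing commands; it may also request that execution
#' resume ("goto") at a given command position. Positions are the 0-based
#' command indices of the target protocol; command kinds cannot be changed.
#'
#' @param identifier non-empty modification identifier.
#' @param target_protocol identifier of the protocol being modified.
#' @param edits list of edits, each `list(position =, attribute =, value =)`.
#' @param goto_position optional 0-based command position at which execution
#'   resumes after the edits are applied.
#' @param protocol optional `hifu_protocol` to validate edits against
#'   immediately (positions exist, attributes exist for the command kind).
#' @return An object of class `hifu_modification`.
#' @export
build_modification <- function(identifier, target_protocol, edits = list(),
                               goto_position = NULL, protocol = NULL) {
  if (!is.character(identifier) || !nzchar(identifier)) {
    stop_validation("identifier", "must be a non-empty string")
  }
  if (!is.character(target_protocol) || !nzchar(target_protocol)) {
    stop_validation("target_protocol", "must be a non-empty string")
  }
  edits <- lapply(edits, function(e) {
    if (!is.list(e) || !all(c("position", "attribute", "value") %in% names(e))) {
      stop_validation("edits",
                      "each edit needs fields position, attribute, value")
    }
    list(position = as.integer(e$position),
         attribute = as.character(e$attribute),
         value = e$value)
  })
  if (!is.null(goto_position)) goto_position <- as.integer(goto_position)
  mod <- structure(list(identifier = identifier,
                        target_protocol = target_protocol,
                        edits = edits,
                        goto_position = goto_position),
                   class = "hifu_modification")
  if (!is.null(protocol)) validate_modification(mod, protocol)
  mod
}

#' @export
print.hifu_modification <- function(x, ...) {
  cat(sprintf("<modification '%s' -> '%s': %d edit(s)%s>\n",
              x$identifier, x$target_protocol, length(x$edits),
              if (is.null(x$goto_position)) ""
              else sprintf(", goto %d", x$goto_position)))
  invisible(x)
}

validate_modification <- function(mod, protocol) {
  n <- length(protocol$commands)
  for (e in mod$edits) {
    if (e$position < 0L || e$position >= n) {
      stop_validation("edits", sprintf(
        "position %d does not exist in protocol '%s' (0..%d)",
        e$position, protocol$identifier, n - 1L))
    }
    cmd <- protocol$commands[[e$position + 1L]]
    if (!e$attribute %in% names(cmd$attributes)) {
      stop_validation("edits", sprintf(
        "command %d (kind %s) has no attribute '%s'",
        e$position, cmd$kind, e$attribute))
    }
  }
  if (!is.null(mod$goto_position) &&
      (mod$goto_position < 0L || mod$goto_position >= n)) {
    stop_validation("goto_position",
                    sprintf("position %d does not exist (0..%d)",
                            mod$goto_position, n - 1L))
  }
  invisible(mod)
}

#' Apply a modification to a protocol (pure)
#'
#' Returns a new protocol with all edits applied; the input is untouched.
#' Used by the engine, where application is atomic: a status snapshot
#' observes either all edits or none.
#'
#' @param protocol a `hifu_protocol`.
#' @param mod a `hifu_modification` targeting it.
#' @return The edited `hifu_protocol`.
#' @export
apply_modification <- function(protocol, mod) {
  if (!identical(mod$target_protocol, protocol$identifier)) {
    stop(sprintf("modification targets protocol '%s' but '%s' is loaded",
                 mod$target_protocol, protocol$identifier), call. = FALSE)
  }
  validate_modification(mod, protocol)
  for (e in mod$edits) {
    cmd <- protocol$commands[[e$position + 1L]]
    val <- e$value
    # coerce edited value to the shape of the existing attribute
    old <- cmd$attributes[[e$attribute]]
    if (inherits(old, "focus_trajectory") && !is.null(val) &&
        !inherits(val, "focus_trajectory")) {
      stop_validation("edits", sprintf(
        "attribute '%s' of command %d must be a focus_trajectory",
        e$attribute, e$position))
    }
    cmd$attributes[e$attribute] <- list(val)  # keeps NULL values in place
    protocol$commands[[e$position + 1L]] <- cmd
  }
  protocol
}
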