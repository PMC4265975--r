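PROTOCOL_SCHEMA <- "sonasim-protocol/1"
MODIFICATION_SCHEMA <- "sonasim-modification/1"

trajectory_to_list <- function(tr) {
  if (is.null(tr)) return(NULL)
  list(points = unname(lapply(seq_len(nrow(tr$points)),
                              function(i) as.numeric(tr$points[i, ]))),
       interval_ms = tr$interval_ms)
}

trajectory_from_list <- function(x, path) {
  if (is.null(x)) return(NULL)
  if (is.null(x$points) || is.null(x$interval_ms)) {
    stop(sprintf("parse error at %s: trajectory needs 'points' and 'interval_ms'",
                 path), call. = FALSE)
  }
  pts <- x$points
  if (is.list(pts)) pts <- do.call(rbind, pts)
  focus_trajectory(pts, x$interval_ms)
}

attributes_to_list <- function(cmd) {
  at <- cmd$attributes
  if (cmd$kind %in% c("continuous_exposure", "pulsed_exposure")) {
    at$trajectory <- trajectory_to_list(at$trajectory)
  }
  at
}

attributes_from_list <- function(kind, at, path) {
  # jsonlite writes non-finite doubles as strings ("Inf"); undo that
  if (!is.null(at$duration_s) && is.character(at$duration_s)) {
    at$duration_s <- as.numeric(at$duration_s)
  }
  if (kind %in% c("continuous_exposure", "pulsed_exposure")) {
    at$trajectory <- trajectory_from_list(at$trajectory,
                                          paste0(path, ".attributes.trajectory"))
    if (!"trajectory" %in% names(at)) at["trajectory"] <- list(NULL)
  }
  at
}

#' Serialize a protocol or modification to JSON
#'
#' Writes the frozen wire/disk format (`sonasim-protocol/1` /
#' `sonasim-modification/1`), UTF-8, with full numeric precision.
#' `hifu_from_json()` restores the object; the round trip is the identity.
#'
#' @param x a `hifu_protocol` or `hifu_modification`.
#' @param pretty pretty-print the JSON.
#' @return A JSON string (class `json`).
#' @export
hifu_to_json <- function(x, pretty = FALSE) {
  if (inherits(x, "hifu_protocol")) {
    body <- list(
      schema = PROTOCOL_SCHEMA,
      identifier = x$identifier,
      commands = lapply(x$commands, function(cmd) {
        list(index = cmd$index,
             time_index_s = cmd$time_index_s,
             kind = cmd$kind,
             attributes = attributes_to_list(cmd))
      }))
  } else if (inherits(x, "hifu_modification")) {
    body <- list(
      schema = MODIFICATION_SCHEMA,
      identifier = x$identifier,
      target_protocol = x$target_protocol,
      edits = lapply(x$edits, function(e) {
        val <- e$value
        if (inherits(val, "focus_trajectory")) val <- trajectory_to_list(val)
        list(position = e$position, attribute = e$attribute, value = val)
      }),
      goto_position = x$goto_position)
  } else {
    stop("cannot serialize object of class ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
  jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA, null = "null",
                   pretty = pretty, always_decimal = FALSE)
}

require_field <- function(obj, field, path) {
  if (!field %in% names(obj) || is.null(obj[[field]])) {
    stop(sprintf("parse error at %s.%s: missing required field", path, field),
         call. = FALSE)
  }
  obj[[field]]
}

#' @rdname hifu_to_json
#' @param text JSON text produced by `hifu_to_json()` (or hand-written to the
#'   same schema).
#' @export
hifu_from_json <- function(text) {
  obj <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE),
    error = function(e) {
      stop("parse error at $: invalid JSON: ", conditionMessage(e),
           call. = FALSE)
    })
  schema <- require_field(obj, "schema", "$")
  if (identical(schema, PROTOCOL_SCHEMA)) {
    identifier <- require_field(obj, "identifier", "$")
    raw_cmds <- require_field(obj, "commands", "$")
    cmds <- lapply(seq_along(raw_cmds), function(i) {
      path <- sprintf("$.commands[%d]", i - 1L)
      rc <- raw_cmds[[i]]
      kind <- require_field(rc, "kind", path)
      if (!kind %in% COMMAND_KINDS) {
        stop(sprintf("parse error at %s.kind: unknown command kind '%s'",
                     path, kind), call. = FALSE)
      }
      at <- attributes_from_list(kind, require_field(rc, "attributes", path),
                                 path)
      rebuild_command(kind, at, require_field(rc, "time_index_s", path), path)
    })
    assemble_protocol(identifier, cmds)
  } else if (identical(schema, MODIFICATION_SCHEMA)) {
    edits <- lapply(obj$edits %||% list(), function(e) {
      val <- e$value
      if (identical(e$attribute, "trajectory") && is.list(val)) {
        val <- trajectory_from_list(val, "$.edits.value")
      }
      list(position = as.integer(e$position), attribute = e$attribute,
           value = val)
    })
    build_modification(require_field(obj, "identifier", "$"),
                       require_field(obj, "target_protocol", "$"),
                       edits = edits,
                       goto_position = obj$goto_position)
  } else {
    stop(sprintf("parse error at $.schema: unsupported schema '%s'", schema),
         call. = FALSE)
  }
}

rebuild_command <- function(kind, at, time_index_s, path) {
  tryCatch(
    switch(kind,
      continuous_exposure = build_continuous_exposure(
        at$acoustic_power_w, at$frequency_mhz, at$trajectory, at$duration_s,
        time_index_s),
      pulsed_exposure = build_pulsed_exposure(
        at$acoustic_power_w, at$frequency_mhz, at$duty_cycle, at$prf_hz,
        at$cycles_per_burst, at$trajectory, at$duration_s, time_index_s,
        at$external_trigger %||% FALSE),
      move_transducer = build_move(at$position_mm, at$rot_lr_deg %||% 0,
                                   at$rot_hf_deg %||% 0, time_index_s),
      pause = build_pause(at$duration_s,
                          at$wait_for_previous %||% FALSE, time_index_s),
      rnd = build_rnd(at$active_mask, at$phases_rad, at$amplitudes,
                      time_index_s, n_elements = length(at$active_mask))),
    error = function(e) {
      stop(sprintf("parse error at %s: %s", path, conditionMessage(e)),
           call. = FALSE)
    })
}

#' Read/write protocols and modifications as JSON files
#'
#' @param x object to write.
#' @param path file path.
#' @export
write_hifu_json <- function(x, path) {
  writeLines(hifu_to_json(x, pretty = TRUE), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_hifu_json
#' @export
read_hifu_json <- function(path) {
  hifu_from_json(paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                       collapse = "\n"))
}
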