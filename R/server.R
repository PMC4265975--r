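#' Serve an engine over TCP (JSON request/response sessions)
#'
#' Runs a client-server session loop around a [HifuEngine]: clients connect
#' over TCP and exchange newline-delimited JSON messages
#' `{"op": ..., "payload": ...}` answered with
#' `{"ok": bool, "result": ..., "error": null|string}`. Supported ops:
#' `load` (payload: protocol JSON object), `execute` (payload: protocol or
#' the identifier of a loaded one), `modify` (payload: modification JSON),
#' `query` (status snapshot), `advance` (payload: `{"dt": seconds}`),
#' `log`, `ping` and `shutdown`. Multiple concurrent sessions are
#' multiplexed with socket polling, so a silent or slow session never
#' blocks another session's status query; requests themselves are served
#' one at a time against the single device, mirroring the one-protocol-at-
#' a-time hardware contract. A malformed message yields a JSON error
#' response and the session stays open.
#'
#' @param port TCP port to listen on.
#' @param engine a [HifuEngine] (fresh one by default).
#' @param host bind address.
#' @param idle_timeout_s stop serving after this many seconds with no
#'   connected session (`Inf` to serve forever).
#' @return Invisibly, the engine (after the loop ends).
#' @export
hifu_serve <- function(port, engine = HifuEngine$new(), host = "127.0.0.1",
                       idle_timeout_s = Inf) {
  srv <- serverSocket(port)
  on.exit(close(srv), add = TRUE)
  sessions <- list()
  protocols <- list()
  last_activity <- Sys.time()
  running <- TRUE
  while (running) {
    if (socketSelect(list(srv), timeout = 0.05)) {
      con <- socketAccept(srv, blocking = FALSE, open = "r+")
      sessions[[length(sessions) + 1L]] <- con
      last_activity <- Sys.time()
    }
    if (length(sessions)) {
      ready <- socketSelect(sessions, timeout = 0.05)
      drop <- integer(0)
      for (i in which(ready)) {
        con <- sessions[[i]]
        line <- tryCatch(readLines(con, n = 1L), error = function(e) character(0))
        if (length(line) == 0L) {  # peer went away
          close(con)
          drop <- c(drop, i)
          next
        }
        last_activity <- Sys.time()
        resp <- handle_request(line, engine, protocols)
        protocols <- resp$protocols
        writeLines(resp$json, con)
        flush(con)
        if (resp$shutdown) running <- FALSE
      }
      if (length(drop)) sessions <- sessions[-drop]
    } else if (is.finite(idle_timeout_s) &&
               as.numeric(Sys.time() - last_activity, units = "secs") >
                 idle_timeout_s) {
      running <- FALSE
    }
  }
  for (con in sessions) try(close(con), silent = TRUE)
  invisible(engine)
}

handle_request <- function(line, engine, protocols) {
  flag <- new.env()
  flag$shutdown <- FALSE
  json <- tryCatch({
    req <- jsonlite::fromJSON(line, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
    op <- req$op %||% stop("missing 'op'")
    result <- switch(op,
      ping = "pong",
      load = {
        proto <- hifu_from_json(jsonlite::toJSON(req$payload,
                                                 auto_unbox = TRUE,
                                                 digits = NA, null = "null"))
        protocols[[proto$identifier]] <- proto
        list(identifier = proto$identifier,
             n_commands = length(proto$commands))
      },
      execute = {
        proto <- if (is.character(req$payload)) {
          protocols[[req$payload]] %||%
            stop(sprintf("no loaded protocol '%s'", req$payload))
        } else {
          hifu_from_json(jsonlite::toJSON(req$payload, auto_unbox = TRUE,
                                          digits = NA, null = "null"))
        }
        engine$execute_protocol(proto)
        list(state = "running", identifier = proto$identifier)
      },
      modify = {
        mod <- hifu_from_json(jsonlite::toJSON(req$payload, auto_unbox = TRUE,
                                               digits = NA, null = "null"))
        engine$execute_modification(mod)
        list(applied = mod$identifier)
      },
      query = unclass(engine$query_status()),
      advance = {
        engine$advance_clock(req$payload$dt %||% 0)
        list(now_s = engine$now())
      },
      log = lapply(engine$event_log(), function(e)
        list(time = e$time, type = e$type)),
      shutdown = {
        flag$shutdown <- TRUE
        "bye"
      },
      stop(sprintf("unknown op '%s'", op)))
    jsonlite::toJSON(list(ok = TRUE, result = result, error = NULL),
                     auto_unbox = TRUE, digits = NA, null = "null")
  }, error = function(e) {
    jsonlite::toJSON(list(ok = FALSE, result = NULL,
                          error = conditionMessage(e)),
                     auto_unbox = TRUE, digits = NA, null = "null")
  })
  list(json = as.character(json), protocols = protocols,
       shutdown = flag$shutdown)
}

#' Connect to a served engine
#'
#' @param port server port.
#' @param host server host.
#' @param timeout_s connect/read timeout (s).
#' @return A `hifu_session`.
#' @export
hifu_connect <- function(port, host = "127.0.0.1", timeout_s = 10) {
  con <- socketConnection(host, port, blocking = TRUE, open = "r+",
                          timeout = timeout_s)
  structure(list(con = con), class = "hifu_session")
}

#' Send one request over a session
#'
#' @param session a `hifu_session` from [hifu_connect()].
#' @param op operation name (see [hifu_serve()]).
#' @param payload optional payload (R list, or an object with a JSON form
#'   such as a `hifu_protocol`/`hifu_modification`).
#' @return The decoded response list (`ok`, `result`, `error`).
#' @export
session_request <- function(session, op, payload = NULL) {
  stopifnot(inherits(session, "hifu_session"))
  if (inherits(payload, "hifu_protocol") ||
      inherits(payload, "hifu_modification")) {
    payload <- jsonlite::fromJSON(hifu_to_json(payload),
                                  simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE,
                                  simplifyMatrix = FALSE)
  }
  msg <- jsonlite::toJSON(list(op = op, payload = payload),
                          auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(as.character(msg), session$con)
  flush(session$con)
  line <- readLines(session$con, n = 1L)
  if (length(line) == 0L) stop("server closed the connection", call. = FALSE)
  jsonlite::fromJSON(line, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}

#' @rdname session_request
#' @export
session_close <- function(session) {
  try(close(session$con), silent = TRUE)
  invisible(NULL)
}
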