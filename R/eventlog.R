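#' Append-only session event log
#'
#' Sessions are logged as ordered events with session-relative timestamps in
#' integer milliseconds of logical time (advanced by the scheduler, never
#' wall clock, so replays are byte-identical). Timestamps must be
#' non-decreasing; ties are allowed.
#'
#' @return An environment of class `event_log`.
#' @export
event_log <- function() {
  e <- new.env(parent = emptyenv())
  e$events <- vector("list", 64L)
  e$n <- 0L
  e$last_ts <- -1L
  class(e) <- "event_log"
  e
}

#' Append one event to a log
#'
#' @param log an [event_log()].
#' @param ts_ms non-negative session-relative timestamp (ms); must be `>=`
#'   the last logged timestamp.
#' @param kind short event type string (e.g. `"badge_awarded"`).
#' @param payload named list of primitive values.
#' @return The log, invisibly (the log is mutated in place).
#' @export
log_event <- function(log, ts_ms, kind, payload = list()) {
  stopifnot(inherits(log, "event_log"), is.character(kind), length(kind) == 1L)
  ts_ms <- as.integer(ts_ms)
  if (is.na(ts_ms) || ts_ms < 0L) stop("timestamp must be a non-negative integer",
                                       call. = FALSE)
  if (ts_ms < log$last_ts) {
    stop(sprintf("event timestamp %d precedes last logged timestamp %d",
                 ts_ms, log$last_ts), call. = FALSE)
  }
  if (log$n == length(log$events)) {
    length(log$events) <- 2L * log$n
  }
  log$n <- log$n + 1L
  log$events[[log$n]] <- list(ts_ms = ts_ms, kind = kind, payload = payload)
  log$last_ts <- ts_ms
  invisible(log)
}

#' Extract logged events as a list
#' @param log an [event_log()].
#' @param kind optional filter on event kind.
#' @return List of events, each `list(ts_ms, kind, payload)`.
#' @export
log_events <- function(log, kind = NULL) {
  stopifnot(inherits(log, "event_log"))
  ev <- log$events[seq_len(log$n)]
  if (!is.null(kind)) ev <- ev[vapply(ev, function(e) e$kind, "") %in% kind]
  ev
}

#' Serialize a log to JSON-Lines
#'
#' One event per line with fields `ts_ms`, `kind`, `payload`.
#'
#' @param log an [event_log()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  lines <- vapply(log_events(log), function(e) {
    jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA, null = "null")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON-Lines session log back into an event log
#' @param path file written by [write_session_log()].
#' @return An [event_log()].
#' @export
read_session_log <- function(path) {
  log <- event_log()
  for (line in readLines(path, warn = FALSE)) {
    if (!nzchar(line)) next
    e <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    log_event(log, e$ts_ms, e$kind, e$payload)
  }
  log
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> %d events, last ts %d ms\n", x$n, max(x$last_ts, 0L)))
  invisible(x)
}
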