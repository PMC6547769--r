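# Screen-event logs and interaction sessions.
#
# A log is a stream of SCREEN_ON / SCREEN_OFF / PRESENT events with absolute
# timestamps. An interaction session is one consecutive ON -> OFF pair;
# PRESENT between them means the phone was unlocked. All downstream sleep
# logic works on OFF -> ON gaps between sessions.

#' Read a screen-event log
#'
#' Reads a log of raw screen events from CSV (canonical dialect: header
#' `timestamp,kind`, ISO-8601 timestamps with offset) or JSON lines
#' (one object `{"timestamp": ..., "kind": ...}` per line). Records are
#' returned sorted ascending by timestamp (stable, so equal-timestamp
#' records keep file order) with exact duplicates (same timestamp and kind)
#' removed.
#'
#' @param path Path to the log file.
#' @param dialect `"csv"` or `"jsonl"`.
#' @param tz Timezone the timestamps are converted into; this defines local
#'   wall-clock time for all time-of-day logic downstream.
#' @return A tibble with columns `timestamp` (POSIXct) and `kind`
#'   (`"SCREEN_ON"`, `"SCREEN_OFF"`, or `"PRESENT"`).
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "timestamp,kind",
#'   "2016-02-01T23:10:00+00:00,SCREEN_OFF",
#'   "2016-02-01T23:09:40+00:00,SCREEN_ON"
#' ), f)
#' read_event_log(f)
read_event_log <- function(path, dialect = c("csv", "jsonl"), tz = "UTC") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (dialect == "csv") {
    lines <- readr::read_lines(path)
    if (length(lines) == 0 || (length(lines) == 1 && lines == "")) {
      return(empty_event_log(tz))
    }
    raw <- readr::read_csv(path, col_types = readr::cols(
      timestamp = readr::col_character(),
      kind = readr::col_character()
    ), progress = FALSE)
    line_no <- seq_len(nrow(raw)) + 1L # header is line 1
  } else {
    lines <- readr::read_lines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) return(empty_event_log(tz))
    recs <- lapply(seq_along(lines), function(i) {
      obj <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) NULL)
      if (is.null(obj) || is.null(obj$timestamp) || is.null(obj$kind)) {
        abort(paste0("unparseable JSONL record at line ", i))
      }
      list(timestamp = as.character(obj$timestamp), kind = as.character(obj$kind))
    })
    raw <- tibble::tibble(
      timestamp = vapply(recs, `[[`, character(1), "timestamp"),
      kind = vapply(recs, `[[`, character(1), "kind")
    )
    line_no <- seq_len(nrow(raw))
  }
  if (nrow(raw) == 0) return(empty_event_log(tz))

  ts <- lubridate::ymd_hms(raw$timestamp, tz = "UTC", quiet = TRUE)
  bad <- which(is.na(ts))
  if (length(bad) > 0) {
    abort(paste0("unparseable timestamp at line ", line_no[bad[1]],
                 ": '", raw$timestamp[bad[1]], "'"))
  }
  bad_kind <- which(!raw$kind %in% EVENT_KINDS)
  if (length(bad_kind) > 0) {
    abort(paste0("unknown event kind at line ", line_no[bad_kind[1]],
                 ": '", raw$kind[bad_kind[1]], "'"))
  }
  events <- tibble::tibble(
    timestamp = lubridate::with_tz(ts, tz),
    kind = raw$kind
  )
  events <- events[order(events$timestamp, method = "radix"), , drop = FALSE]
  events <- dplyr::distinct(events, .data$timestamp, .data$kind, .keep_all = TRUE)
  events
}

empty_event_log <- function(tz = "UTC") {
  tibble::tibble(
    timestamp = lubridate::with_tz(as.POSIXct(character(), tz = "UTC"), tz),
    kind = character()
  )
}

#' Write a screen-event log
#'
#' Writes events in the canonical dialect: CSV with header `timestamp,kind`
#' and ISO-8601 timestamps carrying the UTC offset, or JSON lines with the
#' same two fields. Reading the file back reproduces the retained records
#' exactly.
#'
#' @param events Event tibble as returned by [read_event_log()].
#' @param path Output path.
#' @param dialect `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path, dialect = c("csv", "jsonl")) {
  dialect <- match.arg(dialect)
  stamp <- iso8601_offset(events$timestamp)
  if (dialect == "csv") {
    readr::write_csv(tibble::tibble(timestamp = stamp, kind = events$kind), path)
  } else {
    lines <- vapply(seq_along(stamp), function(i) {
      jsonlite::toJSON(list(timestamp = stamp[i], kind = events$kind[i]),
                       auto_unbox = TRUE)
    }, character(1))
    readr::write_lines(lines, path)
  }
  invisible(path)
}

# ISO-8601 with a colon in the offset (+01:00), second precision
iso8601_offset <- function(t) {
  s <- format(t, "%Y-%m-%dT%H:%M:%S%z")
  sub("([+-][0-9]{2})([0-9]{2})$", "\\1:\\2", s)
}

#' Pair raw screen events into interaction sessions
#'
#' Walks the sorted event stream and pairs each SCREEN_ON with the next
#' SCREEN_OFF; a PRESENT event in between marks the session as unlocked.
#' Malformed subsequences are repaired, never fatal: a SCREEN_ON followed by
#' another SCREEN_ON keeps the later one (the screen was demonstrably on and
#' the later ON is closest to the terminating OFF), a SCREEN_OFF with no
#' open session is dropped, a trailing unmatched SCREEN_ON is dropped, and
#' zero-length pairs are dropped. Repair counts are attached as the
#' `"repairs"` attribute.
#'
#' @param events Event tibble sorted ascending by timestamp.
#' @return A tibble of sessions with columns `on_time`, `off_time`,
#'   `unlocked`, sorted and non-overlapping, plus a `"repairs"` attribute
#'   (named integer vector: `reopened`, `orphan_off`, `trailing_on`,
#'   `zero_length`).
#' @export
pair_sessions <- function(events) {
  stopifnot(all(c("timestamp", "kind") %in% names(events)))
  if (nrow(events) > 1 && is.unsorted(events$timestamp)) {
    abort("events must be sorted ascending by timestamp")
  }
  n <- nrow(events)
  on_time <- events$timestamp[0]
  off_time <- events$timestamp[0]
  unlocked <- logical(0)
  repairs <- c(reopened = 0L, orphan_off = 0L, trailing_on = 0L, zero_length = 0L)

  open_on <- NULL
  open_unlocked <- FALSE
  for (i in seq_len(n)) {
    kind <- events$kind[i]
    t <- events$timestamp[i]
    if (kind == "SCREEN_ON") {
      if (!is.null(open_on)) repairs[["reopened"]] <- repairs[["reopened"]] + 1L
      open_on <- t
      open_unlocked <- FALSE
    } else if (kind == "PRESENT") {
      if (!is.null(open_on)) open_unlocked <- TRUE
    } else { # SCREEN_OFF
      if (is.null(open_on)) {
        repairs[["orphan_off"]] <- repairs[["orphan_off"]] + 1L
      } else if (t <= open_on) {
        repairs[["zero_length"]] <- repairs[["zero_length"]] + 1L
        open_on <- NULL
      } else {
        on_time <- c(on_time, open_on)
        off_time <- c(off_time, t)
        unlocked <- c(unlocked, open_unlocked)
        open_on <- NULL
      }
    }
  }
  if (!is.null(open_on)) repairs[["trailing_on"]] <- repairs[["trailing_on"]] + 1L

  out <- tibble::tibble(on_time = on_time, off_time = off_time, unlocked = unlocked)
  attr(out, "repairs") <- repairs
  out
}
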