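# Wall-clock helpers. All time-of-day logic is local: timestamps carry a
# timezone and are compared on the absolute line, but "22:00" or "noon"
# always mean the clock on the wall where the phone lives.

#' Parse a time of day to minutes after midnight
#'
#' Accepts `"HH:MM"` / `"HH:MM:SS"` strings, [hms::hms] values, or a bare
#' numeric already in minutes. Used for configuration fields such as the
#' habitual bedtime anchor.
#'
#' @param x Time of day in any of the accepted forms.
#' @return Numeric minutes in `[0, 1440)`.
#' @keywords internal
parse_tod <- function(x) {
  if (inherits(x, "hms") || inherits(x, "difftime")) {
    return(as.numeric(x, units = "secs") / 60 %% 1440)
  }
  if (is.numeric(x)) {
    return(x %% 1440)
  }
  if (is.character(x)) {
    parts <- strsplit(x, ":", fixed = TRUE)
    mins <- vapply(parts, function(p) {
      p <- suppressWarnings(as.numeric(p))
      if (any(is.na(p)) || length(p) < 2 || length(p) > 3) {
        abort(paste0("cannot parse time of day: ", paste(p, collapse = ":")))
      }
      p[1] * 60 + p[2] + if (length(p) == 3) p[3] / 60 else 0
    }, numeric(1))
    return(mins %% 1440)
  }
  abort("time of day must be a string, hms, or numeric minutes")
}

#' Local wall-clock minutes after midnight of a timestamp
#' @param t POSIXct vector; its `tzone` attribute defines "local".
#' @return Numeric minutes in `[0, 1440)`.
#' @keywords internal
tod_minutes <- function(t) {
  lt <- as.POSIXlt(t)
  lt$hour * 60 + lt$min + lt$sec / 60
}

#' Circular distance between two times of day, in minutes
#'
#' The clock face wraps at midnight, so 23:00 and 01:00 are 120 min apart,
#' and 21:00 / 23:00 are equidistant from a 22:00 anchor.
#'
#' @param a,b Times of day in minutes after midnight (vectors recycle).
#' @return Non-negative minutes, at most 720.
#' @export
#' @examples
#' circular_diff_min(23 * 60, 1 * 60) # 120
circular_diff_min <- function(a, b) {
  d <- abs(a - b) %% 1440
  pmin(d, 1440 - d)
}

#' Circular median of times of day
#'
#' The median that respects midnight wrap-around: times are unwrapped
#' around each observation in turn and the rotation minimising the total
#' absolute deviation wins. `{23:50, 00:10}` gives 00:00, not 12:00.
#'
#' @param mins Times of day in minutes after midnight.
#' @return A single time of day in minutes, in `[0, 1440)`.
#' @export
circular_median_tod <- function(mins) {
  mins <- mins[!is.na(mins)]
  if (length(mins) == 0) abort("no observations for circular median")
  if (length(mins) == 1) return(mins %% 1440)
  best <- NULL
  best_cost <- Inf
  for (center in mins) {
    dev <- (mins - center + 720) %% 1440 - 720 # unwrap to (-720, 720]
    m <- median(dev)
    cost <- sum(abs(dev - m))
    if (cost < best_cost - 1e-9) {
      best_cost <- cost
      best <- (center + m) %% 1440
    }
  }
  best
}

#' Wake date of the noon-to-noon analysis window containing a timestamp
#'
#' Nights are scanned in windows running from local noon on day D to noon
#' on day D+1; an episode belongs to the window containing its end, and the
#' window is labelled by its wake date (D+1). Noon is used as the anchor
#' because it is maximally distant from typical overnight sleep.
#'
#' @param t POSIXct vector.
#' @param anchor Local time of day splitting consecutive windows
#'   (minutes or `"HH:MM"`; default noon).
#' @return A [Date] vector: the wake date of each timestamp's window.
#' @export
night_window_date <- function(t, anchor = "12:00") {
  anchor <- parse_tod(anchor)
  d <- as.Date(format(t, "%Y-%m-%d"))
  tod <- tod_minutes(t)
  d + as.integer(tod >= anchor)
}

#' Classify a wake date as weekday or weekend
#'
#' Weekend means Saturday or Sunday; a night is classified by the date the
#' sleeper wakes up.
#'
#' @param date A [Date] vector of wake dates.
#' @return Character vector, `"weekday"` or `"weekend"`.
#' @export
day_type_of <- function(date) {
  ifelse(lubridate::wday(date, week_start = 1) >= 6, "weekend", "weekday")
}

# difference in minutes between two POSIXct vectors
diff_min <- function(later, earlier) {
  as.numeric(difftime(later, earlier, units = "mins"))
}
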