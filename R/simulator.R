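# Behavioural simulator: paired screen-event logs and actigraphy-style
# ground truth.
#
# The generator emulates the data-collection setting the estimator is
# meant for: habitual bedtimes in the late evening, day-type-specific wake
# times, a pre-sleep gap between the last phone interaction and sleep
# onset, a post-wake gap before the first interaction, Poisson daytime
# usage, occasional brief mid-night phone checks, and smartwatch-style
# sleep interruptions / unknown segments on the ground-truth side.

#' Behavioural user profile for the simulator
#'
#' Two presets capture the qualitative contrast between a high-engagement
#' cohort ("student": phone close at hand around sleep, short pre/post
#' gaps) and a lower-engagement one ("working_mother": the phone is set
#' aside well before bed and picked up late after waking, and daytime use
#' is sparser). Every field can be overridden.
#'
#' @param preset `"student"` or `"working_mother"`.
#' @param bedtime_mean,bedtime_sd Habitual sleep-onset time of day
#'   (`"HH:MM"` or minutes after midnight; values past midnight are fine
#'   as minutes > 1440) and its SD in minutes.
#' @param wake_weekday_mean,wake_weekday_sd Weekday wake time and SD (min).
#' @param wake_weekend_mean,wake_weekend_sd Weekend wake time and SD (min).
#' @param pre_sleep_gap_mean Mean (minutes) of the exponential gap between
#'   the last interaction and sleep onset.
#' @param post_wake_gap_mean Mean (minutes) of the exponential gap between
#'   waking and the first interaction.
#' @param day_sessions_per_hour Poisson rate of daytime usage sessions.
#' @param session_meanlog,session_sdlog Lognormal parameters of session
#'   length in minutes.
#' @param night_check_prob Per-night probability of one brief (1-5 min)
#'   mid-night phone check.
#' @param interruption_prob,interruption_mean Per-night probability and
#'   exponential mean length (min) of a ground-truth sleep interruption.
#' @param unknown_prob,unknown_mean Per-night probability and exponential
#'   mean length (min) of a ground-truth unknown segment.
#' @param unlock_prob Probability a session includes a PRESENT (unlock)
#'   event.
#' @return A list of class `user_profile` (times stored as minutes).
#' @export
user_profile <- function(preset = c("student", "working_mother"),
                         bedtime_mean = NULL, bedtime_sd = NULL,
                         wake_weekday_mean = NULL, wake_weekday_sd = NULL,
                         wake_weekend_mean = NULL, wake_weekend_sd = NULL,
                         pre_sleep_gap_mean = NULL, post_wake_gap_mean = NULL,
                         day_sessions_per_hour = NULL,
                         session_meanlog = log(2), session_sdlog = 0.8,
                         night_check_prob = NULL,
                         interruption_prob = 0.25, interruption_mean = 5,
                         unknown_prob = 0.1, unknown_mean = 5,
                         unlock_prob = 0.8) {
  preset <- match.arg(preset)
  def <- switch(preset,
    student = list(bedtime_mean = "23:30", bedtime_sd = 45,
                   wake_weekday_mean = "07:00", wake_weekday_sd = 30,
                   wake_weekend_mean = "08:30", wake_weekend_sd = 45,
                   pre_sleep_gap_mean = 10, post_wake_gap_mean = 10,
                   day_sessions_per_hour = 2, night_check_prob = 0.3),
    working_mother = list(bedtime_mean = "23:00", bedtime_sd = 60,
                          wake_weekday_mean = "06:30", wake_weekday_sd = 30,
                          wake_weekend_mean = "07:30", wake_weekend_sd = 60,
                          pre_sleep_gap_mean = 45, post_wake_gap_mean = 60,
                          day_sessions_per_hour = 0.8, night_check_prob = 0.15)
  )
  p <- list(
    engagement_preset = preset,
    bedtime_mean = parse_tod(bedtime_mean %||% def$bedtime_mean),
    bedtime_sd = bedtime_sd %||% def$bedtime_sd,
    wake_weekday_mean = parse_tod(wake_weekday_mean %||% def$wake_weekday_mean),
    wake_weekday_sd = wake_weekday_sd %||% def$wake_weekday_sd,
    wake_weekend_mean = parse_tod(wake_weekend_mean %||% def$wake_weekend_mean),
    wake_weekend_sd = wake_weekend_sd %||% def$wake_weekend_sd,
    pre_sleep_gap_mean = pre_sleep_gap_mean %||% def$pre_sleep_gap_mean,
    post_wake_gap_mean = post_wake_gap_mean %||% def$post_wake_gap_mean,
    day_sessions_per_hour = day_sessions_per_hour %||% def$day_sessions_per_hour,
    session_meanlog = session_meanlog, session_sdlog = session_sdlog,
    night_check_prob = night_check_prob %||% def$night_check_prob,
    interruption_prob = interruption_prob, interruption_mean = interruption_mean,
    unknown_prob = unknown_prob, unknown_mean = unknown_mean,
    unlock_prob = unlock_prob
  )
  validate_profile(p)
  structure(p, class = "user_profile")
}

validate_profile <- function(p) {
  probs <- c(p$night_check_prob, p$interruption_prob, p$unknown_prob,
             p$unlock_prob)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (any(c(p$bedtime_sd, p$wake_weekday_sd, p$wake_weekend_sd) <= 0)) {
    abort("time-of-day SDs must be > 0")
  }
  if (any(c(p$pre_sleep_gap_mean, p$post_wake_gap_mean) < 0)) {
    abort("interaction gaps must be >= 0")
  }
  if (p$day_sessions_per_hour < 0) abort("day_sessions_per_hour must be >= 0")
  invisible(p)
}

# normal truncated at +/- 3 SD, one draw
rtrunc3 <- function(mean, sd) {
  repeat {
    x <- rnorm(1, mean, sd)
    if (abs(x - mean) <= 3 * sd) return(x)
  }
}

rexp_mean <- function(mean) if (mean > 0) rexp(1, rate = 1 / mean) else 0

#' Simulate days of phone usage with paired ground truth
#'
#' Generates, night by night: a sleep interval from truncated-normal
#' (±3 SD) bedtime and day-type-aware wake time; a final pre-sleep session
#' ending `pre_sleep_gap` before sleep onset and a first post-wake session
#' starting `post_wake_gap` after waking; Poisson daytime sessions;
#' an optional brief night-check session inside the sleep interval; and
#' ground-truth segments with sampled interruptions and unknown stretches,
#' consolidated by the smartwatch rules ([consolidate_ground_truth()]).
#' The same seed reproduces the output bit for bit.
#'
#' @param profile A [user_profile()].
#' @param n_days Number of nights to simulate.
#' @param seed Integer seed for the generator.
#' @param start_date Wake date of the first night.
#' @param tz Timezone the log lives in.
#' @return A list with `events` (screen-event tibble), `truth` (nightly
#'   ground-truth tibble: `night_date`, `start`, `end`, `gross_min`,
#'   `net_min`), and `segments` (raw labelled ground-truth segments).
#' @export
#' @examples
#' sim <- sample_user_days(user_profile("student"), n_days = 2, seed = 1)
#' sim$truth
sample_user_days <- function(profile, n_days, seed,
                             start_date = as.Date("2016-01-04"),
                             tz = "UTC") {
  validate_profile(profile)
  if (n_days < 0) abort("n_days must be >= 0")
  if (n_days == 0) {
    return(list(events = empty_event_log(tz),
                truth = empty_truth(tz),
                segments = empty_segments(tz)))
  }
  set.seed(as.integer(seed))
  midnight <- function(date) {
    as.numeric(lubridate::force_tz(lubridate::as_datetime(date), tz))
  }

  nights <- vector("list", n_days)
  for (i in seq_len(n_days)) {
    wake_date <- start_date + (i - 1)
    dt <- day_type_of(wake_date)
    bed_tod <- rtrunc3(profile$bedtime_mean, profile$bedtime_sd)
    wake_tod <- if (dt == "weekend") {
      rtrunc3(profile$wake_weekend_mean, profile$wake_weekend_sd)
    } else {
      rtrunc3(profile$wake_weekday_mean, profile$wake_weekday_sd)
    }
    bed <- round(midnight(wake_date - 1) + bed_tod * 60)
    wake <- round(midnight(wake_date) + wake_tod * 60)

    pre_gap <- round(rexp_mean(profile$pre_sleep_gap_mean) * 60)
    post_gap <- round(rexp_mean(profile$post_wake_gap_mean) * 60)
    eve_len <- session_len_sec(profile)
    morn_len <- session_len_sec(profile)

    check <- NULL
    if (runif(1) < profile$night_check_prob) {
      len <- round(runif(1, 1, 5) * 60)
      lo <- bed + 3600
      hi <- wake - 3600 - len
      if (hi > lo) {
        on <- round(runif(1, lo, hi))
        check <- c(on = on, off = on + len)
      }
    }

    interruption <- sample_truth_segment(
      profile$interruption_prob, profile$interruption_mean, bed, wake)
    unknown <- sample_truth_segment(
      profile$unknown_prob, profile$unknown_mean, bed, wake)
    if (!is.null(interruption) && !is.null(unknown) &&
        unknown[["start"]] < interruption[["end"]] &&
        interruption[["start"]] < unknown[["end"]]) {
      unknown <- NULL # overlapping draws: keep the interruption
    }

    nights[[i]] <- list(
      wake_date = wake_date, bed = bed, wake = wake,
      eve_on = bed - pre_gap - eve_len, eve_off = bed - pre_gap,
      morn_on = wake + post_gap, morn_off = wake + post_gap + morn_len,
      check = check, interruption = interruption, unknown = unknown
    )
  }

  # daytime Poisson sessions in each awake window
  sessions <- list()
  for (i in seq_len(n_days)) {
    win_start <- if (i == 1) {
      midnight(start_date - 1) + 12 * 3600
    } else {
      nights[[i - 1]]$morn_off
    }
    win_end <- nights[[i]]$eve_on
    sessions <- c(sessions, day_sessions(profile, win_start, win_end))
    sessions <- c(sessions, list(
      c(on = nights[[i]]$eve_on, off = nights[[i]]$eve_off),
      c(on = nights[[i]]$morn_on, off = nights[[i]]$morn_off)
    ))
    if (!is.null(nights[[i]]$check)) {
      sessions <- c(sessions, list(nights[[i]]$check))
    }
  }
  sess <- do.call(rbind, sessions)
  sess <- sess[order(sess[, "on"]), , drop = FALSE]
  # drop rare accidental overlaps from the Poisson layer
  keep <- c(TRUE, sess[-1, "on"] > sess[-nrow(sess), "off"])
  while (!all(keep)) {
    sess <- sess[keep, , drop = FALSE]
    keep <- c(TRUE, sess[-1, "on"] > sess[-nrow(sess), "off"])
  }

  events <- sessions_to_events(sess, profile, tz)
  segments <- truth_segments(nights, tz)
  episodes <- consolidate_ground_truth(segments)
  truth <- nightly_ground_truth(episodes)
  list(events = events, truth = truth, segments = segments)
}

session_len_sec <- function(profile) {
  max(round(rlnorm(1, profile$session_meanlog, profile$session_sdlog) * 60), 10)
}

sample_truth_segment <- function(prob, mean_len, bed, wake) {
  if (runif(1) >= prob) return(NULL)
  len <- round(rexp_mean(mean_len) * 60)
  lo <- bed + 1800
  hi <- wake - 1800 - len
  if (len <= 0 || hi <= lo) return(NULL)
  s <- round(runif(1, lo, hi))
  c(start = s, end = s + len)
}

day_sessions <- function(profile, win_start, win_end) {
  hours <- (win_end - win_start) / 3600
  if (hours <= 0 || profile$day_sessions_per_hour <= 0) return(list())
  n <- rpois(1, profile$day_sessions_per_hour * hours)
  if (n == 0) return(list())
  ons <- sort(round(runif(n, win_start, win_end)))
  out <- list()
  for (on in ons) {
    len <- session_len_sec(profile)
    if (on + len < win_end) out[[length(out) + 1]] <- c(on = on, off = on + len)
  }
  out
}

sessions_to_events <- function(sess, profile, tz) {
  ts <- numeric(0)
  kind <- character(0)
  for (r in seq_len(nrow(sess))) {
    on <- sess[r, "on"]
    off <- sess[r, "off"]
    ts <- c(ts, on)
    kind <- c(kind, "SCREEN_ON")
    if (runif(1) < profile$unlock_prob && off - on > 2) {
      ts <- c(ts, on + 1)
      kind <- c(kind, "PRESENT")
    }
    ts <- c(ts, off)
    kind <- c(kind, "SCREEN_OFF")
  }
  tibble::tibble(
    timestamp = lubridate::with_tz(
      as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"), tz),
    kind = kind
  )
}

truth_segments <- function(nights, tz) {
  rows <- list()
  for (nt in nights) {
    marks <- list()
    if (!is.null(nt$interruption)) {
      marks[[length(marks) + 1]] <-
        list(start = nt$interruption[["start"]],
             end = nt$interruption[["end"]], label = "interruption")
    }
    if (!is.null(nt$unknown)) {
      marks[[length(marks) + 1]] <-
        list(start = nt$unknown[["start"]], end = nt$unknown[["end"]],
             label = "unknown")
    }
    marks <- marks[order(vapply(marks, `[[`, numeric(1), "start"))]
    cursor <- nt$bed
    for (m in marks) {
      if (m$start > cursor) {
        rows[[length(rows) + 1]] <-
          list(start = cursor, end = m$start, label = "sleep")
      }
      rows[[length(rows) + 1]] <- m
      cursor <- m$end
    }
    if (cursor < nt$wake) {
      rows[[length(rows) + 1]] <-
        list(start = cursor, end = nt$wake, label = "sleep")
    }
  }
  tibble::tibble(
    start = as_posix(vapply(rows, `[[`, numeric(1), "start"), tz),
    end = as_posix(vapply(rows, `[[`, numeric(1), "end"), tz),
    label = vapply(rows, `[[`, character(1), "label")
  )
}

as_posix <- function(x, tz) {
  lubridate::with_tz(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"), tz)
}

empty_truth <- function(tz = "UTC") {
  t0 <- as_posix(numeric(0), tz)
  tibble::tibble(night_date = as.Date(character()), start = t0, end = t0,
                 gross_min = numeric(), net_min = numeric())
}

empty_segments <- function(tz = "UTC") {
  t0 <- as_posix(numeric(0), tz)
  tibble::tibble(start = t0, end = t0, label = character())
}

#' Consolidate labelled sleep segments into nightly episodes
#'
#' Applies the smartwatch ground-truth rules: an interruption shorter than
#' `max_bridge` minutes between two sleep segments keeps the night as one
#' episode but its length is subtracted from the net duration; an unknown
#' segment shorter than `max_bridge` between two sleeps counts fully as
#' sleep; an interruption or unknown of `max_bridge` minutes or longer
#' ("less than 15 min" is strict) splits the night into separate episodes.
#' Plain gaps in coverage also split episodes.
#'
#' @param segments Tibble of labelled segments (`start`, `end`, `label`
#'   in `sleep` / `interruption` / `unknown`), sorted and non-overlapping.
#' @param max_bridge Bridging threshold in minutes (default 15).
#' @return A tibble of consolidated episodes: `night_date` (wake date of
#'   the analysis window containing the episode end), `start`, `end`,
#'   `gross_min`, `net_min`.
#' @export
#' @examples
#' tz <- "UTC"
#' seg <- tibble::tibble(
#'   start = as.POSIXct(c("2016-01-04 23:00", "2016-01-05 03:00",
#'                        "2016-01-05 03:10"), tz = tz),
#'   end = as.POSIXct(c("2016-01-05 03:00", "2016-01-05 03:10",
#'                      "2016-01-05 07:00"), tz = tz),
#'   label = c("sleep", "interruption", "sleep")
#' )
#' consolidate_ground_truth(seg) # one episode, net 470 min
consolidate_ground_truth <- function(segments, max_bridge = 15) {
  if (nrow(segments) == 0) {
    return(empty_truth(attr(segments$start, "tzone") %||% "UTC"))
  }
  if (is.unsorted(segments$start)) {
    segments <- dplyr::arrange(segments, .data$start)
  }
  if (nrow(segments) > 1 &&
      any(diff_min(segments$start[-1], segments$end[-nrow(segments)]) < 0)) {
    abort("ground-truth segments overlap")
  }
  if (!all(segments$label %in% c("sleep", "interruption", "unknown"))) {
    abort("segment labels must be sleep/interruption/unknown")
  }

  episodes <- list()
  ep <- NULL          # open episode: list(start, end, net_sec)
  pending <- list()   # non-sleep segments since the last sleep segment
  close_ep <- function() {
    if (!is.null(ep)) episodes[[length(episodes) + 1]] <<- ep
    ep <<- NULL
    pending <<- list()
  }
  cursor <- segments$start[1]
  for (i in seq_len(nrow(segments))) {
    s_start <- segments$start[i]
    s_end <- segments$end[i]
    lab <- segments$label[i]
    if (diff_min(s_start, cursor) > 0) close_ep() # uncovered gap
    cursor <- s_end
    if (lab == "sleep") {
      if (is.null(ep)) {
        ep <- list(start = s_start, end = s_end,
                   net = diff_min(s_end, s_start))
        pending <- list()
        next
      }
      lens <- vapply(pending, function(p) diff_min(p$end, p$start), numeric(1))
      if (length(pending) > 0 && any(lens >= max_bridge)) {
        close_ep()
        ep <- list(start = s_start, end = s_end,
                   net = diff_min(s_end, s_start))
      } else {
        extra <- sum(vapply(pending, function(p) {
          if (p$label == "unknown") diff_min(p$end, p$start) else 0
        }, numeric(1)))
        ep$net <- ep$net + diff_min(s_end, s_start) + extra
        ep$end <- s_end
        pending <- list()
      }
    } else {
      if (is.null(ep)) next # leading non-sleep: ignored
      pending[[length(pending) + 1]] <-
        list(start = s_start, end = s_end, label = lab)
    }
  }
  close_ep()

  if (length(episodes) == 0) {
    return(empty_truth(attr(segments$start, "tzone") %||% "UTC"))
  }
  starts <- do.call(c, lapply(episodes, `[[`, "start"))
  ends <- do.call(c, lapply(episodes, `[[`, "end"))
  gross <- diff_min(ends, starts)
  tibble::tibble(
    night_date = night_window_date(ends),
    start = starts,
    end = ends,
    gross_min = gross,
    # summing sub-segment minutes can overshoot the span by an ulp
    net_min = pmin(vapply(episodes, `[[`, numeric(1), "net"), gross)
  )
}

#' Keep the longest consolidated episode per night
#'
#' The night's ground truth is its longest consolidated sleep episode
#' (ties break towards the earlier start).
#'
#' @param episodes Output of [consolidate_ground_truth()].
#' @return One row per `night_date`.
#' @export
nightly_ground_truth <- function(episodes) {
  episodes |>
    dplyr::arrange(.data$night_date, dplyr::desc(.data$net_min), .data$start) |>
    dplyr::distinct(.data$night_date, .keep_all = TRUE)
}

#' Read / write nightly ground truth as CSV
#'
#' Canonical columns: `night_date,start,end,net_min` with ISO-8601
#' timestamps.
#'
#' @param truth Nightly ground-truth tibble.
#' @param path File path.
#' @param tz Timezone for reading timestamps back.
#' @return `read_ground_truth()` returns the tibble; the writer returns
#'   `path` invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- tibble::tibble(
    night_date = truth$night_date,
    start = iso8601_offset(truth$start),
    end = iso8601_offset(truth$end),
    net_min = truth$net_min
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path, tz = "UTC") {
  raw <- readr::read_csv(path, col_types = readr::cols(
    night_date = readr::col_date(),
    start = readr::col_character(),
    end = readr::col_character(),
    net_min = readr::col_double()
  ), progress = FALSE)
  tibble::tibble(
    night_date = raw$night_date,
    start = lubridate::with_tz(lubridate::ymd_hms(raw$start, tz = "UTC"), tz),
    end = lubridate::with_tz(lubridate::ymd_hms(raw$end, tz = "UTC"), tz),
    gross_min = diff_min(
      lubridate::ymd_hms(raw$end, tz = "UTC"),
      lubridate::ymd_hms(raw$start, tz = "UTC")),
    net_min = raw$net_min
  )
}
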