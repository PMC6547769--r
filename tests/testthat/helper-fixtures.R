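# Fixtures are built in code; everything lives in UTC so wall-clock and
# absolute time coincide and expected values are easy to hand-trace.

utc <- function(x) as.POSIXct(x, tz = "UTC")

`%||%` <- function(a, b) if (is.null(a)) b else a

make_events <- function(times, kinds) {
  tibble::tibble(timestamp = utc(times), kind = kinds)
}

make_sessions <- function(on, off, unlocked = FALSE) {
  tibble::tibble(on_time = utc(on), off_time = utc(off),
                 unlocked = rep_len(unlocked, length(on)))
}

# random, sorted, non-overlapping session stream with a mix of short and
# sleep-scale gaps; used by the brute-force oracle tests
random_sessions <- function(n, seed) {
  set.seed(seed)
  gaps_min <- rexp(n, 1 / 90) + ifelse(runif(n) < 0.15, 300, 0)
  lens_min <- runif(n, 0.5, 20)
  on <- cumsum(gaps_min + dplyr::lag(lens_min, default = 0)) * 60
  make_sessions(
    as.POSIXct(on, origin = "2016-03-01", tz = "UTC"),
    as.POSIXct(on + lens_min * 60, origin = "2016-03-01", tz = "UTC")
  )
}

# brute-force re-statement of the candidate rule: every consecutive pair of
# sessions separated by >= min_gap minutes
brute_force_candidates <- function(sessions, min_gap = 240) {
  out <- list()
  for (i in seq_len(nrow(sessions) - 1)) {
    gap <- as.numeric(difftime(sessions$on_time[i + 1], sessions$off_time[i],
                               units = "mins"))
    if (gap >= min_gap) {
      out[[length(out) + 1]] <- tibble::tibble(
        start = sessions$off_time[i], end = sessions$on_time[i + 1])
    }
  }
  if (length(out) == 0) {
    tibble::tibble(start = sessions$off_time[0], end = sessions$on_time[0])
  } else {
    dplyr::bind_rows(out)
  }
}

# idealized profile: the phone goes dark exactly at sleep onset and lights
# up exactly at wake, with no night checks and clean ground truth
zero_gap_profile <- function() {
  user_profile("student",
               pre_sleep_gap_mean = 0, post_wake_gap_mean = 0,
               night_check_prob = 0, interruption_prob = 0,
               unknown_prob = 0)
}

make_segments <- function(start, end, label) {
  tibble::tibble(start = utc(start), end = utc(end), label = label)
}
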