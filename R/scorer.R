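# Likelihood scoring and overnight-episode selection (stage 2).
#
# Every candidate gets three unit-interval scores — closeness of its start
# to a habitual bedtime anchor, of its end to the user's habitual wake
# time (weekday/weekend specific), and of its net duration to a
# recommended duration — each an exponential decay exp(-distance/tau). The
# product of the three is the episode's likelihood, and the best candidate
# per night wins.

#' Scorer configuration
#'
#' @param bed_anchor Assumed habitual time to bed, local time of day
#'   (default `"22:00"` — 10 pm).
#' @param tau_bed,tau_wake,tau_dur Decay scales, in minutes, of the three
#'   scores (default 120 each, the same scale as the detector's two-hour
#'   lookback).
#' @param dur_anchor Reference sleep duration in minutes (default 480, the
#'   midpoint of the recommended 420-540 band).
#' @return A list of class `scorer_config`.
#' @export
scorer_config <- function(bed_anchor = "22:00", tau_bed = 120,
                          tau_wake = 120, tau_dur = 120, dur_anchor = 480) {
  if (any(c(tau_bed, tau_wake, tau_dur) <= 0)) abort("taus must be > 0")
  if (dur_anchor <= 0) abort("dur_anchor must be > 0")
  structure(
    list(bed_anchor = parse_tod(bed_anchor), tau_bed = tau_bed,
         tau_wake = tau_wake, tau_dur = tau_dur, dur_anchor = dur_anchor),
    class = "scorer_config"
  )
}

#' Habitual wake-time profile
#'
#' Holds a user's typical wake time of day, weekday and weekend separately,
#' estimated from the whole log.
#'
#' @param wake_weekday,wake_weekend Local times of day (`"HH:MM"`, hms, or
#'   minutes after midnight).
#' @param derived_from Number of nights the profile was estimated from.
#' @return A list of class `habitual_profile` storing the times as minutes
#'   after midnight.
#' @export
habitual_profile <- function(wake_weekday = "08:00", wake_weekend = "08:00",
                             derived_from = 0L) {
  structure(
    list(wake_weekday = parse_tod(wake_weekday),
         wake_weekend = parse_tod(wake_weekend),
         derived_from = as.integer(derived_from)),
    class = "habitual_profile"
  )
}

#' Estimate a habitual wake time from observed episode ends
#'
#' Circular median of end-of-episode wall-clock times for the requested day
#' type, falling back to the pooled observations when that day type has
#' none, and to 08:00 when there are no observations at all.
#'
#' @param ends POSIXct vector of episode end times.
#' @param end_day_type Character vector (`"weekday"`/`"weekend"`) parallel
#'   to `ends`; defaults to classifying each end's wake date.
#' @param day_type Which day type to estimate for.
#' @return Wake time of day as an [hms::hms] value.
#' @export
estimate_habitual_wake <- function(ends,
                                   end_day_type = day_type_of(night_window_date(ends)),
                                   day_type = c("weekday", "weekend")) {
  day_type <- match.arg(day_type)
  keep <- !is.na(ends)
  ends <- ends[keep]
  end_day_type <- end_day_type[keep]
  use <- ends[end_day_type == day_type]
  if (length(use) == 0) use <- ends
  if (length(use) == 0) return(hms::hms(minutes = 480))
  hms::hms(minutes = circular_median_tod(tod_minutes(use)))
}

#' Score a candidate bedtime against the habitual bed anchor
#'
#' `exp(-d / tau_bed)` where `d` is the circular distance in minutes
#' between the start's wall-clock time and `bed_anchor`; 21:00 and 23:00
#' are equidistant from the default 22:00 anchor.
#'
#' @param start POSIXct vector of candidate start times.
#' @param config A [scorer_config()].
#' @return Scores in `(0, 1]`.
#' @export
score_bedtime <- function(start, config = scorer_config()) {
  exp(-circular_diff_min(tod_minutes(start), config$bed_anchor) / config$tau_bed)
}

#' Score a candidate wake time against the habitual wake time
#'
#' `exp(-d / tau_wake)` where `d` is the circular distance between the
#' end's wall-clock time and the day-type-appropriate habitual wake time.
#'
#' @param end POSIXct vector of candidate end times.
#' @param profile A [habitual_profile()].
#' @param day_type `"weekday"` or `"weekend"` (vector recycles against
#'   `end`).
#' @param config A [scorer_config()].
#' @return Scores in `(0, 1]`.
#' @export
score_wake <- function(end, profile, day_type, config = scorer_config()) {
  anchor <- ifelse(day_type == "weekend", profile$wake_weekend, profile$wake_weekday)
  exp(-circular_diff_min(tod_minutes(end), anchor) / config$tau_wake)
}

#' Score a candidate's net duration against the recommended duration
#'
#' `exp(-|net - dur_anchor| / tau_dur)`; symmetric about the 480-min
#' anchor, so 7 h and 9 h score alike.
#'
#' @param net_min Net episode durations in minutes (break time excluded).
#' @param config A [scorer_config()].
#' @return Scores in `(0, 1]`.
#' @export
score_duration <- function(net_min, config = scorer_config()) {
  exp(-abs(net_min - config$dur_anchor) / config$tau_dur)
}

#' Score candidates on all three criteria
#'
#' Adds `day_type`, the three component scores, and their product
#' `likelihood` to a candidate tibble.
#'
#' @param candidates Candidate tibble from [detect_nights()].
#' @param profile A [habitual_profile()].
#' @param config A [scorer_config()].
#' @return The candidate tibble with columns `day_type`, `s_bed`,
#'   `s_wake`, `s_dur`, `likelihood` appended.
#' @export
score_candidates <- function(candidates, profile, config = scorer_config()) {
  candidates$day_type <- day_type_of(candidates$night_date)
  candidates$s_bed <- score_bedtime(candidates$start, config)
  candidates$s_wake <- score_wake(candidates$end, profile,
                                  candidates$day_type, config)
  candidates$s_dur <- score_duration(candidates$net_min, config)
  candidates$likelihood <- candidates$s_bed * candidates$s_wake * candidates$s_dur
  candidates
}

#' Select the most probable overnight episode per night
#'
#' Scores every candidate and keeps, within each analysis window, the one
#' with the highest likelihood; ties break towards larger net duration,
#' then earlier start. Nights with no candidates contribute no rows (no
#' estimate).
#'
#' @inheritParams score_candidates
#' @return One scored row per night present in `candidates`, sorted by
#'   `night_date`.
#' @export
select_overnight_episode <- function(candidates, profile,
                                     config = scorer_config()) {
  scored <- score_candidates(candidates, profile, config)
  if (nrow(scored) == 0) return(scored)
  scored |>
    dplyr::arrange(.data$night_date, dplyr::desc(.data$likelihood),
                   dplyr::desc(.data$net_min), .data$start) |>
    dplyr::distinct(.data$night_date, .keep_all = TRUE)
}

#' Estimate nightly sleep from a session stream
#'
#' The full two-stage pipeline. Candidates are detected and refined
#' ([detect_nights()]); a provisional habitual wake profile is seeded from
#' the end of each night's longest candidate (circular medians, weekday and
#' weekend separately); episodes are selected; and the profile is
#' re-estimated once from the selected episodes before a final selection
#' pass. On regular sleepers the refinement pass is a fixpoint and changes
#' nothing.
#'
#' @param sessions Session tibble from [pair_sessions()].
#' @param detector A [detector_config()].
#' @param scorer A [scorer_config()].
#' @return A tibble of nightly estimates: `night_date`, `day_type`,
#'   `start`, `end`, `gross_min`, `net_min`, `likelihood`, `s_bed`,
#'   `s_wake`, `s_dur`, with the final [habitual_profile()] attached as
#'   attribute `"profile"`.
#' @export
#' @examples
#' sim <- sample_user_days(user_profile("student"), n_days = 5, seed = 7)
#' estimate_sleep(pair_sessions(sim$events))
estimate_sleep <- function(sessions, detector = detector_config(),
                           scorer = scorer_config()) {
  cands <- detect_nights(sessions, detector)
  if (nrow(cands) == 0) {
    out <- score_candidates(cands, habitual_profile(), scorer)
    attr(out, "profile") <- habitual_profile()
    return(out)
  }
  seeds <- cands |>
    dplyr::arrange(.data$night_date, dplyr::desc(.data$net_min), .data$start) |>
    dplyr::distinct(.data$night_date, .keep_all = TRUE)
  prof <- profile_from_ends(seeds$end, day_type_of(seeds$night_date))
  sel <- select_overnight_episode(cands, prof, scorer)
  prof2 <- profile_from_ends(sel$end, sel$day_type)
  out <- select_overnight_episode(cands, prof2, scorer) |>
    dplyr::select("night_date", "day_type", "start", "end", "gross_min",
                  "net_min", "likelihood", "s_bed", "s_wake", "s_dur",
                  "breaks")
  attr(out, "profile") <- prof2
  out
}

profile_from_ends <- function(ends, day_types) {
  habitual_profile(
    wake_weekday = estimate_habitual_wake(ends, day_types, "weekday"),
    wake_weekend = estimate_habitual_wake(ends, day_types, "weekend"),
    derived_from = length(ends)
  )
}
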