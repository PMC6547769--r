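# Candidate sleep-episode detection (stage 1 of the two-stage estimator).
#
# Stage 1 is deliberately permissive: every OFF -> ON gap of at least
# min_gap is a candidate sleep episode, and bedtimes are walked back across
# brief mid-night phone checks. Choosing which candidate is the overnight
# sleep is the scorer's job (stage 2).

#' Detector configuration
#'
#' Constants governing candidate enumeration and bedtime refinement.
#'
#' @param min_gap Minimum OFF -> ON gap, in minutes, for an interval to
#'   count as a candidate sleep episode (default 240, i.e. "at least
#'   4 hours"; the threshold is inclusive).
#' @param cluster_radius Events closer together than this many minutes are
#'   chained into one interaction cluster when deciding whether an OFF was
#'   a genuine bedtime or the tail of a brief night check (default 5).
#' @param lookback_min Minimum separation, in minutes, between a candidate
#'   night-check cluster and the earlier SCREEN_OFF that replaces it as
#'   bedtime (default 120, i.e. "at least 2 hours earlier that night").
#' @param window_anchor Local time of day splitting consecutive analysis
#'   windows; a night is the window from this anchor on day D to the anchor
#'   on day D+1 (default noon).
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(min_gap = 240, cluster_radius = 5,
                            lookback_min = 120, window_anchor = "12:00") {
  anchor <- parse_tod(window_anchor)
  if (!(min_gap > lookback_min && lookback_min > cluster_radius &&
        cluster_radius > 0)) {
    abort("need min_gap > lookback_min > cluster_radius > 0")
  }
  structure(
    list(min_gap = min_gap, cluster_radius = cluster_radius,
         lookback_min = lookback_min, window_anchor = anchor),
    class = "detector_config"
  )
}

empty_candidates <- function(sessions) {
  t0 <- sessions$off_time[0]
  tibble::tibble(
    night_date = as.Date(character()),
    start = t0, end = t0,
    gross_min = numeric(), net_min = numeric(),
    breaks = list()
  )
}

#' Enumerate candidate sleep episodes from session gaps
#'
#' Emits one candidate per pair of consecutive sessions separated by at
#' least `min_gap` minutes (OFF of the earlier to ON of the later). The
#' scan covers the whole stream, so daytime no-usage blocks also surface as
#' candidates; ranking them against the true night is the scorer's job.
#'
#' @param sessions Session tibble from [pair_sessions()], sorted and
#'   non-overlapping.
#' @param config A [detector_config()].
#' @return A candidate tibble with columns `night_date` (wake date of the
#'   analysis window containing the gap's end), `start`, `end`,
#'   `gross_min`, `net_min`, and `breaks` (list column of per-candidate
#'   break tibbles, empty at this stage).
#' @export
enumerate_gap_candidates <- function(sessions, config = detector_config()) {
  n <- nrow(sessions)
  if (n < 2) return(empty_candidates(sessions))
  gap <- diff_min(sessions$on_time[-1], sessions$off_time[-n])
  i <- which(gap >= config$min_gap)
  if (length(i) == 0) return(empty_candidates(sessions))
  start <- sessions$off_time[i]
  end <- sessions$on_time[i + 1]
  tibble::tibble(
    night_date = night_window_date(end, config$window_anchor),
    start = start,
    end = end,
    gross_min = diff_min(end, start),
    net_min = diff_min(end, start),
    breaks = replicate(length(i), empty_breaks(start), simplify = FALSE)
  )
}

empty_breaks <- function(template) {
  tibble::tibble(break_start = template[0], break_end = template[0])
}

#' Walk a candidate's bedtime back across mid-night phone checks
#'
#' A candidate's start is the last SCREEN_OFF before a long gap — but that
#' OFF may close a brief mid-night phone check rather than the true
#' bedtime. For each candidate this walks backwards: if the session ending
#' at the current start belongs to a short interaction cluster (sessions
#' chained together by event gaps under `cluster_radius`, or a lone session
#' shorter than `cluster_radius`), and an earlier session's OFF lies at
#' least `lookback_min` before that cluster within the same analysis
#' window, the start moves back to that OFF and the cluster is recorded as
#' an in-sleep break. The rule fires repeatedly, so several night checks
#' are absorbed. Gross span never shrinks and the end never moves; net
#' duration subtracts total break time.
#'
#' @param candidates Candidate tibble from [enumerate_gap_candidates()].
#' @param sessions The same session stream the candidates came from.
#' @param config A [detector_config()].
#' @return The candidate tibble with updated `start`, `breaks`,
#'   `gross_min`, `net_min`.
#' @export
refine_bedtime <- function(candidates, sessions, config = detector_config()) {
  if (nrow(candidates) == 0) return(candidates)
  for (r in seq_len(nrow(candidates))) {
    ref <- refine_one(candidates$start[r], candidates$end[r],
                      candidates$night_date[r], sessions, config)
    candidates$start[r] <- ref$start
    candidates$breaks[[r]] <- ref$breaks
  }
  candidates$gross_min <- diff_min(candidates$end, candidates$start)
  candidates$net_min <- candidates$gross_min -
    vapply(candidates$breaks, function(b) {
      if (nrow(b) == 0) 0 else sum(diff_min(b$break_end, b$break_start))
    }, numeric(1))
  candidates
}

refine_one <- function(start, end, night_date, sessions, config) {
  breaks <- empty_breaks(sessions$off_time)
  idx <- match(as.numeric(start), as.numeric(sessions$off_time))
  if (is.na(idx)) {
    return(list(start = start, breaks = breaks))
  }
  repeat {
    # grow the interaction cluster backwards from session idx
    lo <- idx
    while (lo > 1 &&
           diff_min(sessions$on_time[lo], sessions$off_time[lo - 1]) <
             config$cluster_radius) {
      lo <- lo - 1
    }
    own_len <- diff_min(sessions$off_time[idx], sessions$on_time[idx])
    is_check <- lo < idx || own_len < config$cluster_radius
    if (!is_check || lo == 1) break
    prev_off <- sessions$off_time[lo - 1]
    gap_back <- diff_min(sessions$on_time[lo], prev_off)
    same_night <- night_window_date(prev_off, config$window_anchor) == night_date
    if (gap_back < config$lookback_min || !same_night) break
    breaks <- dplyr::bind_rows(
      tibble::tibble(break_start = sessions$on_time[lo],
                     break_end = sessions$off_time[idx]),
      breaks
    )
    idx <- lo - 1
  }
  list(start = sessions$off_time[idx],
       breaks = dplyr::arrange(breaks, .data$break_start))
}

#' Detect sleep candidates for every night in a log
#'
#' Runs candidate enumeration over the whole session stream, refines each
#' candidate's bedtime, and labels every candidate with the wake date of
#' the noon-to-noon analysis window containing its end. Wherever the
#' refinement moved a bedtime, the unrefined original is kept as a
#' separate candidate: the lookback rule cannot tell a brief mid-night
#' check from a genuinely brief last interaction of the evening, so the
#' detector stays permissive and leaves the disambiguation to the scorer
#' (a real night check scores far better refined; a mis-walked bedtime
#' loses to its original). Windows that yield no candidate simply have no
#' rows ("no estimate" nights).
#'
#' @inheritParams enumerate_gap_candidates
#' @return A candidate tibble sorted by `night_date` then `start`.
#' @export
#' @examples
#' sim <- sample_user_days(user_profile("student"), n_days = 3, seed = 1)
#' detect_nights(pair_sessions(sim$events))
detect_nights <- function(sessions, config = detector_config()) {
  raw <- enumerate_gap_candidates(sessions, config)
  refined <- refine_bedtime(raw, sessions, config)
  moved <- refined$start != raw$start
  cands <- dplyr::bind_rows(refined, raw[moved, , drop = FALSE])
  dplyr::arrange(cands, .data$night_date, .data$start)
}
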