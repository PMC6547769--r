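# Validation against ground truth: per-night absolute errors, stratified
# summaries, a paired one-tailed t test on durations, and classification
# against the recommended 7-9 h sleep band.

#' Match estimated nights to ground truth
#'
#' Inner join on `night_date`; nights present on only one side are counted
#' (attributes `n_unmatched_est`, `n_unmatched_truth`) and excluded from
#' error means. All error fields are absolute values.
#'
#' @param estimates Nightly estimates from [estimate_sleep()].
#' @param truth Nightly ground truth (e.g. from [sample_user_days()]).
#' @return A tibble of per-night comparisons: `night_date`, `day_type`,
#'   `est_start`, `est_end`, `est_dur_min`, `truth_start`, `truth_end`,
#'   `truth_dur_min`, `dur_err_min`, `dur_err_pct`, `start_diff_min`,
#'   `end_diff_min`.
#' @export
match_nights <- function(estimates, truth) {
  if (anyDuplicated(estimates$night_date)) {
    abort("duplicate night_date in estimates")
  }
  if (anyDuplicated(truth$night_date)) {
    abort("duplicate night_date in ground truth")
  }
  est <- dplyr::select(estimates, "night_date",
                       est_start = "start", est_end = "end",
                       est_dur_min = "net_min")
  tru <- dplyr::select(truth, "night_date",
                       truth_start = "start", truth_end = "end",
                       truth_dur_min = "net_min")
  cmp <- dplyr::inner_join(est, tru, by = "night_date") |>
    dplyr::mutate(
      day_type = day_type_of(.data$night_date),
      dur_err_min = abs(.data$est_dur_min - .data$truth_dur_min),
      dur_err_pct = 100 * .data$dur_err_min / .data$truth_dur_min,
      start_diff_min = abs(diff_min(.data$est_start, .data$truth_start)),
      end_diff_min = abs(diff_min(.data$est_end, .data$truth_end))
    ) |>
    dplyr::relocate("day_type", .after = "night_date")
  attr(cmp, "n_unmatched_est") <- nrow(estimates) - nrow(cmp)
  attr(cmp, "n_unmatched_truth") <- nrow(truth) - nrow(cmp)
  cmp
}

EVAL_METRICS <- c("dur_err_min", "dur_err_pct", "start_diff_min",
                  "end_diff_min", "est_dur_min", "truth_dur_min")

#' Summarise comparison errors by day-type stratum
#'
#' Arithmetic mean and sample SD (n-1 denominator) of each error metric
#' and of the estimated / ground-truth durations, for all days, weekdays
#' only, and weekend (Saturday/Sunday wake date) only. Empty strata keep
#' their row with `n = 0` and `NA` statistics.
#'
#' @param comparisons Output of [match_nights()].
#' @param strata Which strata to report.
#' @return A long tibble: `stratum`, `n`, `metric`, `mean`, `sd`.
#' @export
aggregate_errors <- function(comparisons,
                             strata = c("all", "weekday", "weekend")) {
  strata <- match.arg(strata, several.ok = TRUE)
  rows <- lapply(strata, function(st) {
    sub <- if (st == "all") comparisons else
      comparisons[comparisons$day_type == st, , drop = FALSE]
    tibble::tibble(
      stratum = st,
      n = nrow(sub),
      metric = EVAL_METRICS,
      mean = vapply(EVAL_METRICS, function(m) {
        if (nrow(sub) == 0) NA_real_ else mean(sub[[m]])
      }, numeric(1), USE.NAMES = FALSE),
      sd = vapply(EVAL_METRICS, function(m) {
        if (nrow(sub) < 2) NA_real_ else sd(sub[[m]])
      }, numeric(1), USE.NAMES = FALSE)
    )
  })
  dplyr::bind_rows(rows)
}

#' Paired one-tailed t test of estimated vs ground-truth durations
#'
#' Tests the per-night differences `est - truth`, with the tail chosen in
#' the direction of the observed mean difference. The verdict is
#' `"adequate"` when `p > alpha` (no significant difference between the
#' estimator and the reference); when significant, the direction reports
#' whether the estimator over- or under-estimates. Identically zero
#' differences (perfect agreement) give `t = 0`, `p = 0.5` by the
#' zero-limit convention.
#'
#' @param est_durs,truth_durs Paired duration vectors, minutes.
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble: `t`, `df`, `p`, `verdict`
#'   (`adequate`/`significant`), `direction` (`over`/`under`, `NA` unless
#'   significant), `mean_diff`.
#' @export
paired_one_tailed_t <- function(est_durs, truth_durs, alpha = 0.05) {
  if (length(est_durs) != length(truth_durs)) {
    abort("paired vectors must have equal length")
  }
  n <- length(est_durs)
  if (n < 2) abort("need at least 2 paired observations")
  d <- est_durs - truth_durs
  md <- mean(d)
  if (all(d == 0)) {
    t_stat <- 0
    p <- 0.5
  } else if (sd(d) == 0) {
    # constant non-zero difference: the zero-variance limit
    t_stat <- sign(md) * Inf
    p <- 0
  } else {
    alt <- if (md > 0) "greater" else "less"
    tt <- stats::t.test(est_durs, truth_durs, paired = TRUE, alternative = alt)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  significant <- p <= alpha
  tibble::tibble(
    t = t_stat,
    df = n - 1,
    p = p,
    verdict = if (significant) "significant" else "adequate",
    direction = if (significant) {
      if (md > 0) "over" else "under"
    } else NA_character_,
    mean_diff = md
  )
}

#' Classify mean sleep duration against the recommended band
#'
#' Recommended nightly sleep for healthy adults is 7-9 h (420-540 min):
#' below 420 is sleep-deprived, above 540 is long, and the boundaries are
#' inclusive into `"adequate"`.
#'
#' @param mean_dur_min Mean nightly sleep duration(s), minutes.
#' @param low,high Band edges in minutes (defaults 420 and 540).
#' @return Character vector: `"deprived"`, `"adequate"`, or `"long"`.
#' @export
#' @examples
#' classify_deprivation(c(377, 420, 541))
classify_deprivation <- function(mean_dur_min, low = 420, high = 540) {
  stopifnot(all(mean_dur_min > 0))
  dplyr::case_when(
    mean_dur_min < low ~ "deprived",
    mean_dur_min > high ~ "long",
    TRUE ~ "adequate"
  )
}

#' Evaluate sleep estimates against ground truth
#'
#' Bundles the whole validation: per-night comparisons, stratified error
#' summaries, the paired one-tailed t test on durations, and deprivation
#' classification of the estimated and reference mean durations.
#'
#' @param estimates Nightly estimates from [estimate_sleep()].
#' @param truth Nightly ground truth.
#' @param alpha Significance level for the t test.
#' @return An object of class `sleep_evaluation`: a list with
#'   `comparisons`, `summary`, `t_test`, `deprivation`, `n_unmatched_est`,
#'   `n_unmatched_truth`. Supports [tidy()], [glance()], [print()], and
#'   [ggplot2::autoplot()].
#' @export
#' @examples
#' sim <- sample_user_days(user_profile("student"), n_days = 10, seed = 3)
#' est <- estimate_sleep(pair_sessions(sim$events))
#' evaluate_sleep(est, sim$truth)
evaluate_sleep <- function(estimates, truth, alpha = 0.05) {
  cmp <- match_nights(estimates, truth)
  if (nrow(cmp) < 2) {
    tt <- tibble::tibble(t = NA_real_, df = NA_real_, p = NA_real_,
                         verdict = NA_character_, direction = NA_character_,
                         mean_diff = NA_real_)
  } else {
    tt <- paired_one_tailed_t(cmp$est_dur_min, cmp$truth_dur_min, alpha)
  }
  depr <- tibble::tibble(
    source = c("estimate", "truth"),
    mean_dur_min = c(mean(cmp$est_dur_min), mean(cmp$truth_dur_min)),
    classification = if (nrow(cmp) == 0) NA_character_ else
      classify_deprivation(c(mean(cmp$est_dur_min), mean(cmp$truth_dur_min)))
  )
  structure(
    list(
      comparisons = cmp,
      summary = aggregate_errors(cmp),
      t_test = tt,
      deprivation = depr,
      n_unmatched_est = attr(cmp, "n_unmatched_est"),
      n_unmatched_truth = attr(cmp, "n_unmatched_truth"),
      alpha = alpha
    ),
    class = "sleep_evaluation"
  )
}

#' @export
print.sleep_evaluation <- function(x, ...) {
  cat("Sleep evaluation over", nrow(x$comparisons), "matched nights",
      sprintf("(%d est / %d truth unmatched)\n",
              x$n_unmatched_est, x$n_unmatched_truth))
  all_rows <- x$summary[x$summary$stratum == "all", ]
  for (m in c("dur_err_min", "dur_err_pct", "start_diff_min", "end_diff_min")) {
    r <- all_rows[all_rows$metric == m, ]
    cat(sprintf("  %-15s mean %6.1f (SD %5.1f)\n", m, r$mean, r$sd))
  }
  if (!is.na(x$t_test$p)) {
    cat(sprintf("  paired one-tailed t: t = %.3f, p = %.3f -> %s%s\n",
                x$t_test$t, x$t_test$p, x$t_test$verdict,
                if (!is.na(x$t_test$direction)) {
                  paste0(" (", x$t_test$direction, "-estimates)")
                } else ""))
  }
  cat(sprintf("  mean duration: estimate %.0f min (%s), truth %.0f min (%s)\n",
              x$deprivation$mean_dur_min[1], x$deprivation$classification[1],
              x$deprivation$mean_dur_min[2], x$deprivation$classification[2]))
  invisible(x)
}

#' Tidy a sleep evaluation
#'
#' @param x A `sleep_evaluation`.
#' @param ... Unused.
#' @return The long summary tibble (`stratum`, `n`, `metric`, `mean`,
#'   `sd`).
#' @importFrom generics tidy
#' @export
tidy.sleep_evaluation <- function(x, ...) {
  x$summary
}

#' @export
generics::tidy

#' One-row summary of a sleep evaluation
#'
#' @param x A `sleep_evaluation`.
#' @param ... Unused.
#' @return A one-row tibble with matched-night count, mean errors, the t
#'   test, and deprivation classifications.
#' @importFrom generics glance
#' @export
glance.sleep_evaluation <- function(x, ...) {
  all_mean <- function(m) {
    x$summary$mean[x$summary$stratum == "all" & x$summary$metric == m]
  }
  tibble::tibble(
    n_nights = nrow(x$comparisons),
    n_unmatched_est = x$n_unmatched_est,
    n_unmatched_truth = x$n_unmatched_truth,
    dur_err_min = all_mean("dur_err_min"),
    dur_err_pct = all_mean("dur_err_pct"),
    start_diff_min = all_mean("start_diff_min"),
    end_diff_min = all_mean("end_diff_min"),
    mean_est_dur = x$deprivation$mean_dur_min[1],
    mean_truth_dur = x$deprivation$mean_dur_min[2],
    t = x$t_test$t,
    p = x$t_test$p,
    verdict = x$t_test$verdict,
    direction = x$t_test$direction,
    deprivation_est = x$deprivation$classification[1],
    deprivation_truth = x$deprivation$classification[2]
  )
}

#' @export
generics::glance
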