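# Plotting. ggplot2 throughout; every result type gets either an
# autoplot() method or a plot_*() helper.

#' Plot nightly durations of an evaluation against the recommended band
#'
#' Estimated and ground-truth net durations per night, with the
#' recommended-sleep band marked at 7 h (420 min) and 9 h (540 min).
#'
#' @param object A `sleep_evaluation` from [evaluate_sleep()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sleep_evaluation <- function(object, ...) {
  cmp <- object$comparisons
  long <- tidyr::pivot_longer(
    dplyr::select(cmp, "night_date", estimate = "est_dur_min",
                  truth = "truth_dur_min"),
    c("estimate", "truth"),
    names_to = "source", values_to = "dur_min"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$night_date, .data$dur_min,
                                     colour = .data$source)) +
    ggplot2::geom_hline(yintercept = 420, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_hline(yintercept = 540, linetype = "dashed",
                        colour = "goldenrod3") +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "wake date", y = "net sleep duration (min)",
                  colour = NULL,
                  title = "Nightly sleep duration vs ground truth",
                  subtitle = "dashed lines: recommended 7-9 h band") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Timeline plot of screen sessions and detected sleep
#'
#' Each session is a vertical tick at its local time of day against its
#' analysis-window date; estimated sleep episodes (if supplied) are drawn
#' as shaded spans, making mis-detected nights easy to spot.
#'
#' @param sessions Session tibble from [pair_sessions()].
#' @param estimates Optional nightly estimates from [estimate_sleep()].
#' @return A ggplot.
#' @export
plot_session_timeline <- function(sessions, estimates = NULL) {
  # unwrap the clock so evening (pre-noon-anchor) hours sit below midnight
  unwrap <- function(t) {
    tod <- tod_minutes(t) / 60
    ifelse(tod >= 12, tod - 24, tod)
  }
  sess <- tibble::tibble(
    date = night_window_date(sessions$on_time),
    from = unwrap(sessions$on_time),
    to = unwrap(sessions$off_time)
  )
  p <- ggplot2::ggplot(sess)
  if (!is.null(estimates) && nrow(estimates) > 0) {
    est <- tibble::tibble(
      date = estimates$night_date,
      from = unwrap(estimates$start),
      to = unwrap(estimates$end)
    )
    p <- p + ggplot2::geom_segment(
      data = est,
      ggplot2::aes(x = .data$date, xend = .data$date,
                   y = .data$from, yend = .data$to),
      colour = "steelblue", linewidth = 4, alpha = 0.35
    )
  }
  p +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$date, xend = .data$date,
                   y = .data$from, yend = .data$to),
      colour = "black", linewidth = 1.5
    ) +
    ggplot2::scale_y_continuous(
      breaks = seq(-12, 12, 4),
      labels = function(h) sprintf("%02d:00", (h + 24) %% 24)
    ) +
    ggplot2::labs(x = "wake date", y = "local time",
                  title = "Screen sessions and estimated sleep") +
    ggplot2::theme_minimal()
}
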