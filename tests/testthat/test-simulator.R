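test_that("the generator is seeded, deterministic, and produces pairable logs", {
  empty <- sample_user_days(user_profile("student"), n_days = 0, seed = 1)
  expect_equal(nrow(empty$events), 0)
  expect_equal(nrow(empty$truth), 0)

  a <- sample_user_days(user_profile("student"), n_days = 14, seed = 123)
  b <- sample_user_days(user_profile("student"), n_days = 14, seed = 123)
  expect_identical(a, b)

  expect_false(is.unsorted(a$events$timestamp))
  expect_true(all(a$events$kind %in% c("SCREEN_ON", "SCREEN_OFF", "PRESENT")))
  sess <- pair_sessions(a$events)
  expect_true(all(attr(sess, "repairs") == 0))
  expect_true(all(sess$on_time < sess$off_time))
  expect_true(all(sess$on_time[-1] > sess$off_time[-nrow(sess)]))
  expect_equal(nrow(a$truth), 14)
  expect_true(all(a$truth$net_min <= a$truth$gross_min))

  expect_error(sample_user_days(user_profile("student", night_check_prob = 2),
                                n_days = 1, seed = 1),
               "probabilities")
})

test_that("the student preset leaves shorter interaction gaps around sleep than the working-mother preset", {
  realized_gaps <- function(preset, seed) {
    sim <- sample_user_days(user_profile(preset), n_days = 60, seed = seed)
    sess <- pair_sessions(sim$events)
    pre <- post <- numeric(0)
    for (i in seq_len(nrow(sim$truth))) {
      before <- sess$off_time[sess$off_time <= sim$truth$start[i]]
      after <- sess$on_time[sess$on_time >= sim$truth$end[i]]
      pre <- c(pre, as.numeric(difftime(sim$truth$start[i], max(before),
                                        units = "mins")))
      post <- c(post, as.numeric(difftime(min(after), sim$truth$end[i],
                                          units = "mins")))
    }
    c(pre = mean(pre), post = mean(post))
  }
  gs <- realized_gaps("student", 4)
  gm <- realized_gaps("working_mother", 4)
  expect_lt(gs[["pre"]], gm[["pre"]])
  expect_lt(gs[["post"]], gm[["post"]])
})

test_that("ground-truth consolidation applies the 15-minute bridging rules", {
  # interruption under 15 min: one episode, net reduced by the interruption
  seg <- make_segments(
    c("2016-01-04 23:00:00", "2016-01-05 03:00:00", "2016-01-05 03:10:00"),
    c("2016-01-05 03:00:00", "2016-01-05 03:10:00", "2016-01-05 07:00:00"),
    c("sleep", "interruption", "sleep")
  )
  ep <- consolidate_ground_truth(seg)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$start, utc("2016-01-04 23:00:00"))
  expect_equal(ep$end, utc("2016-01-05 07:00:00"))
  expect_equal(ep$net_min, 470)

  # unknown under 15 min: counts fully as sleep
  seg2 <- make_segments(
    c("2016-01-04 23:00:00", "2016-01-05 03:00:00", "2016-01-05 03:12:00"),
    c("2016-01-05 03:00:00", "2016-01-05 03:12:00", "2016-01-05 07:00:00"),
    c("sleep", "unknown", "sleep")
  )
  ep2 <- consolidate_ground_truth(seg2)
  expect_equal(nrow(ep2), 1)
  expect_equal(ep2$net_min, 480)

  # 20-min interruption splits the night; the longest piece is the truth
  seg3 <- make_segments(
    c("2016-01-04 23:00:00", "2016-01-05 02:00:00", "2016-01-05 02:20:00"),
    c("2016-01-05 02:00:00", "2016-01-05 02:20:00", "2016-01-05 07:00:00"),
    c("sleep", "interruption", "sleep")
  )
  ep3 <- consolidate_ground_truth(seg3)
  expect_equal(nrow(ep3), 2)
  night <- nightly_ground_truth(ep3)
  expect_equal(nrow(night), 1)
  expect_equal(night$start, utc("2016-01-05 02:20:00"))
  expect_equal(night$net_min, 280)

  # exactly 15 min is NOT bridged ("less than 15 min" is strict)
  seg4 <- make_segments(
    c("2016-01-04 23:00:00", "2016-01-05 03:00:00", "2016-01-05 03:15:00"),
    c("2016-01-05 03:00:00", "2016-01-05 03:15:00", "2016-01-05 07:00:00"),
    c("sleep", "interruption", "sleep")
  )
  expect_equal(nrow(consolidate_ground_truth(seg4)), 2)

  # overlapping segments are a hard error
  seg5 <- make_segments(
    c("2016-01-04 23:00:00", "2016-01-05 01:00:00"),
    c("2016-01-05 02:00:00", "2016-01-05 07:00:00"),
    c("sleep", "sleep")
  )
  expect_error(consolidate_ground_truth(seg5), "overlap")
})

test_that("consolidated net duration conserves gross minus bridged interruptions", {
  for (seed in 1:10) {
    set.seed(seed + 900)
    # random contiguous night: sleep blocks separated by labelled pauses
    n_seg <- sample(3:9, 1)
    labels <- c("sleep",
                sapply(seq_len(n_seg - 1), function(i) {
                  if (i %% 2 == 1) sample(c("interruption", "unknown"), 1)
                  else "sleep"
                }))
    labels <- labels[seq_len(n_seg)]
    lens <- ifelse(labels == "sleep", runif(n_seg, 30, 240),
                   runif(n_seg, 2, 30))
    bounds <- utc("2016-01-04 22:00:00") + cumsum(c(0, lens)) * 60
    seg <- tibble::tibble(start = bounds[-length(bounds)],
                          end = bounds[-1], label = labels)
    ep <- consolidate_ground_truth(seg)
    # per episode: net = gross - interruptions bridged inside it
    for (j in seq_len(nrow(ep))) {
      inside <- seg$start >= ep$start[j] & seg$end <= ep$end[j]
      bridged_int <- sum(lens[inside & labels == "interruption"])
      expect_equal(ep$net_min[j], ep$gross_min[j] - bridged_int,
                   tolerance = 1e-9)
    }
    # no episode spans a pause of 15 min or more
    long_pause <- seg[seg$label != "sleep" &
                        (as.numeric(difftime(seg$end, seg$start,
                                             units = "mins")) >= 15), ]
    for (j in seq_len(nrow(long_pause))) {
      expect_false(any(ep$start < long_pause$start[j] &
                         ep$end > long_pause$end[j]))
    }
  }
})

test_that("ground truth round-trips through its CSV form", {
  sim <- sample_user_days(user_profile("working_mother"), n_days = 5, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(sim$truth, f)
  back <- read_ground_truth(f)
  expect_equal(back$night_date, sim$truth$night_date)
  expect_equal(back$start, sim$truth$start)
  expect_equal(back$end, sim$truth$end)
  expect_equal(back$net_min, sim$truth$net_min)
})
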