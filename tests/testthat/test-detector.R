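test_that("gap candidates require at least the 4-hour separation, inclusive", {
  # single session: nothing to pair into a gap
  expect_equal(nrow(enumerate_gap_candidates(
    make_sessions("2016-02-01 21:00:00", "2016-02-01 21:05:00"))), 0)

  # 23:00 -> 07:00 overnight gap (480 min)
  s <- make_sessions(c("2016-02-01 22:50:00", "2016-02-02 07:00:00"),
                     c("2016-02-01 23:00:00", "2016-02-02 07:10:00"))
  cand <- enumerate_gap_candidates(s)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start, utc("2016-02-01 23:00:00"))
  expect_equal(cand$end, utc("2016-02-02 07:00:00"))
  expect_equal(cand$gross_min, 480)
  expect_equal(cand$night_date, as.Date("2016-02-02"))

  # exactly 240 min still qualifies ("at least 4 hours")
  s240 <- make_sessions(c("2016-02-01 22:50:00", "2016-02-02 03:00:00"),
                        c("2016-02-01 23:00:00", "2016-02-02 03:10:00"))
  expect_equal(nrow(enumerate_gap_candidates(s240)), 1)
  # one minute under does not
  s239 <- make_sessions(c("2016-02-01 22:50:00", "2016-02-02 02:59:00"),
                        c("2016-02-01 23:00:00", "2016-02-02 03:10:00"))
  expect_equal(nrow(enumerate_gap_candidates(s239)), 0)
})

test_that("candidate enumeration matches the brute-force consecutive-gap filter", {
  for (seed in 1:20) {
    s <- random_sessions(50, seed)
    got <- enumerate_gap_candidates(s)
    want <- brute_force_candidates(s)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("bedtime refinement absorbs a mid-night phone check", {
  # quiet night: nothing to refine
  s <- make_sessions(c("2016-02-01 23:00:00", "2016-02-02 07:30:00"),
                     c("2016-02-01 23:10:00", "2016-02-02 07:40:00"))
  cand <- enumerate_gap_candidates(s)
  ref <- refine_bedtime(cand, s)
  expect_equal(ref$start, cand$start)
  expect_equal(nrow(ref$breaks[[1]]), 0)

  # 23:10 bedtime, 03:00-03:04 check, 07:30 wake: start walks back,
  # check becomes a break, net = 500 - 4 = 496
  s2 <- make_sessions(
    c("2016-02-01 23:00:00", "2016-02-02 03:00:00", "2016-02-02 07:30:00"),
    c("2016-02-01 23:10:00", "2016-02-02 03:04:00", "2016-02-02 07:40:00")
  )
  cand2 <- enumerate_gap_candidates(s2)
  expect_equal(cand2$start, utc("2016-02-02 03:04:00"))
  ref2 <- refine_bedtime(cand2, s2)
  expect_equal(ref2$start, utc("2016-02-01 23:10:00"))
  expect_equal(ref2$end, utc("2016-02-02 07:30:00"))
  expect_equal(ref2$breaks[[1]]$break_start, utc("2016-02-02 03:00:00"))
  expect_equal(ref2$breaks[[1]]$break_end, utc("2016-02-02 03:04:00"))
  expect_equal(ref2$net_min, 496)
})

test_that("refinement iterates backwards across several check clusters", {
  # hand-traced backward scan: wake ON 09:45; check clusters 05:30-05:32
  # and 03:00-03:04; true bedtime OFF 23:10. Both clusters are absorbed.
  s <- make_sessions(
    c("2016-02-01 23:00:00", "2016-02-02 03:00:00", "2016-02-02 05:30:00",
      "2016-02-02 09:45:00"),
    c("2016-02-01 23:10:00", "2016-02-02 03:04:00", "2016-02-02 05:32:00",
      "2016-02-02 09:55:00")
  )
  cand <- enumerate_gap_candidates(s)
  expect_equal(cand$start, utc("2016-02-02 05:32:00"))
  ref <- refine_bedtime(cand, s)
  expect_equal(ref$start, utc("2016-02-01 23:10:00"))
  expect_equal(ref$breaks[[1]]$break_start,
               utc(c("2016-02-02 03:00:00", "2016-02-02 05:30:00")))
  expect_equal(ref$breaks[[1]]$break_end,
               utc(c("2016-02-02 03:04:00", "2016-02-02 05:32:00")))
  # gross 23:10 -> 09:45 = 635; net = 635 - 4 - 2 = 629
  expect_equal(ref$gross_min, 635)
  expect_equal(ref$net_min, 629)
})

test_that("the lookback refuses checks too close to bedtime or outside the night", {
  # previous OFF only 90 min before the check: under the 2-h lookback
  s <- make_sessions(
    c("2016-02-02 01:20:00", "2016-02-02 03:00:00", "2016-02-02 07:30:00"),
    c("2016-02-02 01:30:00", "2016-02-02 03:04:00", "2016-02-02 07:40:00")
  )
  ref <- refine_bedtime(enumerate_gap_candidates(s), s)
  expect_equal(ref$start, utc("2016-02-02 03:04:00"))
  expect_equal(nrow(ref$breaks[[1]]), 0)

  # previous OFF before the noon anchor: a different analysis window
  s2 <- make_sessions(
    c("2016-02-01 10:00:00", "2016-02-02 03:00:00", "2016-02-02 07:30:00"),
    c("2016-02-01 10:30:00", "2016-02-02 03:04:00", "2016-02-02 07:40:00")
  )
  cand2 <- enumerate_gap_candidates(s2) # both gaps qualify
  ref2 <- refine_bedtime(cand2, s2)
  later <- ref2[ref2$end == utc("2016-02-02 07:30:00"), ]
  expect_equal(later$start, utc("2016-02-02 03:04:00"))
})

test_that("refinement never shortens the gross span and never moves the end", {
  for (seed in 1:10) {
    s <- random_sessions(60, seed + 100)
    cand <- enumerate_gap_candidates(s)
    ref <- refine_bedtime(cand, s)
    expect_equal(ref$end, cand$end)
    expect_true(all(ref$start <= cand$start))
    expect_true(all(ref$gross_min >= cand$gross_min))
    brk <- vapply(ref$breaks, function(b) {
      if (nrow(b) == 0) 0 else
        sum(as.numeric(difftime(b$break_end, b$break_start, units = "mins")))
    }, numeric(1))
    expect_equal(ref$net_min, ref$gross_min - brk)
    expect_true(all(ref$net_min > 0))
    # determinism
    expect_identical(refine_bedtime(cand, s), ref)
  }
})

test_that("detect_nights covers every simulated night and keeps daytime gaps as candidates", {
  expect_equal(nrow(detect_nights(make_sessions(character(), character()))), 0)

  # three idealized nights: each window's candidates contain the truth
  sim <- sample_user_days(zero_gap_profile(), n_days = 3, seed = 11)
  sess <- pair_sessions(sim$events)
  cands <- detect_nights(sess)
  for (i in seq_len(nrow(sim$truth))) {
    nd <- sim$truth$night_date[i]
    sub <- cands[cands$night_date == nd, ]
    expect_gte(nrow(sub), 1)
    expect_true(any(sub$start <= sim$truth$start[i] &
                      sub$end >= sim$truth$end[i]))
  }

  # a 6-h daytime no-usage block surfaces alongside the night gap;
  # ranking them is the scorer's job
  s <- make_sessions(
    c("2016-02-01 12:00:00", "2016-02-01 18:30:00", "2016-02-02 07:00:00"),
    c("2016-02-01 12:30:00", "2016-02-01 23:00:00", "2016-02-02 07:10:00")
  )
  cand <- detect_nights(s)
  expect_equal(nrow(cand), 2)
  expect_setequal(format(cand$start, "%H:%M"), c("12:30", "23:00"))
})
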