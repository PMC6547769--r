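# sleepscreen

Passive sleep estimation from smartphone screen-interaction logs.

Many people's last act of the day is putting the phone down, and their
first is picking it up. `sleepscreen` exploits that: given nothing but a
log of `SCREEN_ON` / `SCREEN_OFF` / `PRESENT` events, it estimates each
night's sleep start, end, and duration. It is aimed at digital-phenotyping
and mobile-health researchers who want a cheap, privacy-preserving,
device-free sleep signal — and the validation machinery to know when to
trust it.

## The method

**Stage 1 — candidate episodes.** Events are paired into interaction
sessions (ON→OFF, with `PRESENT` marking an unlock). Every gap between
consecutive sessions of at least 4 h is a candidate sleep episode
`[OFF, next ON]`. A candidate's bedtime is walked backwards across brief
mid-night phone checks: if the OFF that starts it closes a short
interaction cluster (events within 5 min of one another) and another OFF
exists at least 2 h earlier that night, the start moves back and the
check is recorded as an in-sleep break. Both gross and break-corrected
(net) durations are kept.

**Stage 2 — likelihood scoring.** Within each noon-to-noon window every
candidate gets three scores, each `exp(-d/τ)` with `τ = 120` min:

* `s_bed` — circular distance of the start's wall-clock time from the
  22:00 habitual-bedtime anchor,
* `s_wake` — circular distance of the end from the user's habitual wake
  time (weekday/weekend estimated separately from the whole log, by
  circular median, bootstrapped from the detector's own output),
* `s_dur` — `|net − 480|`, 480 min being the midpoint of the recommended
  7–9 h (420–540 min) adult sleep band.

The product of the three is the candidate's likelihood; the argmax per
window is the night's estimate.

The package also ships a seeded behavioural simulator (paired event logs
+ actigraphy-style ground truth, with the reference device's
interruption/unknown consolidation rules: pauses `< 15` min are bridged,
longer ones split the night) and an evaluation layer (absolute error
summaries stratified by weekday/weekend, a paired one-tailed *t* test on
durations, and sleep-deprivation classification against the 420/540-min
lines).

## Worked example

```r
library(sleepscreen)

sim  <- sample_user_days(user_profile("student"), n_days = 30, seed = 1)
sess <- pair_sessions(sim$events)
est  <- estimate_sleep(sess)
est[1:3, c("night_date", "start", "end", "net_min", "likelihood")]
#> # A tibble: 3 × 5
#>   night_date start               end                 net_min likelihood
#>   <date>     <dttm>              <dttm>                <dbl>      <dbl>
#> 1 2016-01-04 2016-01-03 22:41:49 2016-01-04 07:10:06    508.      0.528
#> 2 2016-01-05 2016-01-04 23:24:11 2016-01-05 08:13:36    529.      0.183
#> 3 2016-01-06 2016-01-05 23:21:26 2016-01-06 07:02:53    461.      0.432

ev <- evaluate_sleep(est, sim$truth)
ev
#> Sleep evaluation over 30 matched nights (0 est / 0 truth unmatched)
#>   dur_err_min     mean   32.7 (SD  31.3)
#>   dur_err_pct     mean    7.1 (SD   6.9)
#>   start_diff_min  mean   21.0 (SD  28.7)
#>   end_diff_min    mean   14.2 (SD  27.2)
#>   paired one-tailed t: t = 0.130, p = 0.449 -> adequate
#>   mean duration: estimate 476 min (adequate), truth 475 min (adequate)
```

Reading the output: over 30 simulated high-engagement nights the
estimated duration is off by 33 min (7.1% of the true duration) on an
average night, bedtime by 21 min and wake by 14 min; the paired
one-tailed *t* test finds no significant difference between estimated
and reference durations (p = .45, "adequate"); and both the estimated
and true mean durations (476 / 475 min) fall inside the recommended
7–9 h band. `tidy(ev)` returns the weekday/weekend-stratified summary
table, `glance(ev)` a one-row overview, and `ggplot2::autoplot(ev)`
plots nightly durations against the 420/540-min lines.

A command-line front end over the same functions lives in
`inst/scripts/sleepscreen.R`
(`simulate --profile student --days 150 --seed 42 --out dir/`,
`detect --events log.csv --out estimates.csv`,
`evaluate --estimates estimates.csv --truth truth.csv --report report.json`).

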