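---
title: "Estimating nightly sleep from smartphone screen events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating nightly sleep from smartphone screen events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepscreen)
library(dplyr)
```

## The problem

A smartphone logs three screen events: `SCREEN_ON` (the user presses the
power button), `PRESENT` (the phone is unlocked), and `SCREEN_OFF`. For
most people the longest daily stretch without any of these events is the
night's sleep. `sleepscreen` turns that observation into a nightly
estimate of sleep start, end, and duration using nothing but the event
log — no microphone, light sensor, or wearable — and provides the
machinery to validate such estimates against actigraphy-style ground
truth.

The estimator is deliberately simple and fully inspectable. It has two
stages.

## Stage 1: candidate episodes

Raw events are paired into interaction *sessions* (one consecutive
ON→OFF pair; an intervening `PRESENT` marks the session as unlocked).
Malformed subsequences are repaired rather than rejected — a repeated ON
keeps the later one, orphan OFFs and trailing ONs are dropped — and the
repairs are counted so data-quality problems stay visible.

Every gap between consecutive sessions of at least `min_gap` = 240 min
("at least 4 hours", inclusive) becomes a *candidate episode* running
from the earlier session's OFF to the later session's ON. The scan is
deliberately permissive: a long afternoon away from the phone produces a
candidate too, and stage 2 is responsible for ranking it below the true
night.

Candidates are assigned to noon-to-noon *analysis windows* labelled by
their wake date. Noon was chosen as the anchor because it is maximally
distant from typical overnight sleep, so a window boundary almost never
cuts through a night.

**Bedtime refinement.** The OFF that starts a candidate may close a
brief mid-night phone check rather than the true bedtime. For each
candidate the detector walks backwards: if the session ending at the
current start belongs to a short interaction cluster (sessions chained
by event gaps under `cluster_radius` = 5 min, or a lone session shorter
than 5 min) and an earlier OFF lies at least `lookback_min` = 120 min
before that cluster within the same window, the start moves back to that
OFF and the cluster is recorded as an in-sleep *break*. The rule fires
repeatedly, so several checks can be absorbed; both the gross span and
the net duration (gross minus breaks) are kept, since reference devices
also report interruption-corrected durations.

**Keeping the unrefined sibling.** The lookback rule cannot distinguish
a brief 03:00 phone check from a genuinely brief last interaction of the
evening — both are short sessions with a long-quiet stretch before them.
Applied blindly, the rule drags bedtime back by hours for users with
sparse evening usage. `detect_nights()` therefore keeps the unrefined
original as a separate candidate whenever refinement moved a start and
lets the likelihood arbitrate: a real night check scores far better
refined (the walked-back bedtime lands near the habitual bedtime and the
duration near the recommended band), while a mis-walked bedtime loses to
its original. This preserves the refinement exactly where it helps and
neutralises it where it would hurt.

The thresholds are inclusive (≥) following their "at least" phrasing,
and `min_gap > lookback_min > cluster_radius` is enforced at
construction.

## Stage 2: likelihood scoring

Each candidate receives three unit-interval scores, each an exponential
decay $e^{-d/\tau}$ in a distance $d$:

* **bedtime score** — $d$ is the circular (midnight-wrapping) distance
  in minutes between the candidate's start wall-clock time and the
  assumed habitual bedtime anchor, 22:00;
* **wake score** — $d$ is the circular distance between the end
  wall-clock time and the user's *habitual wake time*, weekday and
  weekend (Saturday/Sunday wake date) estimated separately;
* **duration score** — $d = |\text{net duration} - 480|$ min, 480 being
  the midpoint of the recommended 420–540 min (7–9 h) adult sleep band.

The likelihood is the product of the three, treating them as independent
penalty factors; on the log scale the combination is an additive
penalty. Exponential decay was chosen because it is smooth, strictly
monotone, bounded in $(0, 1]$, and parameterised by a single
interpretable scale. All three scales default to $\tau = 120$ min — the
same order as the algorithm's own two-hour lookback constant — and are
configurable in `scorer_config()`. Within each analysis window the
candidate with the highest likelihood is the night's estimate; ties
break towards larger net duration, then earlier start. Windows with no
candidate yield no estimate rather than a guess.

**Habitual wake bootstrapping.** The wake anchor must itself come from
the log. The first pass seeds the profile with, per window, the end of
the longest refined candidate; circular medians of these (weekday and
weekend separately, with a pooled fallback and an 08:00 default for
empty logs) give a provisional profile; episodes are selected; and the
profile is re-estimated once from the selected ends before a final
selection pass. On regular sleepers the second pass is a fixpoint — the
test suite asserts it changes no selection — so further iteration is not
performed. The circular median is used instead of the circular mean
because episode ends are occasionally wild (a truncated night ending at
03:00) and the median ignores them.

## Timezones and numerical conventions

Timestamps are stored timezone-aware and compared on the absolute line;
every time-of-day quantity (the 22:00 anchor, noon windows, habitual
wake times) uses local wall-clock time, so daylight-saving transitions
shift window boundaries with the clock rather than with UTC offsets.
Circular time-of-day distance is `min(|a-b| mod 1440, 1440 - |a-b| mod
1440)`. The circular median unwraps observations around each candidate
rotation point and takes the rotation minimising total absolute
deviation, breaking exact cost ties towards the earlier observation;
`{23:50, 00:10}` gives 00:00, never 12:00. Degenerate inputs are defined
explicitly: empty logs give empty (zero-row) results at every stage, a
session stream with fewer than two sessions yields no candidates, and a
perfect-agreement paired t test returns $t = 0$, $p = 0.5$ (the
zero-variance limit) instead of an error.

## The simulator

`sample_user_days()` generates the paired (event log, ground truth) data
the estimator assumes, night by night: a truncated-normal (±3 SD)
bedtime and day-type-aware wake time; a final evening session ending an
exponential `pre_sleep_gap` before sleep onset; a first morning session
starting an exponential `post_wake_gap` after waking; Poisson daytime
sessions with lognormal lengths; an optional 1–5 min night-check session
placed uniformly inside the night (1-h margins from the edges); and, on
the ground-truth side, occasional interruption and unknown segments.
Everything is integer-seeded and rounded to whole seconds, so the same
seed reproduces output bit for bit across platforms.

Ground truth is consolidated with the reference-device rules: an
interruption shorter than 15 min between two sleeps keeps one episode
with the interruption subtracted from net duration; an unknown segment
shorter than 15 min counts fully as sleep; 15 min or longer (strictly
"less than 15" bridges) splits the night, and the longest piece is the
night's truth.

Two presets encode the cohort contrast the estimator is sensitive to:

| parameter | student | working_mother |
|---|---|---|
| bedtime | 23:30 ± 45 min | 23:00 ± 60 min |
| wake, weekday | 07:00 ± 30 min | 06:30 ± 30 min |
| wake, weekend | 08:30 ± 45 min | 07:30 ± 60 min |
| pre-sleep gap (exp. mean) | 10 min | 45 min |
| post-wake gap (exp. mean) | 10 min | 60 min |
| night-check probability | 0.3 | 0.15 |
| daytime sessions / h | 2 | 0.8 |

The remaining free parameters were fixed once at values typical of
actigraphy and phone-usage data and are not calibration dials: session
lengths lognormal with median 2 min (sdlog 0.8); interruptions with
per-night probability 0.25 and exponential mean 5 min (brief bathroom
trips; rarely ≥15 min, in which case the night genuinely splits);
unknown segments with probability 0.1 and mean 5 min; 80% of sessions
unlocked.

**What the simulator does not emulate.** Sleep is unimodal per night (no
shift work, no naps by default), gaps around sleep are independent
exponentials, and the ground-truth interruptions are sampled
independently of the phone checks (a real smartwatch would usually flag
the check itself as wake). Passing tests on this generator show the
pipeline's logic is correct under its stated assumptions — not that the
printed accuracies transfer to any particular real cohort.

## Evaluation

`match_nights()` inner-joins estimates and truth on wake date and
reports absolute errors: duration error in minutes and as a percentage
of the ground-truth duration, and start/end differences in minutes.
`aggregate_errors()` gives mean and sample SD (n−1) for all days,
weekdays, and weekends; count-weighted stratum means recover the pooled
mean exactly, which the tests assert. `paired_one_tailed_t()` tests the
per-night duration differences with the tail chosen by the sign of the
observed mean difference, calling the estimator *adequate* when
$p > .05$ and otherwise labelling the direction of the bias.
`classify_deprivation()` compares a mean duration against the 420/540
min band with boundaries inclusive into *adequate*.

## Problem sizes

The cohort-level checks simulate 150 days per replicate for the
high-engagement preset and 45 for the low-engagement one (matching the
two cohorts' average participation lengths), five replicates each —
roughly 750 and 225 nights — which keeps the full run under half a
minute while leaving Monte-Carlo noise on the mean relative error well
under a percentage point. The property-style oracle tests use 100 random
instances each.

## Known limitations

* The estimator brackets sleep by the last and first interaction, so its
  duration estimate exceeds the truth by roughly the sum of the
  pre-sleep and post-wake gaps. For low-engagement users those gaps —
  not the algorithm's internals — dominate the error, and the bias is
  systematically positive (overestimation), which the paired t test
  makes visible.
* Refinement only ever extends bedtimes backward; it cannot extend wake
  times forward. A phone check within 4 h of waking therefore truncates
  the detected night at the check, and a check within 2 h of falling
  asleep cannot be absorbed at all (the lookback finds no OFF two hours
  earlier that night).
* The 22:00 bedtime anchor presumes conventional daylight-hours
  schedules; shift workers would be systematically penalised. The anchor
  and all scales are exposed in `scorer_config()`, but no per-user
  learning of them is attempted.
* Nights the user never touches the phone on either side produce no
  candidate and are reported as "no estimate" rather than imputed.
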