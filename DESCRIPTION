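Package: sleepscreen
Title: Sleep Estimation from Smartphone Screen-Interaction Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates nightly sleep start, end, and duration from passively
    logged smartphone screen events (SCREEN_ON, SCREEN_OFF, PRESENT) alone.
    Candidate sleep episodes are enumerated as long no-interaction gaps
    between screen sessions, refined across brief mid-night phone checks,
    and ranked by a three-factor likelihood (proximity to a habitual
    bedtime, to the user's habitual wake time, and to a recommended sleep
    duration). Includes a behavioural simulator that generates paired
    screen-event logs and actigraphy-style ground truth, consolidation
    rules for interrupted and unknown sleep segments, and an evaluation
    layer with absolute-error summaries, paired one-tailed t tests, and
    sleep-deprivation classification against the recommended 7-9 h band.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    hms,
    jsonlite,
    lubridate,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
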