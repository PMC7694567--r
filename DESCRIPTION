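Package: exoresist
Title: Simulation and Analysis of Wearable Adaptive Ankle-Resistance Gait Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying wearable adaptive ankle-resistance training for
    gait rehabilitation in cerebral palsy. Implements the proportional
    resistance controller (stance detection from plantar forefoot force,
    peak-ankle-moment calibration, instantaneous torque command), the
    session-to-session training-progression rules gated by engagement and
    perceived soreness, a metabolic pipeline (Kendall tau-b steady-state
    detection on breath-by-breath gas exchange, Brockway energy conversion,
    net cost of transport), and the paired pre/post statistical battery
    (IQR outlier screening, Lilliefors normality, paired t-tests with
    Holm-Bonferroni correction, Cohen's d, percent-change summaries).
    Seeded synthetic generators for gait trials, breath series, and whole
    cohorts allow the full pipeline to run end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    nortest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
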