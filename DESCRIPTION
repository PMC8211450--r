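Package: shuttlebox
Title: Fiber Photometry and Behavior Quantification for Shuttle-Box Learned Helplessness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-aligned quantification of ventral-tegmental dopamine fiber photometry
    signals together with escape/failure behavior in shuttle-box learned-helplessness
    experiments. Provides windowed median dF/F normalization, block-mean downsampling,
    event alignment, signed peak/AUC/latency transient metrics with amplitude-based
    omission rules, an escape-versus-failure trace-distance statistic, three-state
    behavioral transition models with a Frobenius similarity score, learning curves,
    run-length statistics, Gaussian fits to cohort failure distributions, motion-bout
    detection from body-center tracking, Welch power spectral density summaries for
    spontaneous calcium traces, Pearson cohort correlations, and a synthetic cohort
    generator with known ground truth for end-to-end parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
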