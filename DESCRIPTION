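Package: awsproc
Title: Cleaning and Evaluation of Automated Weighing System Cattle Weight Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Converts noisy automated weighing system (AWS) time series of
    cattle body weight into reliable per-animal estimates via a three-stage
    pipeline: statistical outlier removal (Tukey's fences or a standard
    deviation rule) with per-animal daily averaging, representative-weight
    estimation for the mid-date of each measurement window (mean, median or
    linear-regression prediction), and a physiology-bounded post-processing
    filter built from target average daily gain. Includes an evaluation
    framework (RMSE, 5 and 10 percent error-margin ratios, and a
    multiple-comparison test battery with Dunnett, Tukey HSD, Kruskal-Wallis
    and Dunn tests) and a synthetic herd simulator with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    multcomp,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
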