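Package: evokedmua
Title: Evoked Multi-Unit Activity and Behavioral Episode Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for stimulus-evoked extracellular multi-unit
    activity (MUA) in thalamic slice recordings and for rodent behavioral
    episode statistics. Detects spikes by first-derivative thresholding
    relative to baseline RMS with waveform-duration exclusion, builds
    peri-stimulus time histograms with early (0-1.5 s) and delayed (1.5-3 s)
    response windows, and compares groups with Kolmogorov-Smirnov (Bonferroni)
    and Kruskal-Wallis (Dunn) tests. Quantifies grooming bouts with
    exponential-plateau fits to cumulative duration-probability curves and
    extra-sum-of-squares F tests, and three-chamber sociability preference
    ratios. Includes a seeded synthetic-data generator for recordings and
    behavioral tables with ground truth for validation.
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
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
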