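Package: redecide
Title: Decision-Redecision Metacognition: Task Generation, Behavioral
    Metrics, and First-Level fMRI Design Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying metacognition in decision-redecision
    paradigms. Generates graded 4x4 Sudoku problems and coherence-laddered
    random-dot-motion stimuli, runs the two-consecutive adaptive staircase
    that holds initial-decision accuracy near 50%, and simulates a
    signal-detection observer with a second-order confidence readout that
    produces realistic trial tables (choices, correctness, 1-4 confidence,
    response times for both decision phases). Computes the behavioral
    metacognition statistics used with such data (type-2 ROC uncertainty
    sensitivity, uncertainty bias, accuracy change, Goodman-Kruskal gamma,
    Cronbach alpha, Fisher-z comparisons) and reconstructs the first-level
    fMRI design machinery (canonical double-gamma HRF, demeaned serially
    orthogonalized parametric modulators, variance inflation factors,
    psycho-physiological interaction designs, trial-wise beta-series
    connectivity, oversampled ROI epoching), exercised end to end on
    synthetic ROI BOLD series.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
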