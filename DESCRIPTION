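Package: grndyn
Title: Dynamic Perturbation Analysis of Transcription-Factor-Driven Gene
    Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring gene regulatory network topology from
    paired transcription-factor binding and mRNA expression time courses
    around a nutrient perturbation. Provides exponential decay-rate fitting
    and synthesis-rate deconvolution on nonuniform time grids, a
    two-parameter promoter-occupancy-driven ordinary differential equation
    model of transcription with closed-form steady-state calibration,
    k-means clustering of expression profiles (Pearson correlation
    distance) and of model residuals (Euclidean distance), hypergeometric
    functional-category enrichment, a one-sided Welch fold-change test,
    efficiency-corrected qPCR relative quantification, and a logic
    approximation of the coherent feed-forward loop with bounded
    least-squares fitting of its degradation constants. A synthetic-data
    generator emulates the two-strain (parent / regulator-knockout)
    perturbation panel the analysis assumes, so the whole pipeline is
    testable without external data.
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
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
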