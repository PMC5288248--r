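Package: tssbias
Title: Prevalence Dependence of the True Skill Statistic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the true skill statistic (TSS, also known
    as the Youden index or Peirce skill score) reacts to species prevalence
    when evaluating presence-absence prediction models. Provides confusion
    matrix and threshold-based discrimination metrics (TSS, sensitivity,
    specificity, Cohen's kappa), closed-form expected TSS under observation
    error scenarios (missed presences, fallacious absences, fallacious
    presences), a synthetic data generator drawing predicted probabilities
    from beta distributions of graded discrimination quality, the
    maximum-TSS-over-cutoffs procedure, and a Monte Carlo experiment
    quantifying the small-sample, U-shaped prevalence dependence that
    data-driven cutoff selection induces in maximum TSS.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
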