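Package: dotmag
Title: Simulation and Analysis of Dynamic Dot-Cloud Magnitude Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for magnitude-estimation psychophysics with dynamic
    dot-cloud stimuli in which trial duration, dot numerosity and cumulative
    dot surface are controlled independently. Provides factorial design
    enumeration and pseudo-randomized schedules, a stimulus simulator with
    linear, fast-slow and slow-fast evidence-accumulation regimes, a Bayesian
    synthetic observer with per-dimension priors, rate-duration coupling and
    primacy weighting, psychometric (logit) fitting with point of subjective
    equality and Weber ratio, central-tendency regression of continuous
    estimates, and correlation statistics (Fisher z differences, partial
    correlations, Bonferroni-masked correlation matrices).
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
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
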