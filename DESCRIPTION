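Package: ripplepac
Title: Sharp-Wave-Ripple Detection and Theta-Gamma Coupling Analysis for Hippocampal LFP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis chain for single-channel hippocampal local field
    potential recordings: Hilbert-envelope detection of sharp-wave ripples
    (SWRs) with duration and incidence metrics, SWR-triggered multitaper
    spectrograms with per-frequency z-scored slow-gamma power, and
    theta-slow-gamma phase-amplitude coupling quantified by an
    entropy-normalized modulation index. Includes a synthetic LFP generator
    with full ground truth (pink-noise background, theta rhythm,
    phase-coupled gamma, injected ripple bursts) so every stage is testable
    without animal data, plus the group-comparison statistics layer
    (Levene, one-way ANOVA with Scheffe post-hoc, Kruskal-Wallis with
    Bonferroni correction) and a reproducible pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
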