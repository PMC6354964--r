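Package: neocoupling
Title: Coupling Analysis for Neonatal Olfactory Bulb-Entorhinal Network Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for developmental two-region electrophysiology:
    detection of discontinuous spindle-shaped oscillatory bursts in the local
    field potential, spike-field phase locking via the pairwise phase
    consistency, volume-conduction-robust field-field coupling via the
    imaginary part of spectral coherence, directed connectivity from
    standardized spike-spike cross-covariance with jitter surrogates, and
    quantification of optogenetic, odor and pharmacological perturbations.
    Includes a synthetic two-region session generator with ground truth for
    validation, circular statistics (Rayleigh, two-sample Kuiper), a chi-square
    test of proportions, and an interquartile-range outlier rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
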