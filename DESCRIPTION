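Package: neurodyn
Title: Hippocampal-Prefrontal LFP Dynamics: Spectra, Coupling, Coherence
    and Recognition-Memory Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for two-region local field potential (LFP)
    studies of hippocampal CA1 and prelimbic medial prefrontal cortex.
    Implements multitaper spectral estimation with 1/f normalization and
    baseline z-scoring, Tort-style phase-amplitude coupling comodulograms
    with region-of-interest quantification, weighted phase-lag index
    coherence, phase slope index directionality with circular-shift
    surrogate nulls, accelerometer mobility metrics, novel-object
    recognition discrimination indices, histology co-expression
    aggregation, and the repeated-measures ANOVA designs used to compare
    baseline versus drug epochs across treatment conditions. A synthetic
    session generator with planted 1/f background, band-limited
    oscillations, cross-frequency coupling, lagged inter-regional
    components and condition effects makes every stage testable without
    raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
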