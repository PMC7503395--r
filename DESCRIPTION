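Package: aismature
Title: Patch-Clamp Feature Extraction and Axon Initial Segment Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intrinsic electrophysiology and axon
    initial segment (AIS) morphometry of maturing neurons. Estimates passive
    membrane properties (series resistance, input resistance, capacitance,
    membrane time constant) from voltage-clamp seal tests; extracts rheobase,
    f-I curves, input-output gain and maximal firing frequency from
    current-clamp step protocols; computes action-potential phase-plane
    metrics (threshold at 20 V/s, dV/dt extrema, half-width, initial-segment
    and somatodendritic rising-phase components, after-potential
    classification); measures AIS length and diameter from fluorescence
    intensity line profiles with a relative-intensity threshold; derives AIS
    capacitance and estimated AIS inward current; and compares age groups
    with a normality-gated ANOVA/Kruskal-Wallis pipeline with Bonferroni or
    Dunn post hoc tests. Includes synthetic-data generators (RC seal-test
    transients, leaky integrate-and-fire step responses, a two-compartment
    conductance-based neuron model, and blurred plateau intensity profiles)
    with embedded ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    signal,
    deSolve,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    tiff
Config/testthat/edition: 3
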