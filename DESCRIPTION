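Package: hypnodyn
Title: Sleep-Wake State Dynamics and Cortical EEG Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of rodent sleep architecture and cortical
    dynamics from scored hypnograms and two-channel EEG. Implements bout and
    latency statistics, a Markov transition model of vigilance-state dynamics
    with a fragmentation index, multitaper spectral power and Fisher-z
    coherence, band-specific normalized symbolic transfer entropy for directed
    frontal-occipital connectivity, and Lempel-Ziv complexity corrected by
    phase-randomized surrogates, together with the paired statistical battery
    used for within-subject treatment comparisons and a synthetic-data
    generator with known ground truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    survival,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
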