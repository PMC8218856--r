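Package: erppipe
Title: Simulation and Analysis of Event-Related EEG Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing multi-subject event-related
    EEG studies with a four-condition face-detection design. Generates
    epoched EEG (evoked P3 and late-positive-potential components, spatially
    correlated 1/f background, alpha rhythm, threshold-violating artefacts)
    and reaction times with planted condition effects; preprocesses epochs
    (earlobe re-referencing, zero-phase Butterworth filtering, baseline
    correction, threshold-based artefact rejection); extracts pooled
    window-mean component amplitudes; runs normality-gated repeated-measures
    ANOVA / Friedman statistics with Wilcoxon post hocs and JZS Bayes
    factors; performs spatio-temporal cluster-based permutation tests with
    threshold-free cluster enhancement (TFCE); and carries out time-resolved
    representational similarity analysis via split-half condition distance
    matrices regressed on z-scored model templates with cluster-based group
    inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
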