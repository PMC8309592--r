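Package: vdepeeg
Title: Visual Design Elements and Principles in EEG: Band-Power Statistics
    and Single-Second Convolutional Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how visual design elements and principles
    (VDEPs) of video content -- colour (cold/warm), balance
    (asymmetrical/symmetrical), light (bright/dark) and movement (fast/slow)
    -- relate to viewers' electroencephalography. Provides a synthetic
    generator of DEAP-shaped multi-participant EEG recordings with
    controllable per-band class effects and simulated expert annotators; a
    two-expert annotation resolver with interval construction and class
    balancing; an extraction-transformation process that turns tagged video
    seconds into labelled one-second 128 x 32 epochs; FFT band filtering and
    mean band power in the delta, theta, alpha, beta and gamma bands;
    Lilliefors-corrected normality screening and Mann-Whitney U comparisons
    of band power between VDEP classes; a compact two-dimensional
    convolutional network that decodes the VDEP class of a single epoch,
    evaluated by Monte-Carlo 90/10 cross-validation with AUC, accuracy and
    PR-AUC; and a pipeline orchestrator running the whole analysis from one
    configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    jsonlite,
    yaml,
    nortest,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
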