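Package: retronmr
Title: Low-Field NMR Relaxometry Analysis of Starch Retrogradation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the molecular analysis of starch retrogradation by
    low-field time-domain 1H NMR relaxometry. Simulates inversion-recovery and
    CPMG (Carr-Purcell-Meiboom-Gill) decay curves with known ground truth, fits
    spin-lattice (T1) and mono- or multi-exponential spin-spin (T2) relaxation
    times by Marquardt nonlinear least squares with information-criterion
    selection of the number of proton pools ("spin grouping"), inverts the BPP
    (Bloembergen-Purcell-Pound) dipolar relaxation equations to recover mean
    rotational correlation times of water from (T1, T2) pairs, and assembles
    storage-time series with percent-change trends, one-way ANOVA and Tukey HSD
    homogeneous-subset letters in the layout conventional for starch-paste
    storage studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
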