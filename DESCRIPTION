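Package: rtnf
Title: Simulation and Analysis of Real-Time fMRI Neurofeedback Paradigms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing real-time fMRI neurofeedback
    (NF) experiments that target a single region of interest. Implements the
    parallel and serial block paradigms, the online percent-signal-change
    feedback signal with thermometer quantization, offline region-of-interest
    GLM estimation of per-run training efficiency and most-efficient-run
    selection, group-level behavioral comparisons (Welch t, Mann-Whitney,
    Shapiro-Wilk), a desk-scale whole-brain pipeline (least-squares-all
    first-level GLM, one-sample group maps, sign-flip permutation cluster
    thresholding, conjunction and disjunction), and functional labeling of
    statistic maps by spatial correlation with template network maps. A
    synthetic-data module generates ROI time courses, small 4D volumes,
    motion traces, template sets and multi-subject groups with known ground
    truth.
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
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
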