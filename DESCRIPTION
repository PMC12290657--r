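Package: lobulae
Title: Intrinsic-Coordinate Gradient Analysis of Cerebellar fMRI
Version: 0.1.0
Authors@R:
    person("lobulae", "developers", email = "lobulae@example.org",
           role = c("aut", "cre"))
Description: Rule-based construction of per-lobule boundary masks from a
    cerebellar lobule label map, a white-matter probability map and a
    cerebellum mask; iso-distance gradient step maps (default 7 steps) in
    three intrinsic anatomical directions (fissure depth, mediolateral,
    posterior-anterior); first-level block-design GLM with contrast z-maps
    and fixed-effects combination across runs; step-profile statistics
    (repeated-measures ANOVA with Mauchly's sphericity test and
    Greenhouse-Geisser correction, Holm post-hoc tests, paired t-tests);
    and quadrant centre-of-gravity shift analysis.  Ships a synthetic
    folded-cortex phantom with planted block-design BOLD activation so the
    whole pipeline is testable by parameter recovery without any data
    download.  Minimal NIfTI-1 input/output is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
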