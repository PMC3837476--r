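Package: megpriming
Title: Millisecond-Wise Mixed-Model and Cluster-Permutation Analysis of
    Masked-Priming MEG Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for masked-priming lexical decision
    experiments with MEG source-estimate time courses. Provides a synthetic-data
    generator emulating a 4-condition (identity, regular, irregular,
    pseudo-irregular) past-tense priming design with crossed subject and item
    random effects; trial- and subject-level preprocessing (baseline
    correction, zero-phase low-pass filtering, amplitude-threshold trial
    rejection, reaction-time trimming and subject exclusion); millisecond-wise
    linear mixed-effects modelling with crossed random intercepts; temporal
    cluster-mass (sum-of-t) statistics with max-statistic permutation
    correction in t and square-root-chi-squared variants; functional-ROI
    localization of priming effects on a source grid; and covariate
    orthogonalization and interaction analysis for gradient morphophonological
    support scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
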