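Package: tautraj
Title: Trajectory Analysis of Tau Accumulation in Single-Neuron Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-neuron and mini-pool proteomic
    cohorts ordered along an axis of tau accumulation. Provides Perseus-style
    preprocessing (contaminant removal, group-wise detection filtering,
    cell-quality filtering, downshifted-normal imputation of
    missing-not-at-random values), sample ordering by diffusion-map pseudotime
    or tau-abundance proxy, a Pearson correlation screen with
    Benjamini-Hochberg control, Ward clustering of significant proteins,
    composite proteostasis pathway scores (proteasome, 20S, 19S, lysosomal
    acidification), phospho-site occupancy excess estimation via a
    random-intercept mixed model, and temporal ordering of molecular responses
    through continuous piecewise-linear regression with 0-2 breakpoints and
    BIC model selection. A synthetic-cohort generator with ground-truth tables
    supports validation and power analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    mclust,
    withr
Config/testthat/edition: 3
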