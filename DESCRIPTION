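Package: imgtx
Title: Imaging Transcriptomics of Spatial Gene Expression and Meta-Analytic Brain Activation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links spatial gene-expression atlases (donor sampling sites with
    MNI coordinates and probe-level expression) to coordinate-based
    meta-analytic brain-activation maps built from study activation foci.
    Implements term-based activation-likelihood maps, per-donor
    expression-activation correlations aggregated with an approximate
    random-effects t-test, a study-resampling null for inter-donor
    repeatability, bidirectional stepwise two-gene regression with an
    interaction term, gene-set screening with Benjamini-Hochberg FDR,
    sense-of-direction questionnaire scoring with a sex-adjusted partial
    correlation, and a synthetic-data generator with planted effect sizes
    for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
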