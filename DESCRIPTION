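Package: regcap
Title: Multilayer Regulatory Capacity Models for Subtype-Specific Gene Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a thermodynamic model of transcription regulation in which
    each transcription factor acts on each target gene through a single
    saturable regulatory-capacity parameter (F value), estimated per molecular
    subtype by penalized nonlinear regression. On top of the fitted models the
    package assembles candidate regulatory backbones from binding-score and
    tissue-network inputs, calls subtype-specific (repurposed) regulatory
    edges by label permutation, mines TF-TF co-regulation with robust
    consensus correlation, simulates transcription-factor knockdowns with a
    recursive propagation algorithm protected against feedback loops, scores
    protein signaling activity on signed directed interactomes by Exponential
    Ranking, and learns per-TF elastic-net models that map perturbation-induced
    activity changes to gene-essentiality scores. A synthetic-cohort generator
    reproduces the statistical structure the pipeline assumes so every stage
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    glmnet,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
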