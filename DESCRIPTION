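Package: recapitome
Title: Cross-Species Transcriptome Recapitulation Scoring by Vote-Counting
    Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Aggregates differential-expression signals across multiple
    case/control expression studies by a vote-counting rule, derives
    differentially expressed pathways by hypergeometric over-representation
    against user-supplied GMT gene sets, maps gene identifiers across species
    through an ortholog table, and scores how well model-organism contrasts
    recapitulate a human disease signature at the pathway, biological-category
    and gene-direction level. Includes a negative-binomial multi-study
    simulator with planted signatures so every stage of the pipeline can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
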