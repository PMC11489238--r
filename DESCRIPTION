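Package: toxconcord
Title: In Vitro to In Vivo Concordance Analysis for Targeted Organ-Toxicity Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies targeted qPCR arrays with the delta-delta-Ct method
    (housekeeping normalization, Ct censoring, fold-regulation transform,
    replicate-level significance), summarizes liver and kidney protein-marker
    panels with percentile-bootstrap significance, grades the in vitro
    evidence on an ordinal none/medium/strong/very-strong scale using
    magnitude and overlap-p-value matrices, maps graded endpoints onto
    curated in vivo effect categories for liver and kidney, and scores
    indicative concordance and negative agreement under OR-combination of
    predictors, cell lines and data types. Ships the curated effect
    ontologies, a synthetic-data generator with controllable true
    concordance for end-to-end validation, and plate-reader viability
    normalization with highest-non-cytotoxic concentration selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    boot,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
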