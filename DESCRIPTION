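Package: rxncond
Title: Two-Stage Recommendation of Chemical Reaction Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Recommends reagents, solvents and reaction temperatures for
    organic reactions with a two-stage model: a multi-label candidate
    generation network (focal loss, homoscedastic multi-task weighting)
    proposes plausible reagent and solvent labels from a reaction
    difference fingerprint, candidate combinations are enumerated
    combinatorially and augmented with hard negative samples, and a
    listwise ranking network scores each reaction context by
    yield-derived relevance and predicts a reaction temperature.
    Includes the full preprocessing pipeline for reaction-condition
    tables, example-based multi-label evaluation metrics, top-k
    exact-match protocols, and a synthetic reaction-world generator for
    hermetic benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
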