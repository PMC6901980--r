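Package: toxmod
Title: Injury Module Activation Scoring for Toxicogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Gene-set scoring of toxicant-induced transcriptomic responses.
    Computes per-gene log fold changes and differential-expression calls
    from replicated treatment/control cohorts, signed aggregated fold-change
    (AFC) pathway scores, and absolute aggregated fold-change (AAFC) injury
    module activation scores with random-gene-set permutation nulls,
    z-scores and Fisher combined p-values. Includes cross-condition
    concordance analysis, maximum-score aggregation over exposure
    conditions, risk classification against a target injury module, and a
    synthetic-data generator that plants module activation of known effect
    size and direction for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
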