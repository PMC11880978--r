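Package: axinpool
Title: Bridged Relative Quantification of AXIN1 and AXIN2 Immunoblot Data
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Replicate-aware quantification of immunoblot densitometry and
    reporter assays for Wnt-pathway studies. Implements a three-antibody
    bridging calibration that estimates the endogenous AXIN1:AXIN2 protein
    ratio with antibody affinities cancelling, dilution-series linearity
    checks with saturation flagging, propagation of condition-specific fold
    changes into combined AXIN1+AXIN2 pool compositions (pie-chart data),
    TOP/FOP dual-luciferase normalization, first-order protein-decay
    kinetics under translation inhibition, recruitment-fraction statistics,
    and ground-truth synthetic-data generators for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate:
    'utils.R'
    'quant_core.R'
    'bridging.R'
    'pool_composition.R'
    'assay_models.R'
    'synthetic_data.R'
    'pipeline.R'
    'axinpool-package.R'
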