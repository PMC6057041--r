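Package: icmcda
Title: Multi-Criteria Decision Analysis for Integrated-Care Programme Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-attribute value MCDA toolkit for comparing an integrated-care
    programme against usual care. Provides Triple-Aim criteria catalogs (core and
    programme-type-specific outcome sets), pairwise vector normalization of
    performance scores, weighted-sum overall value scores, two weight-elicitation
    engines (level-overlap-constrained D-efficient discrete choice experiment
    designs with conditional-logit part-worth estimation, and SMARTER swing
    weighting via rank-ordered centroids), deterministic sensitivity analyses,
    Monte-Carlo probabilistic sensitivity analysis, and the Conditional
    Multi-attribute Acceptability Curve (CMAC). Includes a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
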