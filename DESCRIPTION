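Package: whitecca
Title: Canonical Correlation Analysis by Whitening with Signed
    Correlations and Shrinkage Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Canonical correlation analysis (CCA) formulated as a pair of
    uniquely determined whitening transformations. Canonical correlations
    are treated as regression coefficients and may be negative; the sign
    ambiguity of the singular value decomposition is resolved by requiring
    positive diagonals of both rotation matrices. For high-dimensional
    two-table problems (samples much fewer than variables) the joint
    correlation matrix is estimated by analytic shrinkage toward the
    identity, and all matrix square roots are applied through a low-rank
    identity-plus-rank-r representation so that no variable-by-variable
    matrix is ever materialized. Includes the corresponding two-layer
    latent-variable generative model and simulator, a sign-recovery
    simulation experiment, and a command-line workflow for integrating
    two omics data tables with matched samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
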