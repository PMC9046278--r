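Package: ssmcca
Title: Structured Sparse Multiset Canonical Correlation Analysis for
    Multimodal Neuroimaging Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Graph-regularized, L1-sparsified multiset canonical
    correlation analysis under the SUMCOR (sum-of-correlations)
    objective, with projection deflation for higher-order components
    and two-step cross-validated penalty selection.  Includes the
    feature-construction pipeline that renders concurrently recorded
    EEG and fNIRS commensurate for fusion (mu-band power extraction via
    the analytic envelope, power inversion, gamma-shaped hemodynamic
    response convolution, event-locked epoching, trial averaging and
    resampling to a common grid), synthetic-data generators with known
    sparse graph-smooth loadings for validation, permutation
    significance testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
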