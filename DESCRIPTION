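Package: mixqspr
Title: QSPR Modeling of Binary Mixture Properties with Weighted-Mixture Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quantitative structure-property relationship (QSPR)
    modeling for binary mixtures such as deep eutectic solvents (DES).
    Builds molar-fraction-weighted mixture descriptors from per-component
    descriptor tables, performs deterministic mixtures-out and compounds-out
    data splitting driven by (seed, interval) stepping, fits multiple linear
    regression models by sequential forward selection gated by a
    leave-one-out mean-absolute-error reduction policy, and validates them
    with a full battery of internal, leave-chemical-out and external metrics,
    Y-randomization and leverage-based applicability-domain diagnostics.
    Includes intelligent consensus prediction over multiple models,
    non-linear baseline regressors with cross-validated tuning, a synthetic
    data generator with known ground truth, and a frozen published model for
    predicting the surface tension of deep eutectic solvents.
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
    withr,
    caret,
    randomForest,
    e1071,
    nnet,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
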