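Package: sgpath
Title: Lasso, Group Lasso and Sparse-Group Lasso Regularization Paths
    via Proximal Gradient Descent
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits high-dimensional linear models with an unpenalized
    covariate block and a penalized feature block under lasso, group
    lasso, sparse-group lasso and penalty-factor (IPF-lasso)
    regularization.  Full regularization paths are computed by proximal
    gradient descent with backtracking line search over a warm-started
    logarithmic grid of penalty parameters.  Supports positive
    per-feature weights (including minor-allele-frequency based and
    per-modality penalty factors), produces exact-zero coefficient
    estimates, and reports KKT optimality residuals.  Includes a seeded
    generator of grouped, correlated regression problems with known
    sparse-at-group-level truth, hold-out evaluation of fitted paths,
    delimited-text input/output and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    glmnet,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
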