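Package: svrdecon
Title: Immune Cell-Type Deconvolution by Nu-Support Vector Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the relative proportions of immune cell types in bulk
    gene-expression profiles. A cell-type signature matrix is constructed from
    replicated reference profiles by quantile normalization, correlation-based
    outlier screening, black-list filtering of genes expressed in
    non-hematopoietic tissues or cancer cell lines, pairwise Welch tests with
    false-discovery-rate control, and condition-number-driven sizing of the
    top-G union gene list. Mixture samples are then deconvolved by
    linear-kernel nu-support vector regression with model selection over nu,
    negative-coefficient clipping and sum-to-one normalization. Includes
    benchmarking utilities (per-cell-type Pearson correlation and RMSE against
    known compositions), a synthetic-data generator with known ground-truth
    proportions, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    e1071,
    limma,
    jsonlite,
    ape,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
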