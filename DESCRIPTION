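Package: ifser
Title: Effective-Range Filter Feature Selection for Class-Labeled Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Filter feature selection for high-dimensional class-labeled
    numeric matrices, as used for gene-expression classification. Implements
    effective-range based gene selection (ERGS), which scores each feature by
    the overlap of per-class Chebyshev-bound effective ranges, and its
    refinement IFSER, which additionally measures the inclusion (nesting) of
    class ranges and the proportion of samples falling inside overlap and
    inclusion regions. Provides the full scoring pipeline (class statistics,
    effective ranges, area decomposition, sample-proportion scores, feature
    weights and top-k selection), a synthetic-data generator with planted
    informative features, delimited-text input/output, a ranking report
    writer, a leakage-safe leave-one-out cross-validation harness, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    class,
    rpart,
    e1071,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
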