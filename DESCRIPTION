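Package: strucclass
Title: Protein Structural Class Prediction from Integrated Profile,
    Physicochemical and Annotation Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the SCOP-style structural class of a protein (all-alpha,
    all-beta, alpha/beta, alpha+beta) from three integrated feature blocks:
    linear predictive coding (LPC) of sigmoid-normalized PSI-BLAST
    position-specific scoring matrices, PROFEAT-style structural and
    physicochemical sequence descriptors, and binary Gene Ontology annotation
    vectors. Features are ranked by multiclass SVM-RFE (recursive feature
    elimination with a linear-kernel squared-weight criterion, one feature
    removed per iteration), truncated to a top-k set, and classified with a
    one-vs-one RBF-kernel support vector machine tuned by grid search.
    Evaluation uses the jackknife (leave-one-out) test with per-class
    accuracy, Matthews correlation coefficients and macro-averaged
    one-vs-rest ROC curves. A seeded synthetic-data generator emulates the
    full input stack (sequences, PSSMs, GO annotations, class manifests) with
    planted, recoverable class signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
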