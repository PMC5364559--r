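Package: protclass
Title: Protein Descriptor Encoding and Kernel SVM Classification
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Encodes protein sequences into five descriptor families
    (amino acid composition, di-peptide composition, pseudo amino acid
    composition, composition-transition-distribution, and autocorrelation
    over physicochemical amino acid indices), trains binary support
    vector machine classifiers with four kernels via an exact SMO dual
    solver, and evaluates them under balanced-resampling
    cross-validation and leave-one-out protocols with sensitivity,
    specificity, accuracy, precision, Matthews correlation and ROC-AUC
    reporting.  A first-order Markov chain generator produces labeled
    synthetic protein datasets with controllable composition and
    di-peptide structure for end-to-end testing, and a command-line
    interface wires the pieces into encode/train/cv/predict/simulate
    workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    optparse,
    rlang,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
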