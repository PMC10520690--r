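Package: decooc
Title: Cell-Type Deconvolution of Bulk Hi-C Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates cell-type proportions from bulk Hi-C contact maps
    with a convolutional neural network trained on simulated mixtures of
    single-cell or pure cell-line Hi-C profiles. Provides binned contact
    I/O with Knight-Ruiz matrix balancing and observed/expected
    normalisation, a full mixture-simulation framework with known ground
    truth fractions, stitched diagonal window-pair tensor preprocessing,
    five-fold cross-validated training of the network, transfer-learning
    fine-tuning for real tissue samples, concordance metrics (RMSE, Lin's
    CCC and a sample-wise modified CCC), and expected-gradients SHAP
    attribution with open-chromatin interpretation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'decooc-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'utils.R'
    'model.R'
    'finetune.R'
    'hic-io.R'
    'interpret.R'
    'methods.R'
    'metrics.R'
    'preprocess.R'
    'synthetic.R'
    'pipeline.R'
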