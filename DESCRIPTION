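Package: DRPcurves
Title: Learning-Curve Evaluation of Multi-Omics Drug Response Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cancer-blind learning-curve evaluation for drug response
    prediction from multi-omics cell-line profiles. Provides paired
    (cell line, drug, ln IC50) dataset construction with one-hot drug
    encoding, landmark-gene feature selection for RNA-seq, proteomics and
    phosphoproteomics matrices, a drug-average benchmark, gradient-boosted
    tree and feed-forward network learners with random hyperparameter
    search and validation-based early stopping, cancer-blind
    train/validation/test splitting with log-spaced training-subset
    schedules repeated over shuffles, power-law learning-curve fitting,
    region classification, extrapolation and curve-crossing detection, and
    max-size comparison statistics (average rankings, percentage MSE
    reductions, per-drug error analysis). A seeded synthetic-data
    generator emulating GDSC/ProCan-style inputs makes the whole pipeline
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    xgboost,
    jsonlite,
    nortest,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Pharmacogenomics, Proteomics, Transcriptomics,
    MachineLearning, Regression
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'DRPcurves-package.R'
    'curves.R'
    'experiment.R'
    'io.R'
    'models-benchmark.R'
    'models-gbt.R'
    'models-nn.R'
    'pairing.R'
    'plots.R'
    'prep.R'
    'reporting.R'
    'search.R'
    'splitting.R'
    'synthetic.R'
    'utils.R'
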