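Package: tfnoise
Title: Transcription-Factor Binding and Gene Expression Noise
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying and modelling cell-to-cell variability in
    gene expression driven by the transcription-factor (TF) binding process.
    Implements a mean-adjusted noise statistic based on polynomial detrending
    of the coefficient of variation against log mean expression, promoter
    feature engineering (motif scanning with mismatch tolerance, binding-site
    overlap statistics, positional site counts, nucleosome occupancy windows,
    tRNA adaptation index profiles), TF-target co-expression classification,
    a repeated train/test regression protocol reporting fraction of variation
    explained and predicted R-squared with lasso/ridge/stepwise-AIC feature
    selection, a stochastic two-state (telegraph) simulator of transcription
    under single, independent, cooperative and competitive TF binding, and a
    greedy Monte-Carlo sampler of the simulator's parameter space targeting a
    mean expression window. Synthetic data generators with known ground truth
    are included for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    glmnet,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    optparse
Config/testthat/edition: 3
biocViews: GeneExpression, SingleCell, Transcription, Regression,
    MotifAnnotation, StatisticalMethod
RoxygenNote: 7.3.3
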