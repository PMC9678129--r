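Package: milkDIMS
Title: Direct-Infusion MS Metabolomics of Dried Milk Spots with Model
    Triangulation and Stability Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end workflow for untargeted direct-infusion mass
    spectrometry (DIMS) metabolomics of dried milk spots, aimed at
    discriminating lame from healthy dairy cows. Covers ppm-window peak
    alignment of per-sample peak lists into a feature matrix, k-nearest
    neighbour imputation, total-ion-count normalisation with log transform
    and Pareto scaling, PCA and OPLS-DA with VIP scores and S-plots,
    leave-one-out Q2 and permutation validation, univariate t-tests with
    Benjamini-Hochberg FDR, triangulation of four machine-learning
    classifiers with recursive feature elimination, bootstrap stability
    selection over penalised models (elastic net, Lasso, MCP) with a
    permutation-derived stability threshold and sign-based bootstrap
    p-values, and adduct-based metabolite annotation against a local
    compound table. Includes a synthetic-data generator emulating the
    two-day dried-milk-spot study design so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    randomForest,
    e1071,
    pROC,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mzR,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
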