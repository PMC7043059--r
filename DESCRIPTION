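Package: chemPercept
Title: Predicting Color and Odor Perception from Molecular Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying the perceived color and odor of small
    molecules from high-dimensional physicochemical descriptor tables.
    Implements the full analysis pipeline: descriptor-table import with
    missing-value handling (NaN-to-zero imputation, exclusion of molecules
    with excessive missingness), stratified k-fold cross-validation,
    random-forest classification with out-of-bag permutation importance,
    deep belief networks (stacked restricted Boltzmann machines trained by
    contrastive divergence with supervised fine-tuning), genetic-algorithm
    wrapper feature selection with run-consensus, permutation-based feature
    ranking, feature-by-class correlation heat-map clustering, and the
    cross-modal color-odor Pearson correlation network with a dichotomized
    chi-square association test. A synthetic-data generator with planted
    class-coding features provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ranger,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
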