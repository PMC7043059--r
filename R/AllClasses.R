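#' DescriptorSet: molecules by molecular-descriptor table
#'
#' The central container of the package. A `DescriptorSet` extends
#' [SummarizedExperiment::SummarizedExperiment] with descriptors as rows
#' (features) and molecules as columns (samples). It carries two assays:
#' `values`, the numeric descriptor matrix, and `missing`, a logical mask of
#' the same shape that records which entries were missing ("NaN") in the
#' source table. Perceptual class labels (e.g. the 12 colors or 12 odors),
#' when present, live in `colData(x)$percept` as a factor whose levels are
#' the label vocabulary.
#'
#' Entries flagged in the missing mask hold `NA` in the `values` assay until
#' [imputeZero()] replaces them with 0 and clears the mask.
#'
#' @seealso [DescriptorSet()] for construction from a molecules-by-descriptors
#'   matrix, [readDescriptorCsv()] for import, [generateDataset()] for
#'   synthetic data with planted structure.
#' @export
setClass("DescriptorSet", contains = "SummarizedExperiment")

setValidity("DescriptorSet", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("values", "missing") %in% an))
    msg <- c(msg, "assays 'values' and 'missing' are required")
  else {
    miss <- SummarizedExperiment::assay(object, "missing")
    if (!is.logical(miss))
      msg <- c(msg, "'missing' assay must be logical")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "molecule ids (colnames) must be unique")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "descriptor names (rownames) must be unique")
  if ("percept" %in% colnames(SummarizedExperiment::colData(object))) {
    lab <- SummarizedExperiment::colData(object)$percept
    if (!is.factor(lab))
      msg <- c(msg, "'percept' labels must be a factor")
    else if (anyNA(lab))
      msg <- c(msg, "'percept' labels must not contain NA")
  }
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic descriptor dataset
#'
#' Describes the study conditions a synthetic dataset should emulate: the
#' number of molecules and descriptors, an (optionally imbalanced) class
#' layout, how many descriptors genuinely code each class and how strongly,
#' the missing-value rate, and how many descriptors code classes in both of
#' two paired modalities.
#'
#' @slot nMolecules number of molecules (rows of the user-facing table).
#' @slot nFeatures number of descriptors.
#' @slot nClasses number of perceptual categories.
#' @slot classSizes integer vector summing to `nMolecules`.
#' @slot informativePerClass descriptors planted per class.
#' @slot effectSize mean shift of a planted descriptor within its class, in
#'   units of that descriptor's noise SD.
#' @slot nanRate fraction of entries marked missing.
#' @slot sharedFeatureCount descriptors planted in both modalities of a
#'   paired dataset.
#' @slot seed master seed; generation is a pure function of the spec.
#' @export
setClass("SyntheticSpec", representation(
  nMolecules = "integer", nFeatures = "integer", nClasses = "integer",
  classSizes = "integer", informativePerClass = "integer",
  effectSize = "numeric", nanRate = "numeric",
  sharedFeatureCount = "integer", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (!validCount(object@nMolecules)) msg <- c(msg, "nMolecules must be >= 1")
  if (!validCount(object@nFeatures)) msg <- c(msg, "nFeatures must be >= 1")
  if (!validCount(object@nClasses)) msg <- c(msg, "nClasses must be >= 1")
  if (length(object@classSizes) != object@nClasses)
    msg <- c(msg, "classSizes must have one entry per class")
  if (any(object@classSizes < 1L))
    msg <- c(msg, "every class must have at least one molecule")
  if (sum(object@classSizes) != object@nMolecules)
    msg <- c(msg, "classSizes must sum to nMolecules")
  if (!validCount(object@informativePerClass, 0L))
    msg <- c(msg, "informativePerClass must be >= 0")
  if (!validFraction(object@nanRate))
    msg <- c(msg, "nanRate must lie in [0, 1]")
  if (!validCount(object@sharedFeatureCount, 0L))
    msg <- c(msg, "sharedFeatureCount must be >= 0")
  if (object@sharedFeatureCount > object@informativePerClass * object@nClasses)
    msg <- c(msg, "sharedFeatureCount cannot exceed the informative total")
  if (object@nClasses * object@informativePerClass * 2L > object@nFeatures)
    msg <- c(msg, "too many informative features for nFeatures")
  if (length(msg)) msg else TRUE
})

#' Cross-validation fold assignment
#'
#' A stratified partition of molecules into k folds. `foldIndex` maps each
#' molecule id to a fold in 1..k.
#'
#' @slot k number of folds.
#' @slot foldIndex named integer vector (names = molecule ids) in 1..k.
#' @export
setClass("FoldAssignment",
         representation(k = "integer", foldIndex = "integer"))

setValidity("FoldAssignment", function(object) {
  msg <- character()
  if (object@k < 2L) msg <- c(msg, "k must be >= 2")
  if (is.null(names(object@foldIndex)))
    msg <- c(msg, "foldIndex must be named by molecule id")
  if (any(object@foldIndex < 1L | object@foldIndex > object@k))
    msg <- c(msg, "fold indices must lie in 1..k")
  if (length(unique(object@foldIndex)) != object@k)
    msg <- c(msg, "every fold must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Random-forest hyperparameters
#'
#' @slot nTrees trees per forest (nTree; default 100).
#' @slot mTry candidate descriptors per split; `NA` means
#'   `defaultMtry(p)` = floor(sqrt(p)) at fit time.
#' @slot seed RNG seed for bootstrap and split sampling.
#' @export
setClass("ForestConfig", representation(
  nTrees = "integer", mTry = "integer", seed = "integer"))

setValidity("ForestConfig", function(object) {
  msg <- character()
  if (!validCount(object@nTrees)) msg <- c(msg, "nTrees must be >= 1")
  if (!is.na(object@mTry) && object@mTry < 1L)
    msg <- c(msg, "mTry must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Fitted random-forest classifier
#'
#' Wraps the fitted tree ensemble together with everything the out-of-bag
#' permutation-importance computation needs: the training matrix, the label
#' factor, and per-tree in-bag counts.
#'
#' @slot forest the fitted ranger ensemble.
#' @slot config the [ForestConfig-class] used.
#' @slot vocabulary class labels, in order.
#' @slot trainX training matrix (molecules x descriptors).
#' @slot trainY training labels.
#' @export
setClass("ForestModel", representation(
  forest = "ANY", config = "ForestConfig", vocabulary = "character",
  trainX = "matrix", trainY = "factor"))

#' Restricted Boltzmann machine
#'
#' Two-layer energy model with `nVisible` visible and `nHidden` hidden
#' Bernoulli units and no within-layer connections, trained by contrastive
#' divergence (CD-k).
#'
#' @slot weights nVisible x nHidden matrix.
#' @slot visibleBias,hiddenBias bias vectors.
#' @slot learningRate,momentum,cdSteps,epochs,batchSize,seed training
#'   hyperparameters.
#' @slot reconstructionError per-epoch mean squared reconstruction error
#'   (filled by [trainRbm()]).
#' @export
setClass("RBM", representation(
  weights = "matrix", visibleBias = "numeric", hiddenBias = "numeric",
  learningRate = "numeric", momentum = "numeric", cdSteps = "integer",
  epochs = "integer", batchSize = "integer", seed = "integer",
  reconstructionError = "numeric"))

setValidity("RBM", function(object) {
  msg <- character()
  if (length(object@visibleBias) != nrow(object@weights))
    msg <- c(msg, "visibleBias length must equal nrow(weights)")
  if (length(object@hiddenBias) != ncol(object@weights))
    msg <- c(msg, "hiddenBias length must equal ncol(weights)")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@momentum < 0 || object@momentum >= 1)
    msg <- c(msg, "momentum must lie in [0, 1)")
  if (object@cdSteps < 1L) msg <- c(msg, "cdSteps must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Deep belief network
#'
#' A stack of greedily pretrained [RBM-class] layers plus an optional
#' softmax classification head attached by [fineTune()].
#'
#' @slot layerSizes integer vector; first entry is the input dimension, and
#'   consecutive RBMs chain (hidden size of layer i = visible size of i+1).
#' @slot rbms list of RBMs.
#' @slot headWeights,headBias softmax readout (empty until fine-tuned).
#' @slot vocabulary class labels once fine-tuned.
#' @slot trainAccuracy per-epoch fine-tuning accuracy log.
#' @export
setClass("DBN", representation(
  layerSizes = "integer", rbms = "list", headWeights = "matrix",
  headBias = "numeric", vocabulary = "character",
  trainAccuracy = "numeric"))

setValidity("DBN", function(object) {
  msg <- character()
  ls <- object@layerSizes
  if (length(object@rbms) != length(ls) - 1L)
    msg <- c(msg, "need one RBM per consecutive layer pair")
  for (i in seq_along(object@rbms)) {
    r <- object@rbms[[i]]
    if (nrow(r@weights) != ls[i] || ncol(r@weights) != ls[i + 1L])
      msg <- c(msg, sprintf("RBM %d does not chain with layerSizes", i))
  }
  if (length(msg)) msg else TRUE
})

#' Genetic-algorithm wrapper-selection configuration
#'
#' Binary-chromosome GA whose fitness is the cross-validated accuracy of a
#' random forest restricted to the chromosome's active descriptors.
#'
#' @slot populationSize,generations GA budget.
#' @slot crossoverRate probability a child is produced by uniform crossover
#'   (otherwise it clones the better tournament parent).
#' @slot mutationRate per-bit flip probability; `NA` means 1/p.
#' @slot fitnessFolds folds of the internal CV used as fitness.
#' @slot nTrees trees in each fitness forest.
#' @slot tournamentSize,elitism selection pressure controls.
#' @slot initProb probability a bit starts active.
#' @slot seed run seed.
#' @export
setClass("GAConfig", representation(
  populationSize = "integer", generations = "integer",
  crossoverRate = "numeric", mutationRate = "numeric",
  fitnessFolds = "integer", nTrees = "integer", tournamentSize = "integer",
  elitism = "integer", initProb = "numeric", seed = "integer"))

setValidity("GAConfig", function(object) {
  msg <- character()
  if (!validCount(object@populationSize)) msg <- c(msg, "populationSize >= 1")
  if (!validCount(object@generations)) msg <- c(msg, "generations >= 1")
  if (!validFraction(object@crossoverRate))
    msg <- c(msg, "crossoverRate must lie in [0, 1]")
  if (!is.na(object@mutationRate) && !validFraction(object@mutationRate))
    msg <- c(msg, "mutationRate must lie in [0, 1]")
  if (object@fitnessFolds < 2L) msg <- c(msg, "fitnessFolds must be >= 2")
  if (!validFraction(object@initProb)) msg <- c(msg, "initProb in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Result of one GA selection run
#'
#' @slot mask logical vector over descriptors (the best chromosome of the
#'   final generation).
#' @slot featureNames descriptor names, parallel to `mask`.
#' @slot trace data.frame with per-generation best and mean fitness.
#' @slot fitness fitness of `mask`.
#' @slot repairs number of all-zero chromosomes repaired during the run.
#' @export
setClass("GASelection", representation(
  mask = "logical", featureNames = "character", trace = "data.frame",
  fitness = "numeric", repairs = "integer"))

#' Consensus over repeated GA selection runs
#'
#' @slot runs number of repeated runs R.
#' @slot selectionCount per-descriptor count in 0..R.
#' @slot minCount consensus threshold.
#' @slot consensusFeatures descriptors with `selectionCount >= minCount`.
#' @export
setClass("ConsensusSelection", representation(
  runs = "integer", selectionCount = "integer", minCount = "integer",
  consensusFeatures = "character"))

setValidity("ConsensusSelection", function(object) {
  msg <- character()
  if (any(object@selectionCount < 0L | object@selectionCount > object@runs))
    msg <- c(msg, "selection counts must lie in 0..runs")
  if (object@minCount > object@runs)
    msg <- c(msg, "minCount cannot exceed the number of runs")
  if (length(msg)) msg else TRUE
})

#' Permutation-based feature ranking
#'
#' For each descriptor, the mean over repetitions of |acc2 - acc1|, where
#' acc1 is the unperturbed validation accuracy and acc2 the accuracy after
#' randomly permuting that descriptor's column across validation molecules.
#'
#' @slot indicator named mean |acc2 - acc1| per descriptor.
#' @slot rank permutation of descriptors, most important first.
#' @slot acc1 baseline validation accuracies (one per repetition).
#' @slot repetitions number of repetitions.
#' @export
setClass("RankingResult", representation(
  indicator = "numeric", rank = "character", acc1 = "numeric",
  repetitions = "integer"))

#' Cross-validation result
#'
#' @slot foldAccuracy,foldKappa per-fold metrics.
#' @slot confusion pooled confusion matrix (rows = true, columns =
#'   predicted).
#' @slot vocabulary class labels.
#' @slot skippedFolds folds skipped because training lacked all classes.
#' @export
setClass("CVResult", representation(
  foldAccuracy = "numeric", foldKappa = "numeric", confusion = "matrix",
  vocabulary = "character", skippedFolds = "integer"))

#' Chi-square test on a dichotomized 2x2 color-odor table
#'
#' @slot table the 2x2 contingency table.
#' @slot statistic Pearson chi-square statistic.
#' @slot dof degrees of freedom (1).
#' @slot pValue upper-tail p-value.
#' @slot corrected whether the Yates continuity correction was applied.
#' @export
setClass("ChiSquareResult", representation(
  table = "matrix", statistic = "numeric", dof = "integer",
  pValue = "numeric", corrected = "logical"))

#' Cross-modal feature correlation network
#'
#' Nodes are key descriptors for either modality (tagged color-key,
#' odor-key, or shared); edges connect color-key to odor-key descriptors
#' whose Pearson correlation across the shared molecules meets the
#' threshold.
#'
#' @slot nodes data.frame with columns `feature` and `modality`.
#' @slot edges data.frame with columns `colorFeature`, `odorFeature`, `r`.
#' @slot threshold |r| cutoff.
#' @export
setClass("CrossModalNetwork", representation(
  nodes = "data.frame", edges = "data.frame", threshold = "numeric"))
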