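#' Random-forest configuration
#'
#' @param nTrees trees per forest (default 100).
#' @param mTry candidate descriptors per split; `NULL` means
#'   `defaultMtry(p)` at fit time.
#' @param seed RNG seed.
#' @return A [ForestConfig-class].
#' @export
forestConfig <- function(nTrees = 100L, mTry = NULL, seed = 1L) {
  cfg <- new("ForestConfig", nTrees = as.integer(nTrees),
             mTry = if (is.null(mTry)) NA_integer_ else as.integer(mTry),
             seed = as.integer(seed))
  validObject(cfg)
  cfg
}

#' Default number of split candidates
#'
#' The square-root convention: `floor(sqrt(p))` descriptors are sampled at
#' each split, giving 72 for a 5,270-descriptor table.
#'
#' @param p number of descriptors.
#' @return integer mTry.
#' @examples
#' defaultMtry(5270) # 72
#' @export
defaultMtry <- function(p) {
  if (!validCount(p)) stop("p must be a positive count")
  as.integer(floor(sqrt(p)))
}

dsToXy <- function(x, requireLabels = TRUE) {
  if (is(x, "DescriptorSet")) {
    if (any(SummarizedExperiment::assay(x, "missing")))
      stop("dataset still has missing entries; run imputeZero() first")
    X <- descriptorMatrix(x)
    y <- perceptLabels(x)
    if (requireLabels && is.null(y)) stop("dataset is unlabeled")
    list(X = X, y = y)
  } else {
    list(X = as.matrix(x), y = NULL)
  }
}

#' Fit a random-forest classifier
#'
#' Grows `nTrees` trees, each on a bootstrap sample of the molecules with
#' `mTry` candidate descriptors per split; prediction is by majority vote
#' over trees with ties broken toward the lowest vocabulary index.
#' Per-tree in-bag records are kept so out-of-bag permutation importance can
#' be computed. Deterministic under the config seed.
#'
#' @param x a labeled, imputed [DescriptorSet-class].
#' @param config a [ForestConfig-class].
#' @return A [ForestModel-class].
#' @export
fitForest <- function(x, config = forestConfig()) {
  d <- dsToXy(x)
  y <- droplevels(d$y)
  if (nlevels(y) < 2L)
    stop("training data must contain at least 2 classes")
  mtry <- if (is.na(config@mTry)) defaultMtry(ncol(d$X)) else
    min(config@mTry, ncol(d$X))
  fit <- ranger::ranger(x = d$X, y = y, num.trees = config@nTrees,
                        mtry = mtry, num.threads = 1L, seed = config@seed,
                        keep.inbag = TRUE)
  new("ForestModel", forest = fit, config = config,
      vocabulary = levels(perceptLabels(x)), trainX = d$X, trainY = d$y)
}

# Per-tree class predictions as indices into the model vocabulary.
treeVotes <- function(model, X) {
  pr <- predict(model@forest, data = X, predict.all = TRUE,
                num.threads = 1L)$predictions
  # per-tree values index directly into the fitted factor levels
  labChar <- model@forest$forest$levels[pr]
  matrix(match(labChar, model@vocabulary), nrow(pr), ncol(pr))
}

#' @describeIn fitForest majority-vote class predictions for new molecules
#'   (ties go to the lowest vocabulary index).
#' @param object a [ForestModel-class].
#' @param newdata a [DescriptorSet-class] or molecules-by-descriptors
#'   matrix over the training descriptors.
#' @param ... unused.
#' @export
setMethod("predictLabels", "ForestModel", function(object, newdata, ...) {
  d <- dsToXy(newdata, requireLabels = FALSE)
  votes <- treeVotes(object, d$X[, colnames(object@trainX), drop = FALSE])
  idx <- majorityVote(votes, length(object@vocabulary))
  factor(object@vocabulary[idx], levels = object@vocabulary)
})

#' Per-tree vote counts
#'
#' @param model a [ForestModel-class].
#' @param newdata molecules to predict.
#' @return molecules x classes matrix of vote counts (rows sum to nTrees).
#' @export
voteCounts <- function(model, newdata) {
  d <- dsToXy(newdata, requireLabels = FALSE)
  votes <- treeVotes(model, d$X[, colnames(model@trainX), drop = FALSE])
  counts <- t(apply(votes, 1L, tabulate, nbins = length(model@vocabulary)))
  dimnames(counts) <- list(rownames(d$X), model@vocabulary)
  counts
}

#' Out-of-bag permutation importance
#'
#' For each descriptor, its column is permuted across the training molecules
#' (one seeded permutation per descriptor) and each tree is re-evaluated on
#' its own out-of-bag molecules; the importance is the mean over trees of
#' the increase in OOB misclassification error. A descriptor no tree ever
#' splits on scores exactly 0.
#'
#' @param model a [ForestModel-class] fitted with in-bag records (the
#'   default).
#' @param seed RNG seed for the permutations.
#' @return named numeric vector, one importance per descriptor.
#' @export
oobImportance <- function(model, seed = 1L) {
  if (is.null(model@forest$inbag.counts))
    stop("model was fitted without in-bag records")
  X <- model@trainX
  yIdx <- match(as.character(model@trainY), model@vocabulary)
  inbag <- do.call(cbind, model@forest$inbag.counts)   # n x trees
  oob <- inbag == 0L
  oobN <- colSums(oob)
  ok <- oobN > 0L
  baseVotes <- treeVotes(model, X)
  errBase <- colSums((baseVotes != yIdx) & oob) / pmax(oobN, 1L)
  set.seed(deriveSeed(seed, "oobperm"))
  imp <- vapply(seq_len(ncol(X)), function(j) {
    Xp <- X
    Xp[, j] <- X[sample(nrow(X)), j]
    v <- treeVotes(model, Xp)
    errPerm <- colSums((v != yIdx) & oob) / pmax(oobN, 1L)
    mean((errPerm - errBase)[ok])
  }, numeric(1))
  names(imp) <- colnames(X)
  imp
}

#' Out-of-bag error estimate
#'
#' Mean over trees of the misclassification rate on each tree's own
#' out-of-bag molecules; an internal estimate of held-out error.
#'
#' @param model a [ForestModel-class].
#' @return OOB error rate in \[0, 1\].
#' @export
oobError <- function(model) {
  if (is.null(model@forest$inbag.counts))
    stop("model was fitted without in-bag records")
  inbag <- do.call(cbind, model@forest$inbag.counts)
  oob <- inbag == 0L
  yIdx <- match(as.character(model@trainY), model@vocabulary)
  votes <- treeVotes(model, model@trainX)
  oobN <- colSums(oob)
  ok <- oobN > 0L
  mean((colSums((votes != yIdx) & oob) / pmax(oobN, 1L))[ok])
}

#' Descriptors needed for classification
#'
#' A descriptor is "needed" when its permutation importance is nonzero;
#' negative importances (permutation noise) are clamped to 0 first.
#'
#' @param importance named numeric importance vector.
#' @return named logical mask; `sum(mask)` is the needed-feature count.
#' @export
neededFeatures <- function(importance) {
  pmax(importance, 0) > 0
}

#' Export an importance vector as CSV
#'
#' @param importance named numeric vector.
#' @param path output file (columns `descriptor`, `importance`).
#' @return `path`, invisibly.
#' @export
writeImportance <- function(importance, path) {
  data.table::fwrite(data.frame(descriptor = names(importance),
                                importance = unname(importance)), path)
  invisible(path)
}

setMethod("show", "ForestModel", function(object) {
  cat("ForestModel:", object@config@nTrees, "trees,",
      length(object@vocabulary), "classes,", ncol(object@trainX),
      "descriptors\n")
})
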