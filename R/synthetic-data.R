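#' Specify a synthetic descriptor dataset
#'
#' The generator emulates the structure of large molecular-descriptor tables
#' used for perceptual classification: thousands of descriptors on wildly
#' heterogeneous scales, a sparse subset that genuinely codes each class,
#' uniformly random missing entries, and (optionally) imbalanced 12-class
#' label layouts. It plants `informativePerClass` descriptors per class whose
#' class-conditional mean is shifted by `effectSize` noise-SDs, and records
#' the planted set as retrievable ground truth.
#'
#' @param nMolecules,nFeatures table dimensions.
#' @param nClasses number of perceptual categories (default 12).
#' @param classSizes integer vector summing to `nMolecules`; names, if
#'   given, become the label vocabulary. Defaults to a near-balanced split.
#' @param informativePerClass planted descriptors per class. Default 2,
#'   matching the scale of key-descriptor sets reported for 12-category
#'   perception tasks (roughly two key descriptors per category).
#' @param effectSize class-mean shift in units of the descriptor's noise SD
#'   (default 3, a strongly separable signal).
#' @param nanRate fraction of entries marked missing (default 0.067, the
#'   rate implied by an average of 353 missing entries among 5,270
#'   descriptors).
#' @param sharedFeatureCount descriptors informative for both modalities in
#'   a paired dataset (default 0).
#' @param seed master seed; all generation is a pure function of the spec.
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nMolecules, nFeatures, nClasses = 12L,
                          classSizes = NULL, informativePerClass = 2L,
                          effectSize = 3, nanRate = 0.067,
                          sharedFeatureCount = 0L, seed = 1L) {
  if (is.null(classSizes)) {
    base <- nMolecules %/% nClasses
    classSizes <- rep(base, nClasses)
    extra <- nMolecules - sum(classSizes)
    if (extra > 0) classSizes[seq_len(extra)] <- classSizes[seq_len(extra)] + 1L
  }
  nm <- names(classSizes)
  spec <- new("SyntheticSpec",
              nMolecules = as.integer(nMolecules),
              nFeatures = as.integer(nFeatures),
              nClasses = as.integer(nClasses),
              classSizes = as.integer(classSizes),
              informativePerClass = as.integer(informativePerClass),
              effectSize = as.numeric(effectSize),
              nanRate = as.numeric(nanRate),
              sharedFeatureCount = as.integer(sharedFeatureCount),
              seed = as.integer(seed))
  validObject(spec)
  attr(spec, "classNames") <- nm
  spec
}

#' The printed 12-color class-size profile
#'
#' Named molecule counts per color category of the 1,267-molecule color
#' dataset (560 colorless, 301 white, 257 yellow, down to 6 gray), offered
#' as a ready-made imbalanced layout for the generator.
#'
#' @return named integer vector summing to 1267.
#' @examples
#' spec <- syntheticSpec(1267, 800, classSizes = colorClassSizes())
#' @export
colorClassSizes <- function() {
  c(colorless = 560L, white = 301L, yellow = 257L, orange = 31L,
    green = 24L, brown = 20L, black = 17L, red = 16L, amber = 15L,
    purple = 11L, blue = 9L, gray = 6L)
}

specVocabulary <- function(spec) {
  nm <- attr(spec, "classNames")
  if (!is.null(nm)) nm else sprintf("class%02d", seq_len(spec@nClasses))
}

# Background draw: heavy-tailed heterogeneous scales (log-normal sigma),
# with a fraction of integer-valued count-like background descriptors.
generateValues <- function(spec, rngSeed) {
  set.seed(rngSeed)
  n <- spec@nMolecules; p <- spec@nFeatures
  sigma <- exp(rnorm(p, 0, 1))
  mu <- rnorm(p, 0, 1) * sigma
  X <- sweep(sweep(matrix(rnorm(n * p), n, p), 2, sigma, "*"), 2, mu, "+")
  integerCols <- sample(p, floor(0.25 * p))
  list(X = X, sigma = sigma, integerCols = integerCols)
}

plantSignal <- function(X, sigma, labels, planted, effectSize, rngSeed) {
  set.seed(rngSeed)
  shifts <- list()
  for (cl in names(planted)) {
    rows <- which(labels == cl)
    for (j in planted[[cl]]) {
      s <- sample(c(-1, 1), 1L) * effectSize * sigma[j]
      X[rows, j] <- X[rows, j] + s
      shifts[[length(shifts) + 1L]] <-
        data.frame(class = cl, feature = j, shift = s)
    }
  }
  list(X = X, shifts = do.call(rbind, shifts))
}

finishDataset <- function(X, integerCols, planted, labels, vocabulary, spec,
                          extraTruth = list()) {
  n <- nrow(X); p <- ncol(X)
  # keep planted descriptors continuous so the ground truth stays clean
  plantedIdx <- unique(unlist(planted))
  intCols <- setdiff(integerCols, plantedIdx)
  X[, intCols] <- round(X[, intCols])
  rownames(X) <- sprintf("CID%06d", seq_len(n))
  colnames(X) <- sprintf("D%05d", seq_len(p))
  plantedNames <- lapply(planted, function(j) colnames(X)[j])
  ds <- DescriptorSet(X, labels = labels, vocabulary = vocabulary)
  S4Vectors::metadata(ds)$groundTruth <- c(list(
    spec = spec, planted = plantedNames,
    allPlanted = colnames(X)[sort(plantedIdx)],
    integerColumns = colnames(X)[sort(intCols)]), extraTruth)
  if (spec@nanRate > 0)
    ds <- injectMissing(ds, spec@nanRate, deriveSeed(spec@seed, "missing"))
  ds
}

#' Generate a labeled synthetic descriptor dataset
#'
#' Draws a background table of label-independent descriptors on
#' heterogeneous (log-normal) scales, shifts the class-conditional mean of
#' each planted descriptor by `effectSize` noise-SDs (random sign), rounds a
#' quarter of the background descriptors to integers to mimic count-type
#' descriptors, marks entries missing at `nanRate`, and records the planted
#' descriptors in `plantedFeatures()`. Generation is a pure function of the
#' spec (same spec, same seed: byte-identical output).
#'
#' @param spec a [SyntheticSpec-class] from [syntheticSpec()].
#' @return A labeled [DescriptorSet-class] with ground truth in
#'   `plantedFeatures()`.
#' @examples
#' ds <- generateDataset(syntheticSpec(60, 40, nClasses = 3, seed = 7))
#' plantedFeatures(ds)$planted
#' @export
generateDataset <- function(spec) {
  validObject(spec)
  vocab <- specVocabulary(spec)
  set.seed(deriveSeed(spec@seed, "labels"))
  labels <- factor(rep(vocab, spec@classSizes), levels = vocab)
  labels <- sample(labels)

  gv <- generateValues(spec, deriveSeed(spec@seed, "background"))
  set.seed(deriveSeed(spec@seed, "planted"))
  idx <- sample(spec@nFeatures, spec@nClasses * spec@informativePerClass)
  planted <- split(idx, rep(vocab, each = spec@informativePerClass))[vocab]
  ps <- plantSignal(gv$X, gv$sigma, labels, planted, spec@effectSize,
                    deriveSeed(spec@seed, "shift"))
  finishDataset(ps$X, gv$integerCols, planted, labels, vocab, spec,
                list(shifts = ps$shifts))
}

#' Mark entries missing uniformly at random
#'
#' Each entry is independently flagged missing with probability `nanRate`
#' (MCAR); flagged values become `NA` and the original values are kept only
#' in the ground-truth record (`metadata(x)$injected`).
#'
#' @param x a [DescriptorSet-class].
#' @param nanRate fraction in \[0, 1\].
#' @param seed RNG seed.
#' @return The table with updated missing mask.
#' @export
injectMissing <- function(x, nanRate, seed = 1L) {
  if (!validFraction(nanRate)) stop("nanRate must lie in [0, 1]")
  if (nanRate == 0) return(x)
  vals <- SummarizedExperiment::assay(x, "values")
  mask <- SummarizedExperiment::assay(x, "missing")
  set.seed(deriveSeed(seed, "inject"))
  hit <- matrix(runif(length(vals)) < nanRate, nrow(vals), ncol(vals))
  newHit <- hit & !mask
  S4Vectors::metadata(x)$injected <- list(
    index = which(newHit), original = vals[newHit], nanRate = nanRate)
  vals[newHit] <- NA_real_
  mask[newHit] <- TRUE
  SummarizedExperiment::assay(x, "values") <- vals
  SummarizedExperiment::assay(x, "missing") <- mask
  x
}

#' Generate a paired color/odor dataset over the same molecules
#'
#' Both datasets share one descriptor value matrix (as when one molecule set
#' carries both a color and an odor label) but have independent label
#' assignments. `sharedFeatureCount` planted descriptors are informative for
#' one class of *each* modality, so a cross-modal correlation network over
#' the true key descriptors has planted shared nodes.
#'
#' @param spec a [SyntheticSpec-class]; `spec@sharedFeatureCount` controls
#'   the overlap of the two planted sets.
#' @return list with elements `color` and `odor`, two labeled
#'   [DescriptorSet-class] objects over identical molecules and values.
#' @export
generatePairedDataset <- function(spec) {
  validObject(spec)
  k <- spec@nClasses; ipc <- spec@informativePerClass
  vocabC <- paste0("color", sprintf("%02d", seq_len(k)))
  vocabO <- paste0("odor", sprintf("%02d", seq_len(k)))
  set.seed(deriveSeed(spec@seed, "pairlabels"))
  labC <- sample(factor(rep(vocabC, spec@classSizes), levels = vocabC))
  labO <- sample(factor(rep(vocabO, spec@classSizes), levels = vocabO))

  gv <- generateValues(spec, deriveSeed(spec@seed, "background"))
  set.seed(deriveSeed(spec@seed, "planted"))
  nShared <- spec@sharedFeatureCount
  total <- 2L * k * ipc - nShared
  idx <- sample(spec@nFeatures, total)
  colorIdx <- idx[seq_len(k * ipc)]
  sharedIdx <- colorIdx[seq_len(nShared)]
  odorIdx <- c(sharedIdx, idx[(k * ipc + 1L):total])
  plantedC <- split(colorIdx, rep(vocabC, each = ipc))[vocabC]
  plantedO <- split(odorIdx, rep(vocabO, each = ipc))[vocabO]

  psC <- plantSignal(gv$X, gv$sigma, labC, plantedC, spec@effectSize,
                     deriveSeed(spec@seed, "shiftC"))
  psO <- plantSignal(psC$X, gv$sigma, labO, plantedO, spec@effectSize,
                     deriveSeed(spec@seed, "shiftO"))
  planted <- c(plantedC, plantedO)
  sharedTruth <- list(sharedIndex = sharedIdx)

  base <- finishDataset(psO$X, gv$integerCols, planted, labC, vocabC, spec,
                        c(sharedTruth, list(shifts = rbind(psC$shifts,
                                                           psO$shifts))))
  gt <- S4Vectors::metadata(base)$groundTruth
  sharedNames <- if (nShared > 0)
    descriptorNames(base)[sort(sharedIdx)] else character()
  gt$shared <- sharedNames
  gt$plantedColor <- gt$planted[vocabC]
  gt$plantedOdor <- gt$planted[vocabO]

  dsColor <- base
  S4Vectors::metadata(dsColor)$groundTruth <- gt
  dsOdor <- dsColor
  SummarizedExperiment::colData(dsOdor)$percept <-
    factor(as.character(labO), levels = vocabO)
  list(color = dsColor, odor = dsOdor)
}
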