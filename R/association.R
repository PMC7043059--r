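#' Build a confusion matrix
#'
#' @param true,predicted factors over the same vocabulary.
#' @param vocabulary ordered class labels; defaults to the levels of
#'   `true`.
#' @return c x c integer matrix, rows = true label, columns = predicted.
#' @export
confusionMatrix <- function(true, predicted, vocabulary = NULL) {
  if (is.null(vocabulary)) vocabulary <- levels(as.factor(true))
  t(vapply(vocabulary, function(tr) {
    tabulate(match(as.character(predicted)[as.character(true) == tr],
                   vocabulary), nbins = length(vocabulary))
  }, integer(length(vocabulary)))) |> structure(
    dimnames = list(true = vocabulary, predicted = vocabulary))
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement: kappa = (p_o - p_e) / (1 - p_e) with
#' p_o = trace / total and p_e = sum of (row margin x column margin) /
#' total^2. Any diagonal-only matrix gives exactly 1; in the degenerate
#' single-class perfect case (p_e = p_o = 1) kappa is defined as 1.
#'
#' @param cm square count matrix (rows = true, columns = predicted).
#' @return kappa in \[-1, 1\].
#' @examples
#' cohenKappa(diag(c(560, 301, 257)))  # 1
#' @export
cohenKappa <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Cross-validate a learner
#'
#' For each fold: train the learner on the complement, predict the fold,
#' record accuracy and Cohen's kappa, and accumulate the pooled confusion
#' matrix. A fold whose training complement lacks every class is skipped
#' with a warning and reported in `@skippedFolds`.
#'
#' @param x a labeled, imputed [DescriptorSet-class].
#' @param folds a [FoldAssignment-class] over the molecules of `x`.
#' @param learner a list with `fit(ds)` returning a model and
#'   `predict(model, ds)` returning a factor over the vocabulary — see
#'   [forestLearner()] and [dbnLearner()].
#' @return A [CVResult-class].
#' @export
crossValidate <- function(x, folds, learner) {
  lab <- perceptLabels(x)
  vocab <- levels(lab)
  idx <- folds@foldIndex[moleculeIds(x)]
  if (anyNA(idx)) stop("fold assignment does not cover all molecules")
  cm <- matrix(0L, length(vocab), length(vocab),
               dimnames = list(true = vocab, predicted = vocab))
  accs <- numeric(); kappas <- numeric(); skipped <- integer()
  for (f in sort(unique(idx))) {
    trainDs <- x[, idx != f]
    testDs <- x[, idx == f]
    if (nlevels(droplevels(perceptLabels(trainDs))) < 2L) {
      warning("fold ", f, " skipped: training data lacks class variety")
      skipped <- c(skipped, f)
      next
    }
    model <- learner$fit(trainDs)
    pred <- learner$predict(model, testDs)
    truth <- perceptLabels(testDs)
    accs <- c(accs, mean(as.character(pred) == as.character(truth)))
    cmF <- confusionMatrix(truth, pred, vocab)
    kappas <- c(kappas, cohenKappa(cmF))
    cm <- cm + cmF
  }
  new("CVResult", foldAccuracy = accs, foldKappa = kappas, confusion = cm,
      vocabulary = vocab, skippedFolds = skipped)
}

#' Forest learner for cross-validation
#'
#' @param config a [ForestConfig-class].
#' @return learner list with `fit` and `predict` for [crossValidate()].
#' @export
forestLearner <- function(config = forestConfig()) {
  list(fit = function(ds) fitForest(ds, config),
       predict = function(model, ds) predictLabels(model, ds))
}

#' @describeIn crossValidate accuracy mean over folds.
#' @param result a [CVResult-class].
#' @export
accuracyMean <- function(result) mean(result@foldAccuracy)

#' @describeIn crossValidate accuracy SD over folds.
#' @export
accuracySd <- function(result) sd(result@foldAccuracy)

#' @describeIn crossValidate kappa mean over folds.
#' @export
kappaMean <- function(result) mean(result@foldKappa)

#' @describeIn crossValidate kappa SD over folds.
#' @export
kappaSd <- function(result) sd(result@foldKappa)

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: accuracy %.2f%% +/- %.2f%% (mean +/- SD over %d folds)\n",
              100 * mean(object@foldAccuracy), 100 * sd(object@foldAccuracy),
              length(object@foldAccuracy)))
  cat(sprintf("          kappa    %.4f +/- %.4f\n",
              mean(object@foldKappa), sd(object@foldKappa)))
  if (length(object@skippedFolds))
    cat("  skipped folds:", paste(object@skippedFolds, collapse = ", "), "\n")
})

#' z-score standardization
#'
#' (x - mean) / SD with the sample (n-1) SD convention; the result has mean
#' 0 and unit SD. Constant input is an error (named when the vector carries
#' a name attribute).
#'
#' @param values numeric vector with at least 2 values.
#' @param name optional label used in the zero-SD error message.
#' @return standardized numeric vector.
#' @export
zscore <- function(values, name = NULL) {
  if (length(values) < 2L) stop("zscore needs at least 2 values")
  s <- sd(values)
  if (!is.finite(s) || s == 0)
    stop("zero standard deviation",
         if (!is.null(name)) paste0(" in feature '", name, "'") else "")
  (values - mean(values)) / s
}

#' Feature-by-class correlation matrix
#'
#' Entry (f, c) is the Pearson correlation between descriptor f (z-scored)
#' and the one-hot indicator of class c — the point-biserial correlation.
#' A constant descriptor yields a row of zeros (with a message) rather than
#' an error.
#'
#' @param x a labeled, imputed [DescriptorSet-class].
#' @param features descriptor names (default: all).
#' @return features x classes matrix of correlations in \[-1, 1\].
#' @export
featureClassCorrelation <- function(x, features = NULL) {
  if (is.null(features)) features <- descriptorNames(x)
  vals <- descriptorMatrix(x)[, features, drop = FALSE]
  lab <- perceptLabels(x)
  if (is.null(lab)) stop("dataset is unlabeled")
  out <- matrix(0, length(features), nlevels(lab),
                dimnames = list(features, levels(lab)))
  const <- apply(vals, 2L, sd) == 0
  if (any(const))
    message("constant descriptor(s) set to correlation 0: ",
            paste(features[const], collapse = ", "))
  for (cl in levels(lab)) {
    ind <- as.numeric(lab == cl)
    if (sd(ind) == 0) next
    out[!const, cl] <- drop(cor(vals[, !const, drop = FALSE], ind))
  }
  out
}

#' Agglomerative clustering of a feature-by-class matrix
#'
#' Clusters rows and columns under Euclidean distance (average linkage) and
#' returns the leaf orders and merge trees used to arrange correlation heat
#' maps.
#'
#' @param m numeric matrix (e.g. from [featureClassCorrelation()]).
#' @param linkage agglomeration method (default "average").
#' @return list with `rowOrder`, `colOrder`, `rowDendrogram`,
#'   `colDendrogram` (`NULL` tree and trivial order for single rows or
#'   columns).
#' @export
hierarchicalCluster <- function(m, linkage = "average") {
  if (!all(is.finite(m))) stop("matrix must be finite")
  clusterAxis <- function(mm) {
    if (nrow(mm) < 2L)
      return(list(order = seq_len(nrow(mm)), tree = NULL))
    hc <- hclust(dist(mm, method = "euclidean"), method = linkage)
    list(order = hc$order, tree = as.dendrogram(hc))
  }
  r <- clusterAxis(m)
  c <- clusterAxis(t(m))
  list(rowOrder = r$order, colOrder = c$order,
       rowDendrogram = r$tree, colDendrogram = c$tree)
}

#' Heat map of a feature-by-class correlation matrix
#'
#' Renders the clustered matrix with `pheatmap` when available, otherwise
#' with `stats::heatmap`.
#'
#' @param m matrix from [featureClassCorrelation()].
#' @param filename optional output file (PNG/SVG chosen by extension;
#'   pheatmap only).
#' @param ... passed to the plotting backend.
#' @return the plotting backend's value, invisibly.
#' @export
plotFeatureClassHeatmap <- function(m, filename = NA, ...) {
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    invisible(pheatmap::pheatmap(m, clustering_method = "average",
                                 filename = filename, ...))
  } else {
    invisible(stats::heatmap(m, hclustfun = function(d)
      hclust(d, method = "average"), ...))
  }
}

#' Cross-modal color-odor feature network
#'
#' Pearson-correlates every color-key descriptor with every odor-key
#' descriptor across the molecules shared by both modalities (descriptor
#' columns are z-scored first, which leaves Pearson r unchanged) and keeps
#' edges with |r| at or above the threshold. The default threshold
#' 0.300552 reproduces the published cutoff. Descriptors present in both
#' key sets are tagged `shared`.
#'
#' @param colorValues,odorValues molecules x key-descriptor matrices over
#'   the same molecules (matching rownames when present).
#' @param threshold |r| cutoff (default 0.300552).
#' @return A [CrossModalNetwork-class].
#' @export
crossModalNetwork <- function(colorValues, odorValues,
                              threshold = 0.300552) {
  colorValues <- as.matrix(colorValues)
  odorValues <- as.matrix(odorValues)
  if (nrow(colorValues) != nrow(odorValues))
    stop("both matrices must cover the same shared molecules")
  if (!is.null(rownames(colorValues)) && !is.null(rownames(odorValues)) &&
      !identical(rownames(colorValues), rownames(odorValues)))
    stop("shared molecule ids disagree between the two matrices")
  if (nrow(colorValues) < 3L)
    stop("need at least 3 shared molecules")
  cf <- colnames(colorValues); of <- colnames(odorValues)
  r <- suppressWarnings(cor(colorValues, odorValues))
  r[!is.finite(r)] <- 0
  hit <- which(abs(r) >= threshold, arr.ind = TRUE)
  edges <- data.frame(colorFeature = cf[hit[, 1]],
                      odorFeature = of[hit[, 2]],
                      r = r[hit], stringsAsFactors = FALSE)
  edges <- edges[order(-abs(edges$r)), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(
    feature = union(cf, of),
    modality = ifelse(union(cf, of) %in% intersect(cf, of), "shared",
                      ifelse(union(cf, of) %in% cf, "color-key",
                             "odor-key")),
    stringsAsFactors = FALSE)
  new("CrossModalNetwork", nodes = nodes, edges = edges,
      threshold = threshold)
}

#' @describeIn crossModalNetwork edge table (colorFeature, odorFeature, r).
#' @param x a [CrossModalNetwork-class].
#' @export
setMethod("networkEdges", "CrossModalNetwork", function(x) x@edges)

#' @describeIn crossModalNetwork node table with modality tags.
#' @export
setMethod("networkNodes", "CrossModalNetwork", function(x) x@nodes)

setMethod("show", "CrossModalNetwork", function(object) {
  cat("CrossModalNetwork:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges at |r| >=", object@threshold, "\n")
  shared <- object@nodes$feature[object@nodes$modality == "shared"]
  if (length(shared))
    cat("  shared descriptors:", paste(shared, collapse = ", "), "\n")
})

#' Export a network edge list as CSV
#'
#' @param x a [CrossModalNetwork-class].
#' @param path output file (columns `feature_a`, `feature_b`, `r`).
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(x, path) {
  e <- x@edges
  data.table::fwrite(data.frame(feature_a = e$colorFeature,
                                feature_b = e$odorFeature, r = e$r), path)
  invisible(path)
}

#' Dichotomized chi-square association of color and odor
#'
#' Colors are dichotomized into \{white or colorless\} vs other and odors
#' into \{odorless\} vs other, and the resulting 2x2 table is tested with
#' the Pearson chi-square on 1 degree of freedom (no continuity correction
#' by default; set `correct = TRUE` for the Yates-corrected convention).
#'
#' @param colorLabels,odorLabels label vectors over the same molecules.
#' @param colorPositive labels forming the first color category (default
#'   `c("white", "colorless")`).
#' @param odorPositive labels forming the first odor category (default
#'   `"odorless"`).
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return A [ChiSquareResult-class].
#' @export
dichotomizeChi2 <- function(colorLabels, odorLabels,
                            colorPositive = c("white", "colorless"),
                            odorPositive = "odorless", correct = FALSE) {
  if (length(colorLabels) != length(odorLabels))
    stop("label vectors must cover the same molecules")
  cb <- factor(ifelse(as.character(colorLabels) %in% colorPositive,
                      "white/colorless", "other"),
               levels = c("white/colorless", "other"))
  ob <- factor(ifelse(as.character(odorLabels) %in% odorPositive,
                      "odorless", "other"), levels = c("odorless", "other"))
  tab <- as.matrix(table(color = cb, odor = ob))
  chiSquare2x2(tab, correct = correct)
}

#' @rdname dichotomizeChi2
#' @param tab a 2x2 count matrix.
#' @export
chiSquare2x2 <- function(tab, correct = FALSE) {
  tab <- matrix(as.vector(as.matrix(tab)), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
  if (!all(dim(tab) == 2L)) stop("table must be 2x2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in the 2x2 table")
  n <- sum(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / n
  dev <- abs(tab - expd)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expd)
  new("ChiSquareResult", table = tab, statistic = stat, dof = 1L,
      pValue = pchisq(stat, df = 1, lower.tail = FALSE),
      corrected = correct)
}

setMethod("show", "ChiSquareResult", function(object) {
  cat(sprintf("ChiSquareResult: chi2 = %.3f (df = 1), P = %.3g%s\n",
              object@statistic, object@pValue,
              if (object@corrected) " [Yates-corrected]" else ""))
  print(object@table)
})
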