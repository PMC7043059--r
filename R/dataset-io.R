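missingTokens <- function() {
  tok <- c("nan", "na")
  out <- unique(unlist(lapply(tok, function(t) {
    chars <- strsplit(t, "")[[1]]
    grid <- expand.grid(lapply(chars, function(ch) c(ch, toupper(ch))),
                        stringsAsFactors = FALSE)
    apply(grid, 1, paste, collapse = "")
  })))
  c("", out)
}

#' Read a descriptor-table CSV
#'
#' Expects the dialect written by [writeDescriptorCsv()]: a header row with a
#' molecule-id column (`cid`), an optional label column, and one column per
#' descriptor; "." decimal separator; missing cells spelled "NaN", "na" (any
#' case) or left empty. Missing cells are recorded in the missing mask, not
#' silently zeroed.
#'
#' @param path CSV file.
#' @param labelColumn name of the label column, or `NULL` for an unlabeled
#'   table.
#' @param idColumn name of the molecule-id column (default `"cid"`).
#' @param vocabulary optional ordered label vocabulary; labels outside it
#'   are an error. Defaults to the sorted unique labels in the file.
#' @return A labeled or unlabeled [DescriptorSet-class].
#' @export
readDescriptorCsv <- function(path, labelColumn = NULL, idColumn = "cid",
                              vocabulary = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, na.strings = missingTokens(),
                          colClasses = list(character = idColumn),
                          data.table = FALSE, showProgress = FALSE)
  if (!idColumn %in% names(dt))
    stop("molecule-id column '", idColumn, "' not found")
  ids <- as.character(dt[[idColumn]])
  dup <- which(duplicated(ids))
  if (length(dup))
    stop("duplicate molecule id '", ids[dup[1]], "' at row ", dup[1])
  labels <- NULL
  if (!is.null(labelColumn)) {
    if (!labelColumn %in% names(dt))
      stop("label column '", labelColumn, "' not found")
    labels <- as.character(dt[[labelColumn]])
    if (anyNA(labels))
      stop("missing label at row ", which(is.na(labels))[1])
    if (!is.null(vocabulary)) {
      bad <- which(!labels %in% vocabulary)
      if (length(bad))
        stop("unknown label '", labels[bad[1]], "' at row ", bad[1],
             ", column '", labelColumn, "'")
    }
  }
  featCols <- setdiff(names(dt), c(idColumn, labelColumn))
  vals <- as.matrix(dt[featCols])
  if (!is.numeric(vals))
    stop("non-numeric descriptor value; first offending column: ",
         featCols[which(!vapply(dt[featCols], is.numeric, TRUE))[1]])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  DescriptorSet(vals, missing = is.na(vals), labels = labels,
                vocabulary = vocabulary)
}

#' Write a descriptor-table CSV
#'
#' Writes the `cid,label,<descriptors...>` dialect consumed by
#' [readDescriptorCsv()]. Missing entries are written as `NaN`; numeric
#' values round-trip at full precision.
#'
#' @param x a [DescriptorSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDescriptorCsv <- function(x, path) {
  vals <- descriptorMatrix(x)
  df <- data.frame(cid = moleculeIds(x), stringsAsFactors = FALSE)
  lab <- perceptLabels(x)
  if (!is.null(lab)) df$label <- as.character(lab)
  # %.17g guarantees doubles survive the text round trip bit-exactly
  chars <- as.data.frame(apply(vals, 2L, function(col)
    ifelse(is.na(col), NA_character_, sprintf("%.17g", col)),
    simplify = FALSE), check.names = FALSE, optional = TRUE)
  df <- cbind(df, chars)
  data.table::fwrite(df, path, na = "NaN", quote = FALSE)
  invisible(path)
}

#' Exclude molecules with excessive missingness
#'
#' Removes molecules whose per-row count of missing descriptors strictly
#' exceeds `maxMissing` (default 2,000, the exclusion rule used for
#' 5,270-descriptor tables; a molecule with exactly `maxMissing` missing
#' entries is retained). Applied before imputation. Survivor order is
#' preserved and the removed ids are reported in
#' `metadata(x)$removedMolecules`.
#'
#' @param x a [DescriptorSet-class].
#' @param maxMissing largest tolerated per-molecule missing count.
#' @return The filtered [DescriptorSet-class].
#' @export
filterHighMissing <- function(x, maxMissing = 2000L) {
  if (maxMissing < 0) stop("maxMissing must be >= 0")
  counts <- colSums(SummarizedExperiment::assay(x, "missing"))
  keep <- counts <= maxMissing
  out <- x[, keep]
  S4Vectors::metadata(out)$removedMolecules <-
    data.frame(cid = moleculeIds(x)[!keep],
               missingCount = unname(counts[!keep]))
  out
}

#' Replace missing entries with zero
#'
#' Sets every masked entry's value to 0 and clears the missing mask;
#' non-missing values are untouched. Idempotent.
#'
#' @param x a [DescriptorSet-class].
#' @return The imputed [DescriptorSet-class].
#' @export
imputeZero <- function(x) {
  vals <- SummarizedExperiment::assay(x, "values")
  mask <- SummarizedExperiment::assay(x, "missing")
  vals[mask] <- 0
  mask[] <- FALSE
  SummarizedExperiment::assay(x, "values") <- vals
  SummarizedExperiment::assay(x, "missing") <- mask
  x
}

#' Average number of missing entries per molecule
#'
#' Arithmetic mean over molecules of the per-row missing count, computed
#' from the missing mask (i.e. before imputation).
#'
#' @param x a [DescriptorSet-class].
#' @return a real number (entries per molecule).
#' @export
meanMissingCount <- function(x) {
  if (ncol(x) == 0L) stop("empty table: no molecules")
  mean(colSums(SummarizedExperiment::assay(x, "missing")))
}

#' Build stratified cross-validation folds
#'
#' Partitions molecules into `k` folds (default 4), stratified by class:
#' each class's molecules are shuffled and dealt cyclically onto folds via a
#' pointer that continues across classes, so per-class counts differ by at
#' most one between folds and overall fold sizes differ by at most one.
#' Classes with fewer members than `k` land in only some folds.
#' Deterministic under `seed`.
#'
#' @param x a labeled [DescriptorSet-class].
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @return A [FoldAssignment-class].
#' @export
makeFolds <- function(x, k = 4L, seed = 1L) {
  lab <- perceptLabels(x)
  if (is.null(lab)) stop("makeFolds needs a labeled dataset")
  n <- ncol(x); k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k must not exceed the number of molecules")
  set.seed(deriveSeed(seed, "folds"))
  fold <- integer(n)
  ptr <- 0L
  # larger classes first so small classes fill the currently lightest folds
  for (cl in names(sort(table(lab), decreasing = TRUE))) {
    idx <- which(lab == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- (ptr + seq_along(idx) - 1L) %% k + 1L
    ptr <- (ptr + length(idx)) %% k
  }
  names(fold) <- moleculeIds(x)
  new("FoldAssignment", k = k, foldIndex = fold)
}

#' Export a fold assignment as a two-column CSV
#'
#' @param folds a [FoldAssignment-class].
#' @param path output file (columns `cid`, `fold`).
#' @return `path`, invisibly.
#' @export
writeFolds <- function(folds, path) {
  data.table::fwrite(data.frame(cid = names(folds@foldIndex),
                                fold = unname(folds@foldIndex)), path)
  invisible(path)
}

setMethod("show", "FoldAssignment", function(object) {
  cat("FoldAssignment: k =", object@k, "over", length(object@foldIndex),
      "molecules; fold sizes:",
      paste(tabulate(object@foldIndex, object@k), collapse = ", "), "\n")
})
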