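#' Construct a DescriptorSet
#'
#' Builds the package's central container from a molecules-by-descriptors
#' matrix, the orientation descriptor tables are shipped in. Internally the
#' matrix is stored transposed (descriptors as rows), following the
#' SummarizedExperiment convention of features-in-rows.
#'
#' @param values numeric matrix, one row per molecule, one column per
#'   descriptor. Rownames are molecule ids (e.g. PubChem CIDs), colnames
#'   descriptor names.
#' @param missing optional logical matrix of the same shape marking missing
#'   ("NaN") entries. Defaults to `is.na(values)`.
#' @param labels optional perceptual class per molecule (character or
#'   factor).
#' @param vocabulary ordered label vocabulary; defaults to the factor levels
#'   of `labels`, or its sorted unique values.
#' @return A [DescriptorSet-class].
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("CID", 1:3), paste0("D", 1:4)))
#' ds <- DescriptorSet(m, labels = c("red", "blue", "red"))
#' nMolecules(ds)
#' @export
DescriptorSet <- function(values, missing = NULL, labels = NULL,
                          vocabulary = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("MOL", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("D", seq_len(ncol(values)))
  if (is.null(missing)) missing <- is.na(values)
  missing <- as.matrix(missing)
  if (!identical(dim(missing), dim(values)))
    stop("'missing' must have the same shape as 'values'")
  storage.mode(missing) <- "logical"
  dimnames(missing) <- dimnames(values)
  values[missing] <- NA_real_

  cd <- S4Vectors::DataFrame(row.names = rownames(values))
  if (!is.null(labels)) {
    if (length(labels) != nrow(values))
      stop("labels length must equal the number of molecules")
    if (is.null(vocabulary))
      vocabulary <- if (is.factor(labels)) levels(labels)
                    else sort(unique(as.character(labels)))
    if (!all(as.character(labels) %in% vocabulary))
      stop("unknown label value(s): ",
           paste(setdiff(unique(as.character(labels)), vocabulary),
                 collapse = ", "))
    cd$percept <- factor(as.character(labels), levels = vocabulary)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = t(values), missing = t(missing)), colData = cd)
  new("DescriptorSet", se)
}

#' @describeIn DescriptorSet molecule identifiers.
#' @param x a DescriptorSet.
#' @export
setMethod("moleculeIds", "DescriptorSet", function(x) colnames(x))

#' @describeIn DescriptorSet descriptor names.
#' @export
setMethod("descriptorNames", "DescriptorSet", function(x) rownames(x))

#' @describeIn DescriptorSet the molecules-by-descriptors value matrix
#'   (missing entries as `NA` until imputed).
#' @export
setMethod("descriptorMatrix", "DescriptorSet",
          function(x) t(SummarizedExperiment::assay(x, "values")))

#' @describeIn DescriptorSet logical molecules-by-descriptors missingness
#'   mask.
#' @export
setMethod("missingMask", "DescriptorSet",
          function(x) t(SummarizedExperiment::assay(x, "missing")))

#' @describeIn DescriptorSet per-molecule class labels (factor), or `NULL`.
#' @export
setMethod("perceptLabels", "DescriptorSet", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("percept" %in% colnames(cd)) cd$percept else NULL
})

#' @describeIn DescriptorSet the ordered label vocabulary, or `NULL`.
#' @export
setMethod("labelVocabulary", "DescriptorSet", function(x) {
  lab <- perceptLabels(x)
  if (is.null(lab)) NULL else levels(lab)
})

#' @describeIn DescriptorSet ground-truth record of planted class-coding
#'   descriptors for synthetic data (`NULL` for real data).
#' @export
setMethod("plantedFeatures", "DescriptorSet", function(x) {
  S4Vectors::metadata(x)$groundTruth
})

#' Number of molecules / descriptors
#'
#' @param x a [DescriptorSet-class].
#' @return integer count.
#' @export
nMolecules <- function(x) ncol(x)

#' @rdname nMolecules
#' @export
nDescriptors <- function(x) nrow(x)

setMethod("show", "DescriptorSet", function(object) {
  cat("DescriptorSet:", ncol(object), "molecules x", nrow(object),
      "descriptors\n")
  nmiss <- sum(SummarizedExperiment::assay(object, "missing"))
  cat("  missing entries:", nmiss, "\n")
  lab <- perceptLabels(object)
  if (!is.null(lab)) {
    cat("  labels (", nlevels(lab), " classes): ",
        paste(head(levels(lab), 6), collapse = ", "),
        if (nlevels(lab) > 6) ", ..." else "", "\n", sep = "")
  } else cat("  unlabeled\n")
  gt <- S4Vectors::metadata(object)$groundTruth
  if (!is.null(gt))
    cat("  synthetic; planted descriptors:",
        length(unique(unlist(gt$planted))), "\n")
})

# Subset a DescriptorSet to named descriptors (keeps class and metadata).
#' Restrict a DescriptorSet to a subset of descriptors
#'
#' @param x a [DescriptorSet-class].
#' @param features descriptor names (or logical/integer index over
#'   descriptors).
#' @return a [DescriptorSet-class] with only the requested descriptors.
#' @export
selectFeatures <- function(x, features) {
  if (is.character(features)) {
    missing <- setdiff(features, rownames(x))
    if (length(missing))
      stop("unknown descriptor(s): ", paste(head(missing, 5), collapse = ", "))
  }
  x[features, ]
}
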