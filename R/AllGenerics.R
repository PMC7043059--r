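#' @export
setGeneric("moleculeIds", function(x) standardGeneric("moleculeIds"))

#' @export
setGeneric("descriptorNames", function(x) standardGeneric("descriptorNames"))

#' @export
setGeneric("descriptorMatrix", function(x) standardGeneric("descriptorMatrix"))

#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @export
setGeneric("perceptLabels", function(x) standardGeneric("perceptLabels"))

#' @export
setGeneric("labelVocabulary", function(x) standardGeneric("labelVocabulary"))

#' @export
setGeneric("plantedFeatures", function(x) standardGeneric("plantedFeatures"))

#' @export
setGeneric("predictLabels", function(object, newdata, ...)
  standardGeneric("predictLabels"))

#' @export
setGeneric("consensusFeatures", function(x) standardGeneric("consensusFeatures"))

#' @export
setGeneric("selectionCounts", function(x) standardGeneric("selectionCounts"))

#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
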