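#' @rdname ExpressionSeries-accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ExpressionSeries-accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname ExpressionSeries-accessors
#' @export
setGeneric("sampleSplit", function(x) standardGeneric("sampleSplit"))

#' @rdname ExpressionSeries-accessors
#' @export
setGeneric("sampleConfounder", function(x) standardGeneric("sampleConfounder"))

#' @rdname ExpressionSeries-accessors
#' @export
setGeneric("learningSamples", function(x) standardGeneric("learningSamples"))

#' @rdname ExpressionSeries-accessors
#' @export
setGeneric("testingSamples", function(x) standardGeneric("testingSamples"))

#' @rdname GeneSignature-accessors
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))

#' @rdname RelevanceTable-accessors
#' @export
setGeneric("geneRelevance", function(x) standardGeneric("geneRelevance"))

#' @rdname RelevanceTable-accessors
#' @export
setGeneric("sampleRelevance", function(x) standardGeneric("sampleRelevance"))

#' @rdname RelevanceTable-accessors
#' @export
setGeneric("relevanceThreshold", function(x) standardGeneric("relevanceThreshold"))

#' @rdname ClassificationReport-accessors
#' @export
setGeneric("decisions", function(x) standardGeneric("decisions"))

#' @rdname ClassificationReport-accessors
#' @export
setGeneric("predictionCounts", function(x) standardGeneric("predictionCounts"))
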