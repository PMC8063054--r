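#' @rdname CountExperiment-class
#' @param x a CountExperiment or NormalizedExperiment.
#' @export
setGeneric("cellType", function(x) standardGeneric("cellType"))

#' @rdname CountExperiment-class
#' @export
setGeneric("study", function(x) standardGeneric("study"))

#' @rdname NormalizedExperiment-class
#' @param x a NormalizedExperiment.
#' @export
setGeneric("transformLog", function(x) standardGeneric("transformLog"))

#' @rdname SampleEmbedding-class
#' @param x a SampleEmbedding.
#' @export
setGeneric("sampleCoordinates", function(x) standardGeneric("sampleCoordinates"))

#' @rdname SampleEmbedding-class
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @rdname VennPartition-class
#' @param x a VennPartition or CascadeResult.
#' @export
setGeneric("regionSets", function(x) standardGeneric("regionSets"))

#' @rdname VennPartition-class
#' @export
setGeneric("regionCounts", function(x) standardGeneric("regionCounts"))

#' @rdname CascadeResult-class
#' @param x a CascadeResult.
#' @export
setGeneric("stageGenes", function(x) standardGeneric("stageGenes"))

#' @rdname CascadeResult-class
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))
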