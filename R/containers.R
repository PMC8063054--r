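#' Construct a CountExperiment
#'
#' @param counts integer matrix, genes x samples, with unique row and column
#'   names.
#' @param cell_type character vector, one label per sample.
#' @param study character vector, one study/batch label per sample.
#' @param meta optional extra per-sample columns (data.frame).
#' @return a [CountExperiment-class] object.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ce <- CountExperiment(m, cell_type = c("monocyte", "iMG"),
#'                       study = c("A", "A"))
#' cellType(ce)
#' @export
CountExperiment <- function(counts, cell_type, study, meta = NULL) {
    counts <- as.matrix(counts)
    if (length(cell_type) != ncol(counts) || length(study) != ncol(counts))
        stop("cell_type and study must have one entry per sample")
    cd <- S4Vectors::DataFrame(cell_type = as.character(cell_type),
                               study = as.character(study),
                               row.names = colnames(counts))
    if (!is.null(meta)) cd <- cbind(cd, S4Vectors::DataFrame(meta))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    methods::new("CountExperiment", se)
}

#' @describeIn CountExperiment counts assay accessor.
#' @param object,x a CountExperiment.
#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "CountExperiment", function(object)
    SummarizedExperiment::assay(object, "counts"))

#' @rdname CountExperiment
#' @export
setMethod("cellType", "SummarizedExperiment", function(x)
    as.character(SummarizedExperiment::colData(x)$cell_type))

#' @rdname CountExperiment
#' @export
setMethod("study", "SummarizedExperiment", function(x)
    as.character(SummarizedExperiment::colData(x)$study))

setMethod("show", "CountExperiment", function(object) {
    cat(sprintf("CountExperiment: %d genes x %d samples\n",
                nrow(object), ncol(object)))
    tab <- table(cellType(object), study(object))
    cat("samples per cell type x study:\n")
    print(tab)
    invisible(object)
})

#' Construct a NormalizedExperiment
#'
#' Usually produced by the normalization functions rather than called
#' directly. \code{entry} is appended to the parent transform log when
#' \code{from} is itself a NormalizedExperiment.
#'
#' @param values numeric matrix, genes x samples.
#' @param from the CountExperiment or NormalizedExperiment the values derive
#'   from (supplies colData and any existing transform log).
#' @param entry named list describing the transform just applied; must
#'   contain \code{name}.
#' @return a [NormalizedExperiment-class].
#' @export
NormalizedExperiment <- function(values, from, entry) {
    log0 <- if (methods::is(from, "NormalizedExperiment"))
        from@transformLog else list()
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(normalized = values),
        colData = SummarizedExperiment::colData(from))
    methods::new("NormalizedExperiment", se,
                 transformLog = c(log0, list(entry)))
}

#' @describeIn NormalizedExperiment the normalized values matrix.
#' @param object,x a NormalizedExperiment.
#' @export
normValues <- function(object) SummarizedExperiment::assay(object, "normalized")

#' @rdname NormalizedExperiment
#' @export
setMethod("transformLog", "NormalizedExperiment", function(x) x@transformLog)

setMethod("show", "NormalizedExperiment", function(object) {
    cat(sprintf("NormalizedExperiment: %d genes x %d samples\n",
                nrow(object), ncol(object)))
    cat("transforms:", paste(vapply(object@transformLog, `[[`, "", "name"),
                             collapse = " -> "), "\n")
    invisible(object)
})

#' @rdname SampleEmbedding-class
#' @export
setMethod("sampleCoordinates", "SampleEmbedding", function(x) x@coordinates)

#' @rdname SampleEmbedding-class
#' @export
setMethod("explainedVariance", "SampleEmbedding", function(x) x@explained)

setMethod("show", "SampleEmbedding", function(object) {
    cat(sprintf("SampleEmbedding (%s): %d samples, %d axes\n",
                object@method, nrow(object@coordinates),
                ncol(object@coordinates)))
    cat("explained shares:",
        paste(sprintf("%.3f", object@explained), collapse = " "), "\n")
    invisible(object)
})

#' @rdname VennPartition-class
#' @export
setMethod("regionSets", "VennPartition", function(x) x@regions)

#' @rdname VennPartition-class
#' @export
setMethod("regionCounts", "VennPartition", function(x)
    vapply(x@regions, length, integer(1)))

setMethod("show", "VennPartition", function(object) {
    cat("VennPartition of sets:",
        paste(object@setNames, collapse = ", "), "\n")
    print(regionCounts(object))
    invisible(object)
})

#' @rdname CascadeResult-class
#' @export
setMethod("stageGenes", "CascadeResult", function(x) x@stageGenes)

#' @rdname CascadeResult-class
#' @export
setMethod("stageCounts", "CascadeResult", function(x)
    vapply(x@stageGenes, length, integer(1)))

setMethod("show", "CascadeResult", function(object) {
    cat("Signature filtering cascade:\n")
    print(stageCounts(object))
    invisible(object)
})
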