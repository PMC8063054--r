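#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' CountExperiment: integer RNA-seq counts with cell-type and study annotation
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one assay
#' named \code{"counts"} (non-negative integers, genes x samples) together
#' with mandatory per-sample annotation columns \code{cell_type} and
#' \code{study}. All downstream stages of the identity-validation pipeline
#' (normalization, embedding, differential expression, the signature cascade)
#' accept this class.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @seealso [CountExperiment()] for the constructor, [cellType()], [study()].
#' @export
setClass("CountExperiment", contains = "SummarizedExperiment")

setValidity("CountExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- SummarizedExperiment::assay(object, "counts")
        if (anyNA(m) || any(!is.finite(m)))
            msg <- c(msg, "counts must be finite and non-missing")
        else {
            if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
            if (any(m != round(m))) msg <- c(msg, "counts must be integers")
        }
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, dup_msg("gene", rownames(object)))
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, dup_msg("sample", colnames(object)))
    for (col in c("cell_type", "study"))
        if (!col %in% colnames(SummarizedExperiment::colData(object)))
            msg <- c(msg, sprintf("colData column '%s' is required", col))
    if (length(msg)) msg else TRUE
})

dup_msg <- function(what, ids) {
    if (is.null(ids)) return(sprintf("%s ids (dimnames) are required", what))
    d <- unique(ids[duplicated(ids)])
    sprintf("duplicate %s ids: %s", what, paste(d, collapse = ", "))
}

#' NormalizedExperiment: real-valued expression with a transform log
#'
#' Extends \linkS4class{SummarizedExperiment} with an append-only record of
#' the transforms applied (size-factor normalization, FPKM, log, VST,
#' batch removal, unit rescaling), each entry a named list with at least a
#' \code{name} element and any parameters used. The single assay is named
#' \code{"normalized"}.
#'
#' @slot transformLog list of applied transforms, in order of application.
#' @export
setClass("NormalizedExperiment",
    contains = "SummarizedExperiment",
    representation(transformLog = "list"))

setValidity("NormalizedExperiment", function(object) {
    msg <- character()
    m <- SummarizedExperiment::assay(object)
    if (anyNA(m) || any(!is.finite(m)))
        msg <- c(msg, "normalized values must be finite")
    if (length(object@transformLog) == 0L)
        msg <- c(msg, "transformLog must record at least one transform")
    if (!all(vapply(object@transformLog,
                    function(e) is.list(e) && !is.null(e$name), logical(1))))
        msg <- c(msg, "every transformLog entry needs a 'name'")
    if (length(msg)) msg else TRUE
})

#' SampleEmbedding: low-dimensional sample coordinates
#'
#' Result container for [pcaEmbedding()] and [classicalMDS()]. Coordinates
#' are samples x k with sample ids as rownames; \code{explained} carries the
#' per-axis eigenvalue (or variance) shares, sorted non-increasing.
#'
#' @slot coordinates numeric matrix, samples x k.
#' @slot explained non-negative numeric, one share per axis.
#' @slot method "pca" or "cmds".
#' @slot extra list of method-specific diagnostics (e.g. negative MDS
#'   eigenvalues, which are reported but never used for coordinates).
#' @export
setClass("SampleEmbedding", representation(
    coordinates = "matrix",
    explained   = "numeric",
    method      = "character",
    extra       = "list"))

setValidity("SampleEmbedding", function(object) {
    msg <- character()
    if (!object@method %in% c("pca", "cmds"))
        msg <- c(msg, "method must be 'pca' or 'cmds'")
    if (ncol(object@coordinates) < 1L)
        msg <- c(msg, "at least one axis required")
    if (any(!is.finite(object@coordinates)))
        msg <- c(msg, "coordinates must be finite")
    if (is.unsorted(rev(object@explained)))
        msg <- c(msg, "explained shares must be non-increasing")
    if (any(object@explained < -1e-12))
        msg <- c(msg, "explained shares must be non-negative")
    if (length(object@explained) != ncol(object@coordinates))
        msg <- c(msg, "one explained share per axis required")
    if (length(msg)) msg else TRUE
})

#' VennPartition: disjoint 7-region partition of three gene sets
#'
#' @slot regions named list of character vectors for the regions
#'   \code{A_only, B_only, C_only, AB, AC, BC, ABC}.
#' @slot setNames the names of sets A, B and C, in order.
#' @export
setClass("VennPartition", representation(
    regions  = "list",
    setNames = "character"))

.venn_region_names <- c("A_only", "B_only", "C_only", "AB", "AC", "BC", "ABC")

setValidity("VennPartition", function(object) {
    msg <- character()
    if (!identical(names(object@regions), .venn_region_names))
        msg <- c(msg, "regions must be named A_only,...,ABC in order")
    all_genes <- unlist(object@regions, use.names = FALSE)
    if (anyDuplicated(all_genes))
        msg <- c(msg, "regions must be pairwise disjoint")
    if (length(object@setNames) != 3L)
        msg <- c(msg, "exactly three set names required")
    if (length(msg)) msg else TRUE
})

#' CascadeResult: signature-gene filtering cascade output
#'
#' Records, for each stage of the signature cascade
#' (\code{signature_union}, \code{overlap_with_data}, \code{consistent},
#' \code{de_filtered}), the surviving gene set and its size, plus the
#' thresholds used and the per-gene consistency table.
#'
#' @slot stageGenes named list of character vectors, one per stage, in order.
#' @slot params named list of thresholds (fc_cut, p_cut, expr_cut, cons_cut,
#'   fold-change scale).
#' @slot consistency data.frame with columns gene, x, y, score.
#' @export
setClass("CascadeResult", representation(
    stageGenes  = "list",
    params      = "list",
    consistency = "data.frame"))

setValidity("CascadeResult", function(object) {
    msg <- character()
    st <- object@stageGenes
    if (length(st) < 2L) msg <- c(msg, "at least two stages required")
    # subset chain holds from the overlap stage onward
    for (i in seq_along(st)[-(1:2)])
        if (!all(st[[i]] %in% st[[i - 1L]]))
            msg <- c(msg, sprintf("stage '%s' is not a subset of '%s'",
                                  names(st)[i], names(st)[i - 1L]))
    if (length(msg)) msg else TRUE
})
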