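#' Gene list container
#'
#' A named set of gene symbols. Symbols are trimmed and deduplicated
#' case-insensitively (first spelling kept); an empty result is an error.
#'
#' @param name list name.
#' @param symbols character vector of gene symbols.
#' @return object of class \code{GeneList} with elements name, symbols.
#' @export
geneList <- function(name, symbols) {
    symbols <- trimws(as.character(symbols))
    symbols <- symbols[nzchar(symbols)]
    symbols <- symbols[!duplicated(normalize_symbols(symbols))]
    if (!length(symbols))
        stop("gene list '", name, "' is empty after normalization")
    structure(list(name = name, symbols = symbols), class = "GeneList")
}

#' @export
print.GeneList <- function(x, ...) {
    cat(sprintf("GeneList '%s': %d symbols\n", x$name, length(x$symbols)))
    invisible(x)
}

#' Read a one-symbol-per-line gene list
#'
#' @param path text file, one symbol per line; blank lines and lines
#'   starting with '#' are ignored.
#' @param name list name (defaults to the file name).
#' @return a \code{GeneList}.
#' @export
readGeneList <- function(path, name = basename(path)) {
    if (!file.exists(path)) stop("gene list file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    geneList(name, lines)
}

#' @rdname readGeneList
#' @param x a GeneList to write.
#' @export
writeGeneList <- function(x, path) {
    writeLines(x$symbols, path)
    invisible(path)
}

#' Union of gene lists
#'
#' Deduplicated union under the same case-insensitive symbol normalization
#' used for cross-dataset merging, so e.g. \{A, B\} and \{b, C\} union to
#' three symbols. Used to assemble a non-overlapping signature set from
#' several published microglial gene lists.
#'
#' @param lists a list of \code{GeneList} objects (>= 1).
#' @param name name for the union.
#' @return a \code{GeneList}.
#' @export
unionGeneLists <- function(lists, name = "union") {
    if (!length(lists)) stop("at least one gene list is required")
    geneList(name, unlist(lapply(lists, `[[`, "symbols"), use.names = FALSE))
}

#' Read a gene-by-sample count matrix with sample metadata
#'
#' The counts file is tab-delimited with a header row of sample ids and
#' gene ids in the first column; the metadata file is tab-delimited with
#' columns \code{sample_id}, \code{cell_type}, \code{study}. Non-integer or
#' negative cells, duplicated ids, and samples missing from the metadata
#' are rejected with informative errors.
#'
#' @param path counts TSV.
#' @param meta_path sample metadata TSV.
#' @return a [CountExperiment-class].
#' @export
readCounts <- function(path, meta_path) {
    for (p in c(path, meta_path))
        if (!file.exists(p)) stop("file not found: ", p)
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    gene_ids <- trimws(as.character(tab[[1]]))
    if (anyDuplicated(gene_ids))
        stop("duplicate gene ids in ", path, ": ",
             paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (anyDuplicated(colnames(m)))
        stop("duplicate sample ids in ", path, ": ",
             paste(unique(colnames(m)[duplicated(colnames(m))]),
                   collapse = ", "))
    if (!is.numeric(m) || anyNA(m) || any(m != round(m)) || any(m < 0))
        stop("counts must be non-negative integers: ", path)
    storage.mode(m) <- "integer"
    rownames(m) <- gene_ids
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
    need <- c("sample_id", "cell_type", "study")
    if (!all(need %in% colnames(meta)))
        stop("metadata must have columns: ", paste(need, collapse = ", "))
    missing <- setdiff(colnames(m), meta$sample_id)
    if (length(missing))
        stop("samples missing from metadata: ",
             paste(missing, collapse = ", "))
    meta <- meta[match(colnames(m), meta$sample_id), ]
    CountExperiment(m, cell_type = meta$cell_type, study = meta$study)
}

#' @rdname readCounts
#' @param m a CountExperiment to write.
#' @param prefix output path prefix; writes \code{<prefix>_counts.tsv} and
#'   \code{<prefix>_meta.tsv}.
#' @return invisibly, the two paths written.
#' @export
writeCounts <- function(m, prefix) {
    k <- SummarizedExperiment::assay(m, "counts")
    cp <- paste0(prefix, "_counts.tsv")
    mp <- paste0(prefix, "_meta.tsv")
    utils::write.table(data.frame(gene_id = rownames(k), k,
                                  check.names = FALSE),
                       cp, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(sample_id = colnames(k),
                                  cell_type = cellType(m),
                                  study = study(m)),
                       mp, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(counts = cp, meta = mp))
}

#' Read counts from MatrixMarket triplet format
#'
#' Alternative input path: an MTX coordinate file with sidecar
#' one-id-per-line gene and sample lists, plus the same metadata TSV as
#' [readCounts()].
#'
#' @param mtx_path MatrixMarket file.
#' @param genes_path,samples_path sidecar id lists (row ids, column ids).
#' @param meta_path sample metadata TSV.
#' @return a [CountExperiment-class].
#' @export
readCountsMTX <- function(mtx_path, genes_path, samples_path, meta_path) {
    m <- as.matrix(Matrix::readMM(mtx_path))
    rownames(m) <- readLines(genes_path, warn = FALSE)
    colnames(m) <- readLines(samples_path, warn = FALSE)
    storage.mode(m) <- "integer"
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
    meta <- meta[match(colnames(m), meta$sample_id), ]
    if (anyNA(meta$sample_id))
        stop("samples missing from metadata: ",
             paste(setdiff(colnames(m), meta$sample_id), collapse = ", "))
    CountExperiment(m, cell_type = meta$cell_type, study = meta$study)
}

#' Read a gene-length table
#'
#' @param path TSV with columns \code{gene_id}, \code{length} (bp).
#' @return named numeric vector of lengths.
#' @export
readGeneLengths <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (any(tab$length <= 0)) stop("gene lengths must be positive")
    stats::setNames(as.numeric(tab$length), tab$gene_id)
}

#' Read / write a qPCR CT table
#'
#' @param path TSV with columns condition, replicate, gene, ct.
#' @return data.frame.
#' @export
readCtTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("condition", "replicate", "gene", "ct")
    if (!all(need %in% colnames(tab)))
        stop("CT table must have columns: ", paste(need, collapse = ", "))
    tab
}

#' @rdname readCtTable
#' @param x CT table to write.
#' @export
writeCtTable <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Merge two count datasets on shared gene symbols
#'
#' Restricts both matrices to the intersection of their gene symbols
#' (case-insensitive, whitespace-trimmed — the convention used when merging
#' expression studies on bare symbols) and concatenates samples. Study and
#' cell-type labels are preserved. The merged gene ids take the spelling of
#' the first dataset.
#'
#' @param a,b [CountExperiment-class] objects.
#' @return a [CountExperiment-class] over the shared genes.
#' @export
mergeDatasets <- function(a, b) {
    na <- normalize_symbols(rownames(a))
    nb <- normalize_symbols(rownames(b))
    shared <- intersect(na, nb)
    if (!length(shared))
        stop("no shared gene symbols between the datasets; check that both ",
             "use the same identifier system (symbols, not e.g. Ensembl ids)")
    ia <- match(shared, na)
    ib <- match(shared, nb)
    ka <- SummarizedExperiment::assay(a, "counts")[ia, , drop = FALSE]
    kb <- SummarizedExperiment::assay(b, "counts")[ib, , drop = FALSE]
    rownames(kb) <- rownames(ka)
    CountExperiment(cbind(ka, kb),
                    cell_type = c(cellType(a), cellType(b)),
                    study = c(study(a), study(b)))
}
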