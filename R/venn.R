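#' Genes expressed in a cell type
#'
#' A gene is called expressed in a cell type when its mean normalized count
#' over that cell type's samples strictly exceeds the cutoff (default 10);
#' a gene with mean exactly at the cutoff is excluded. Normalized counts
#' are on the size-factor scale, the same scale as the DE base mean.
#'
#' @param m a [NormalizedExperiment-class] (size-factor normalized).
#' @param cell_type label to evaluate.
#' @param cutoff presence threshold on the mean normalized count
#'   (default 10, strict \code{>}).
#' @return character vector of gene ids.
#' @export
expressedGenes <- function(m, cell_type, cutoff = 10) {
    ct <- cellType(m)
    if (!cell_type %in% ct)
        stop("unknown cell type: ", cell_type)
    v <- normValues(m)
    mu <- rowMeans(v[, ct == cell_type, drop = FALSE])
    rownames(v)[mu > cutoff]
}

#' Three-set Venn partition
#'
#' Partitions the union of three gene sets into the seven disjoint regions
#' of a three-set Venn diagram (unique to each set, each pairwise-only
#' intersection, and the triple intersection).
#'
#' @param a,b,c character vectors (gene sets).
#' @param set_names names of the three sets.
#' @return a [VennPartition-class].
#' @examples
#' vp <- vennPartition(c("g1", "g2", "g3"), c("g2", "g3", "g4"),
#'                     c("g3", "g5"))
#' regionCounts(vp)
#' @export
vennPartition <- function(a, b, c, set_names = c("A", "B", "C")) {
    a <- unique(a); b <- unique(b); c <- unique(c)
    universe <- union(union(a, b), c)
    ina <- universe %in% a
    inb <- universe %in% b
    inc <- universe %in% c
    regions <- list(
        A_only = universe[ina & !inb & !inc],
        B_only = universe[!ina & inb & !inc],
        C_only = universe[!ina & !inb & inc],
        AB     = universe[ina & inb & !inc],
        AC     = universe[ina & !inb & inc],
        BC     = universe[!ina & inb & inc],
        ABC    = universe[ina & inb & inc])
    methods::new("VennPartition", regions = regions, setNames = set_names)
}
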