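# Sign convention shared by PCA and MDS axes: flip each axis so the
# coordinate with the largest magnitude is positive, making output
# reproducible across LAPACK implementations.
fix_axis_signs <- function(coords) {
    for (j in seq_len(ncol(coords))) {
        i <- which.max(abs(coords[, j]))
        if (length(i) && coords[i, j] < 0) coords[, j] <- -coords[, j]
    }
    coords
}

as_values <- function(m) {
    if (methods::is(m, "NormalizedExperiment")) normValues(m)
    else if (methods::is(m, "SummarizedExperiment"))
        SummarizedExperiment::assay(m)
    else as.matrix(m)
}

#' Pairwise sample distances
#'
#' Euclidean (default, the heatmap/MDS convention of the toolchain this
#' pipeline mirrors) or correlation distance (1 - Pearson) between the
#' columns of a normalized expression matrix.
#'
#' @param m a [NormalizedExperiment-class] or genes x samples matrix.
#' @param metric "euclidean" or "correlation".
#' @return a symmetric samples x samples matrix with zero diagonal.
#' @export
sampleDistances <- function(m, metric = c("euclidean", "correlation")) {
    metric <- match.arg(metric)
    v <- as_values(m)
    d <- switch(metric,
        euclidean   = as.matrix(stats::dist(t(v))),
        correlation = 1 - stats::cor(v))
    diag(d) <- 0
    d
}

check_distance_matrix <- function(d) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12)
        stop("distance matrix must be symmetric")
    if (any(diag(d) != 0)) stop("distance matrix must have zero diagonal")
    if (any(d < 0)) stop("distances must be non-negative")
    d
}

#' Principal component analysis of samples
#'
#' Singular value decomposition of the gene-centered matrix; sample scores
#' with eigenvalue (variance) shares per axis. Axis signs follow the
#' package-wide largest-coordinate-positive convention.
#'
#' @param m a [NormalizedExperiment-class] or genes x samples matrix.
#' @param k number of components (<= min(genes, samples - 1)).
#' @return a [SampleEmbedding-class] with method "pca".
#' @export
pcaEmbedding <- function(m, k = 2L) {
    v <- as_values(m)
    n <- ncol(v)
    if (n < 2L) stop("at least two samples are required")
    kmax <- min(nrow(v), n - 1L)
    if (k > kmax)
        stop(sprintf("k = %d exceeds the maximum rank %d", k, kmax))
    p <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
    ev <- p$sdev^2
    coords <- fix_axis_signs(p$x[, seq_len(k), drop = FALSE])
    rownames(coords) <- colnames(v)
    methods::new("SampleEmbedding", coordinates = coords,
                 explained = ev[seq_len(k)] / sum(ev),
                 method = "pca", extra = list(all_eigenvalues = ev))
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix and embeds samples on the
#' top-k non-negative eigenpairs, coordinates scaled by the square root of
#' each eigenvalue (the \code{cmdscale} construction). Negative eigenvalues
#' — which arise for non-Euclidean distances — are reported in the result's
#' \code{extra} slot and never used for coordinates.
#'
#' @param d symmetric distance matrix or \code{dist} object.
#' @param k number of axes (<= n - 1). If fewer positive eigenvalues exist,
#'   the embedding has fewer axes.
#' @return a [SampleEmbedding-class] with method "cmds".
#' @export
classicalMDS <- function(d, k = 2L) {
    d <- check_distance_matrix(d)
    n <- nrow(d)
    if (k > n - 1L) stop(sprintf("k = %d exceeds n - 1 = %d", k, n - 1L))
    if (all(d == 0)) {
        coords <- matrix(0, n, k, dimnames = list(rownames(d), NULL))
        return(methods::new("SampleEmbedding", coordinates = coords,
                            explained = rep(0, k), method = "cmds",
                            extra = list(eigenvalues = rep(0, n))))
    }
    fit <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE)
    if (max(fit$eig) <= 0)
        stop("degenerate geometry: no positive eigenvalue; the distances ",
             "admit no Euclidean embedding")
    pos <- sum(fit$eig > 1e-12 * max(fit$eig))
    keep <- seq_len(min(k, pos, ncol(fit$points)))
    coords <- fix_axis_signs(fit$points[, keep, drop = FALSE])
    rownames(coords) <- rownames(d)
    methods::new("SampleEmbedding", coordinates = coords,
                 explained = fit$eig[keep] / sum(pmax(fit$eig, 0)),
                 method = "cmds",
                 extra = list(eigenvalues = fit$eig,
                              negative_eigenvalues = fit$eig[fit$eig < 0]))
}

#' Agglomerative hierarchical clustering of samples
#'
#' Standard agglomerative merge history via \code{stats::hclust};
#' complete, average or single linkage.
#'
#' @param d symmetric distance matrix or \code{dist}.
#' @param linkage "complete", "average" or "single".
#' @return an \code{hclust} object (merge history, heights, labels).
#' @export
hierarchicalCluster <- function(d,
        linkage = c("complete", "average", "single")) {
    linkage <- match.arg(linkage)
    d <- check_distance_matrix(d)
    if (nrow(d) < 2L) stop("at least two samples are required")
    stats::hclust(stats::as.dist(d), method = linkage)
}

#' Cluster purity against known classes
#'
#' Cuts the dendrogram into k clusters and scores the fraction of samples
#' whose cluster's majority class matches their own label — a quantitative
#' version of "cell type X clusters with cell type Y" statements.
#'
#' @param dendro an \code{hclust} from [hierarchicalCluster()].
#' @param labels per-sample class labels, in the order of
#'   \code{dendro$labels} (or named by sample id).
#' @param k number of clusters (<= number of samples).
#' @return purity in \[0, 1\].
#' @export
clusterPurity <- function(dendro, labels, k) {
    n <- length(dendro$labels %||% dendro$order)
    if (k > n) stop(sprintf("k = %d exceeds the %d samples", k, n))
    if (!is.null(names(labels)) && !is.null(dendro$labels))
        labels <- labels[dendro$labels]
    cl <- stats::cutree(dendro, k = k)
    sum(tapply(labels, cl, function(x) max(table(x)))) / length(labels)
}

#' Nearest reference centroid per query sample
#'
#' In an embedding, computes the centroid of each reference cell type and
#' reports, for each query-type sample, which reference centroid is
#' nearest — e.g. whether induced microglia-like samples land nearer the
#' reference microglia than the reference monocytes.
#'
#' @param emb a [SampleEmbedding-class].
#' @param cell_types per-sample labels named by sample id (or in embedding
#'   row order).
#' @param query cell-type label of the query samples.
#' @param refs cell-type labels of the candidate reference populations.
#' @return list with \code{per_sample} (named character: nearest reference
#'   for each query sample) and \code{majority} (single label).
#' @export
nearestReferenceCentroid <- function(emb, cell_types, query, refs) {
    x <- sampleCoordinates(emb)
    if (!is.null(names(cell_types))) cell_types <- cell_types[rownames(x)]
    if (!query %in% cell_types) stop("no samples of query type ", query)
    if (!all(refs %in% cell_types))
        stop("missing reference type(s): ",
             paste(setdiff(refs, cell_types), collapse = ", "))
    centroids <- t(sapply(refs, function(r)
        colMeans(x[cell_types == r, , drop = FALSE])))
    q <- x[cell_types == query, , drop = FALSE]
    nearest <- apply(q, 1, function(p)
        refs[which.min(colSums((t(centroids) - p)^2))])
    list(per_sample = nearest,
         majority = names(sort(table(nearest), decreasing = TRUE))[1])
}
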