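#' Median-of-ratios size factors
#'
#' Per-sample scaling constants computed the way negative-binomial
#' differential-expression tools define library-size normalization: for each
#' sample, the median over reference-eligible genes (those with no zero
#' count in any sample) of the ratio count / geometric mean across samples.
#' This estimator is robust to a minority of strongly differential genes,
#' which is why it is preferred over total-count scaling when downstream
#' thresholds are expressed on the normalized-count scale.
#'
#' @param m a [CountExperiment-class] or counts matrix.
#' @return named numeric vector of positive factors, one per sample.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), 3,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' computeSizeFactors(m)  # c(1, 2) / sqrt(2)
#' @export
computeSizeFactors <- function(m) {
    k <- if (methods::is(m, "SummarizedExperiment"))
        SummarizedExperiment::assay(m, "counts") else as.matrix(m)
    eligible <- rowSums(k == 0) == 0L
    if (!any(eligible))
        stop("no gene has all-positive counts; median-of-ratios is ",
             "undefined — consider total-count ratio normalization instead")
    lg <- log(k[eligible, , drop = FALSE])
    log_geo <- rowMeans(lg)
    f <- apply(lg, 2, function(col) exp(stats::median(col - log_geo)))
    stats::setNames(f, colnames(k))
}

#' Divide counts by size factors
#'
#' @param m a [CountExperiment-class].
#' @param f named size factors covering every sample (defaults to
#'   [computeSizeFactors()] of \code{m}).
#' @return a [NormalizedExperiment-class] with transform "size_factor".
#' @export
normalizeCounts <- function(m, f = computeSizeFactors(m)) {
    k <- SummarizedExperiment::assay(m, "counts")
    missing <- setdiff(colnames(k), names(f))
    if (length(missing))
        stop("no size factor for sample(s): ", paste(missing, collapse = ", "))
    v <- sweep(k, 2, f[colnames(k)], `/`)
    NormalizedExperiment(v, m,
        list(name = "size_factor", factors = as.list(f[colnames(k)])))
}

#' Fragments per kilobase per million mapped reads
#'
#' \eqn{FPKM_{gs} = 10^9 \, k_{gs} / (L_g \, N_s)} with \eqn{L_g} the gene
#' length in bp and \eqn{N_s} the column total. Depth- and length-normalized;
#' scaling a whole column leaves its FPKM unchanged.
#'
#' @param m a [CountExperiment-class].
#' @param lengths named numeric vector or two-column data.frame
#'   (gene, length) of transcript lengths in bp; every gene needs a length.
#' @return a [NormalizedExperiment-class] with transform "fpkm".
#' @export
fpkm <- function(m, lengths) {
    if (is.data.frame(lengths))
        lengths <- stats::setNames(lengths[[2]], lengths[[1]])
    k <- SummarizedExperiment::assay(m, "counts")
    missing <- setdiff(rownames(k), names(lengths))
    if (length(missing))
        stop("no length for gene(s): ", paste(missing, collapse = ", "))
    len <- lengths[rownames(k)]
    if (any(len <= 0)) stop("gene lengths must be positive")
    v <- 1e9 * sweep(k / len, 2, colSums(k), `/`)
    NormalizedExperiment(v, m, list(name = "fpkm"))
}

#' Closed-form variance-stabilizing transform
#'
#' Applies the variance-stabilizing transform for the negative-binomial
#' variance function \eqn{v(\mu) = \mu + \alpha \mu^2} with a single pooled
#' dispersion: size-factor-normalized counts \eqn{x} are mapped to
#' \deqn{vst(x) = \frac{2}{\ln 2}\,\mathrm{asinh}(\sqrt{\alpha x}) -
#'   \log_2(4\alpha),}
#' which is monotone, flattens the mean-variance relationship, and is
#' affinely calibrated so that \eqn{vst(x) \to \log_2 x} for large counts.
#' A per-gene dispersion trend (as full DE toolchains fit) is deliberately
#' not used: the pooled form preserves the monotonicity and
#' variance-flattening that clustering and embedding rely on.
#'
#' @param m a [CountExperiment-class].
#' @param dispersion pooled NB dispersion alpha (> 0).
#' @param f size factors (defaults to median-of-ratios of \code{m}).
#' @return a [NormalizedExperiment-class] with transform "vst".
#' @export
vstTransform <- function(m, dispersion = 0.1, f = computeSizeFactors(m)) {
    if (!is.finite(dispersion) || dispersion <= 0)
        stop("dispersion must be positive")
    x <- normValues(normalizeCounts(m, f))
    v <- (2 / log(2)) * asinh(sqrt(dispersion * x)) - log2(4 * dispersion)
    NormalizedExperiment(v, m,
        list(name = "vst", dispersion = dispersion,
             factors = as.list(f[colnames(x)])))
}

# raw asinh branch (0 at x = 0), exposed for tests of the fixed point
vst_raw <- function(x, dispersion) (2 / log(2)) * asinh(sqrt(dispersion * x))

#' Log2 transform with pseudocount
#'
#' \code{log2(x + pseudocount)} on normalized values; the conventional
#' log-transformation when none more specific is requested.
#'
#' @param m a [NormalizedExperiment-class] or [CountExperiment-class].
#' @param pseudocount added before the log (default 1).
#' @return a [NormalizedExperiment-class] with transform "log2".
#' @export
logTransform <- function(m, pseudocount = 1) {
    v <- if (methods::is(m, "NormalizedExperiment")) normValues(m)
         else SummarizedExperiment::assay(m, "counts")
    NormalizedExperiment(log2(v + pseudocount), m,
        list(name = "log2", pseudocount = pseudocount))
}

#' Remove additive batch effects from log-scale expression
#'
#' Per-gene linear model of expression on condition plus batch; the fitted
#' batch coefficients are subtracted so that condition structure is
#' preserved while study-of-origin shifts are removed. The fit is delegated
#' to \code{limma::removeBatchEffect}, the standard tool for this model.
#' Values must already be on a log-like scale (log2, VST, log-FPKM).
#'
#' @param m a [NormalizedExperiment-class].
#' @param batches per-sample batch labels (defaults to the study column).
#' @param keep per-sample condition labels to protect (defaults to the
#'   cell_type column); set \code{NULL} to fit batch only.
#' @return a [NormalizedExperiment-class] with transform "batch_removed".
#' @export
correctBatchEffect <- function(m, batches = study(m), keep = cellType(m)) {
    v <- normValues(m)
    if (length(batches) != ncol(v))
        stop("one batch label per sample is required")
    batches <- factor(batches)
    if (nlevels(batches) < 2L)
        return(NormalizedExperiment(v, m,
            list(name = "batch_removed", batches = levels(batches))))
    if (!is.null(keep)) {
        keep <- factor(keep)
        design <- stats::model.matrix(~keep)
        full <- cbind(design, stats::model.matrix(~batches)[, -1, drop = FALSE])
        if (qr(full)$rank < ncol(full))
            stop("batch is confounded with the protected condition (",
                 paste(levels(keep), collapse = "/"),
                 "); the batch coefficients are not estimable")
    } else design <- matrix(1, ncol(v), 1)
    out <- limma::removeBatchEffect(v, batch = batches, design = design)
    # recenter so each gene's grand mean is exactly preserved even when
    # batch sizes are unbalanced (sum-to-zero contrasts only guarantee it
    # across batch levels, not across samples)
    out <- out + (rowMeans(v) - rowMeans(out))
    NormalizedExperiment(out, m,
        list(name = "batch_removed", batches = levels(batches),
             protected = !is.null(keep)))
}

#' Per-gene min-max rescaling to the unit interval
#'
#' Affine map of each gene to min 0, max 1; a constant gene maps to 0 by
#' convention (documented here because boundary behavior is the only
#' ambiguity of min-max rescaling).
#'
#' @param m a [NormalizedExperiment-class].
#' @return a [NormalizedExperiment-class] with transform "rescale01".
#' @export
rescaleUnitInterval <- function(m) {
    v <- normValues(m)
    rng <- cbind(apply(v, 1, min), apply(v, 1, max))
    span <- rng[, 2] - rng[, 1]
    out <- (v - rng[, 1]) / ifelse(span > 0, span, 1)
    out[span == 0, ] <- 0
    NormalizedExperiment(out, m, list(name = "rescale01"))
}
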