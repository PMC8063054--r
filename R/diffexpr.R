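# Two-group negative-binomial differential expression.
#
# Parameterization matches the simulator: variance = mu + alpha * mu^2.
# All statistics are computed from size-factor-normalized counts, so the
# whole test is exactly invariant to rescaling a sample's counts together
# with its size factor.

.alpha_floor <- 1e-8

#' Per-gene NB dispersion by method of moments with decile-trend shrinkage
#'
#' For each gene, the raw dispersion is the method-of-moments estimate from
#' within-group means and variances of size-factor-normalized counts,
#' \eqn{\hat\alpha = (v - \bar m)/\bar m^2} with \eqn{v} the pooled
#' within-group variance, floored at 1e-8. Raw estimates are then shrunk
#' 50/50 toward the mean raw dispersion of the gene's expression decile — a
#' deliberately simple stand-in for the empirical-Bayes dispersion trends of
#' full DE toolchains, sufficient to stabilize the small-sample Wald test.
#'
#' @param m a [CountExperiment-class].
#' @param groups two-level per-sample labels (factor or character).
#' @param f size factors (defaults to median-of-ratios).
#' @return named numeric vector of per-gene dispersions (>= 1e-8).
#' @export
estimateDispersion <- function(m, groups, f = computeSizeFactors(m)) {
    x <- normValues(normalizeCounts(m, f))
    g <- factor(groups)
    if (nlevels(g) != 2L) stop("exactly two group levels are required")
    n <- table(g)
    if (any(n < 2L))
        stop("each group needs >= 2 samples; got ",
             paste(sprintf("%s=%d", names(n), n), collapse = ", "))
    i1 <- g == levels(g)[1]
    m1 <- rowMeans(x[, i1, drop = FALSE])
    m2 <- rowMeans(x[, !i1, drop = FALSE])
    v1 <- apply(x[, i1, drop = FALSE], 1, stats::var)
    v2 <- apply(x[, !i1, drop = FALSE], 1, stats::var)
    vp <- ((n[1] - 1) * v1 + (n[2] - 1) * v2) / (sum(n) - 2)
    mbar <- (n[1] * m1 + n[2] * m2) / sum(n)
    raw <- ifelse(mbar > 0, (vp - mbar) / mbar^2, .alpha_floor)
    raw <- pmax(raw, .alpha_floor)
    # decile trend on mean expression
    dec <- cut(rank(mbar, ties.method = "first"),
               breaks = 10, labels = FALSE)
    trend <- tapply(raw, dec, mean)[as.character(dec)]
    alpha <- pmax(0.5 * raw + 0.5 * as.numeric(trend), .alpha_floor)
    stats::setNames(alpha, rownames(x))
}

#' Negative-binomial Wald test between two groups
#'
#' Per-gene group means of size-factor-normalized counts under an NB model
#' with fixed per-gene dispersion; the Wald statistic is
#' \eqn{\log_2 FC / SE} with the standard error from the NB Fisher
#' information \eqn{n\,q/(1 + \alpha q)} per group, two-sided p-values from
#' the normal reference and Benjamini-Hochberg adjustment. No fold-change
#' shrinkage is applied. Genes with zero counts in every sample are dropped
#' before testing and listed in the \code{"dropped"} attribute; a group with
#' all-zero counts is floored at half a normalized count so fold changes
#' stay finite.
#'
#' The second factor level is the numerator: \code{log2fc > 0} means higher
#' expression in \code{levels(factor(groups))[2]}.
#'
#' @param m a [CountExperiment-class].
#' @param groups two-level per-sample labels.
#' @param f size factors.
#' @param alpha per-gene dispersions (defaults to [estimateDispersion()]).
#' @return data.frame (one row per tested gene): gene, base_mean, log2fc,
#'   se, wald_p, adj_p.
#' @export
nbWaldTest <- function(m, groups, f = computeSizeFactors(m),
                       alpha = estimateDispersion(m, groups, f)) {
    x <- normValues(normalizeCounts(m, f))
    g <- factor(groups)
    if (nlevels(g) != 2L) stop("exactly two group levels are required")
    keep <- rowSums(x) > 0
    dropped <- rownames(x)[!keep]
    x <- x[keep, , drop = FALSE]
    a <- alpha[rownames(x)]
    i2 <- g == levels(g)[2]
    n1 <- sum(!i2); n2 <- sum(i2)
    q_floor <- 0.5
    q1 <- pmax(rowMeans(x[, !i2, drop = FALSE]), q_floor)
    q2 <- pmax(rowMeans(x[, i2, drop = FALSE]), q_floor)
    log2fc <- log2(q2) - log2(q1)
    # Var(ln q_hat) = (1 + alpha q)/(n q) from the NB Fisher information
    se <- sqrt((1 + a * q1) / (n1 * q1) +
               (1 + a * q2) / (n2 * q2)) / log(2)
    z <- log2fc / se
    wald_p <- 2 * stats::pnorm(-abs(z))
    res <- data.frame(gene = rownames(x),
                      base_mean = rowMeans(x),
                      log2fc = log2fc, se = se,
                      wald_p = wald_p,
                      adj_p = stats::p.adjust(wald_p, method = "BH"),
                      row.names = NULL)
    attr(res, "dropped") <- dropped
    attr(res, "numerator") <- levels(g)[2]
    res
}

#' Volcano-plot significance classification
#'
#' Flags genes passing both thresholds with strict inequalities:
#' \code{p < p_cut} and \code{|log2fc| > lfc_cut}. A gene sitting exactly on
#' either boundary is not significant. By default the FDR-adjusted p-value
#' is thresholded; set \code{use_adjusted = FALSE} for raw Wald p.
#'
#' @param de a DEResult data.frame from [nbWaldTest()].
#' @param p_cut p-value threshold (default 1e-16).
#' @param lfc_cut absolute log2 fold-change threshold (default 2).
#' @param use_adjusted threshold adj_p (default) or wald_p.
#' @return the input with a logical \code{significant} column; thresholds in
#'   attributes.
#' @export
volcanoClassify <- function(de, p_cut = 1e-16, lfc_cut = 2,
                            use_adjusted = TRUE) {
    p <- if (use_adjusted) de$adj_p else de$wald_p
    de$significant <- p < p_cut & abs(de$log2fc) > lfc_cut
    attr(de, "thresholds") <- list(p_cut = p_cut, lfc_cut = lfc_cut,
                                   use_adjusted = use_adjusted)
    de
}
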