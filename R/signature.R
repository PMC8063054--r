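#' Cross-dataset fold-change consistency score
#'
#' The score \deqn{s(x, y) = \frac{2xy}{\sqrt{x^2 + y^2}}} compares a gene's
#' fold change \code{x} (monocyte to microglia-like, test dataset) with its
#' fold change \code{y} (monocyte to microglia, reference dataset):
#' same-sign large fold changes score high, opposite signs score negative,
#' and \eqn{s(x, x) = \sqrt{2}\,|x|\,\mathrm{sign}(x)}. The score is 0 at
#' the origin by convention, symmetric in its arguments, and scales
#' linearly: \eqn{s(cx, cy) = c\,s(x, y)} for \eqn{c > 0}.
#'
#' @param x,y finite numeric vectors (recycled), fold changes in the two
#'   datasets.
#' @return numeric vector of scores.
#' @examples
#' consistencyScore(1, 1)    # sqrt(2)
#' consistencyScore(3, -1)   # -6/sqrt(10)
#' @export
consistencyScore <- function(x, y) {
    if (any(!is.finite(x)) || any(!is.finite(y)))
        stop("fold changes must be finite")
    r <- sqrt(x^2 + y^2)
    ifelse(r == 0, 0, 2 * x * y / r)
}

#' Select consistent genes by score cutoff
#'
#' Genes whose consistency score strictly exceeds the cutoff (default 0.50;
#' a gene scoring exactly 0.50 is excluded). Because
#' \eqn{s(x,x) = \sqrt{2}x}, no gene with same-sign fold changes both below
#' \eqn{0.50/\sqrt 2 \approx 0.354} can pass the default cutoff.
#'
#' @param records data.frame with columns gene, x, y (score added if
#'   absent).
#' @param cutoff score threshold, strict inequality (default 0.50).
#' @return character vector of gene ids.
#' @export
consistentGenes <- function(records, cutoff = 0.50) {
    if (is.null(records$score))
        records$score <- consistencyScore(records$x, records$y)
    records$gene[records$score > cutoff]
}

# log2 fold change between two cell types from size-factor-normalized group
# means, pseudocount 1 to protect zero groups
group_log2fc <- function(m, query, baseline, f = computeSizeFactors(m)) {
    ct <- cellType(m)
    for (lab in c(query, baseline))
        if (!lab %in% ct)
            stop("cell type '", lab, "' absent from the dataset")
    x <- normValues(normalizeCounts(m, f))
    log2(rowMeans(x[, ct == query, drop = FALSE]) + 1) -
        log2(rowMeans(x[, ct == baseline, drop = FALSE]) + 1)
}

#' Signature-gene filtering cascade
#'
#' The four-stage filter that produces the clustered microglial gene set:
#' \enumerate{
#'   \item \code{signature_union}: the curated signature list;
#'   \item \code{overlap_with_data}: signature genes present in both
#'     datasets (case-insensitive symbol match);
#'   \item \code{consistent}: genes whose cross-dataset fold-change
#'     consistency score exceeds \code{cons_cut} — \code{x} is the
#'     monocyte-to-microglia-like log2 fold change in the test dataset,
#'     \code{y} the monocyte-to-microglia log2 fold change in the reference;
#'   \item \code{de_filtered}: consistent genes also passing the test-side
#'     differential expression filter \code{|FC| >= fc_cut},
#'     \code{p <= p_cut} and \code{base_mean >= expr_cut}
#'     (inclusive boundaries, per the criteria's wording).
#' }
#' Fold changes feeding the score are signed log2 ratios of size-factor
#' normalized group means (pseudocount 1); set \code{fc_scale = "linear"}
#' to score linear ratios instead for sensitivity analysis. The stage-4
#' \code{fc_cut} is always interpreted on the linear scale (1.2 means
#' \code{|log2FC| >= log2(1.2)}). The DE p-value is the raw Wald p by
#' default (\code{use_adjusted_p = TRUE} switches to BH-adjusted).
#'
#' @param test [CountExperiment-class] containing \code{test_contrast} cell
#'   types (the dataset under validation).
#' @param ref [CountExperiment-class] containing \code{ref_contrast} cell
#'   types (the published reference).
#' @param sig a \code{GeneList} of signature symbols.
#' @param fc_cut,p_cut,expr_cut stage-4 thresholds (defaults 1.2, 0.001, 5).
#' @param cons_cut consistency-score cutoff (default 0.50, strict).
#' @param test_contrast,ref_contrast length-2 character,
#'   \code{c(query, baseline)} cell types in each dataset.
#' @param fc_scale "log2" (default) or "linear" fold changes in the score.
#' @param use_adjusted_p threshold BH-adjusted p in stage 4 (default FALSE).
#' @return a [CascadeResult-class].
#' @export
signatureCascade <- function(test, ref, sig,
                             fc_cut = 1.2, p_cut = 0.001, expr_cut = 5,
                             cons_cut = 0.50,
                             test_contrast = c("iMG", "monocyte"),
                             ref_contrast = c("ref_microglia",
                                              "ref_monocyte"),
                             fc_scale = c("log2", "linear"),
                             use_adjusted_p = FALSE) {
    fc_scale <- match.arg(fc_scale)
    missing_ct <- c(setdiff(test_contrast, cellType(test)),
                    setdiff(ref_contrast, cellType(ref)))
    if (length(missing_ct))
        stop("required cell type(s) absent: ",
             paste(unique(missing_ct), collapse = ", "))

    stage1 <- sig$symbols
    key1 <- normalize_symbols(stage1)
    kt <- normalize_symbols(rownames(test))
    kr <- normalize_symbols(rownames(ref))
    in_both <- key1 %in% kt & key1 %in% kr
    stage2 <- stage1[in_both]
    if (!length(stage2))
        warning("no signature gene is present in both datasets")

    gt <- rownames(test)[match(normalize_symbols(stage2), kt)]
    gr <- rownames(ref)[match(normalize_symbols(stage2), kr)]

    x <- group_log2fc(test, test_contrast[1], test_contrast[2])[gt]
    y <- group_log2fc(ref, ref_contrast[1], ref_contrast[2])[gr]
    if (fc_scale == "linear") { x <- 2^x; y <- 2^y }
    cons <- data.frame(gene = stage2, x = unname(x), y = unname(y),
                       score = consistencyScore(unname(x), unname(y)))
    stage3 <- consistentGenes(cons, cons_cut)

    stage4 <- character()
    if (length(stage3)) {
        ct <- cellType(test)
        sub <- test[, ct %in% test_contrast]
        de <- nbWaldTest(sub, factor(cellType(sub),
                                     levels = rev(test_contrast)))
        p <- if (use_adjusted_p) de$adj_p else de$wald_p
        pass <- de$gene[abs(de$log2fc) >= log2(fc_cut) &
                        p <= p_cut & de$base_mean >= expr_cut]
        stage4 <- stage3[normalize_symbols(stage3) %in%
                         normalize_symbols(pass)]
    }

    methods::new("CascadeResult",
        stageGenes = list(signature_union = stage1,
                          overlap_with_data = stage2,
                          consistent = stage3,
                          de_filtered = stage4),
        params = list(fc_cut = fc_cut, p_cut = p_cut, expr_cut = expr_cut,
                      cons_cut = cons_cut, fc_scale = fc_scale,
                      use_adjusted_p = use_adjusted_p,
                      test_contrast = test_contrast,
                      ref_contrast = ref_contrast),
        consistency = cons)
}
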