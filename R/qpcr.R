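#' Relative expression by the 2^-ddCT method
#'
#' Livak relative quantification: per replicate,
#' \eqn{\Delta CT = CT_{target} - CT_{housekeeping}}; then
#' \eqn{\Delta\Delta CT = \Delta CT_{treated} - \overline{\Delta CT}_{control}}
#' and fold change \eqn{2^{-\Delta\Delta CT}}. The control baseline is the
#' mean control \eqn{\Delta CT}; per-replicate folds are retained so a mean
#' and SD can be reported. Any additive CT offset applied to both genes of
#' a replicate cancels exactly.
#'
#' @param t CT table (data.frame: condition, replicate, gene, ct) with
#'   gene values "target" and "housekeeping".
#' @param treated,control condition labels.
#' @return list with \code{folds} (per treated replicate), \code{mean},
#'   \code{sd}, and \code{control_folds} (control replicates against their
#'   own mean baseline).
#' @examples
#' ct <- simulateCtTable(3, c(control = 5, treated = 3), noise_sd = 0)
#' ddctFoldChange(ct, "treated", "control")$mean  # exactly 4
#' @export
ddctFoldChange <- function(t, treated, control) {
    delta <- function(cond) {
        sub <- t[t$condition == cond, ]
        if (!nrow(sub)) stop("condition not present: ", cond)
        tg <- sub[sub$gene == "target", ]
        hk <- sub[sub$gene == "housekeeping", ]
        if (!nrow(hk)) stop("missing housekeeping rows for ", cond)
        if (!all(sort(tg$replicate) == sort(hk$replicate)))
            stop("every replicate of '", cond,
                 "' needs both target and housekeeping CT")
        stats::setNames(tg$ct[order(tg$replicate)] -
                        hk$ct[order(hk$replicate)],
                        sort(tg$replicate))
    }
    d_treat <- delta(treated)
    d_ctrl <- delta(control)
    folds <- 2^-(d_treat - mean(d_ctrl))
    list(folds = folds, mean = mean(folds), sd = stats::sd(folds),
         control_folds = 2^-(d_ctrl - mean(d_ctrl)))
}

#' Compare fold changes across groups
#'
#' Two groups: two-sided Student's t-test. More than two groups: one-way
#' ANOVA F-test.
#'
#' @param folds_by_group named list of numeric vectors (>= 2 groups,
#'   >= 2 replicates each).
#' @return list with \code{p_value}, \code{method}, and the underlying fit.
#' @export
groupCompare <- function(folds_by_group) {
    if (length(folds_by_group) < 2L)
        stop("at least two groups are required")
    sizes <- lengths(folds_by_group)
    if (any(sizes < 2L))
        stop("each group needs >= 2 replicates; got ",
             paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "))
    if (length(folds_by_group) == 2L) {
        ht <- stats::t.test(folds_by_group[[1]], folds_by_group[[2]])
        list(p_value = ht$p.value, method = "t-test", fit = ht)
    } else {
        y <- unlist(folds_by_group, use.names = FALSE)
        grp <- factor(rep(names(folds_by_group), sizes))
        fit <- stats::aov(y ~ grp)
        p <- summary(fit)[[1]][["Pr(>F)"]][1]
        list(p_value = p, method = "anova", fit = fit)
    }
}
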