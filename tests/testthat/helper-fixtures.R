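# Small fixture builders shared across test files.

# tiny deterministic CountExperiment; counts chosen by hand
toy_counts <- function(values = NULL, n_genes = 3L, samples = c("s1", "s2"),
                       cell_type = rep("monocyte", length(samples)),
                       study = rep("A", length(samples))) {
    if (is.null(values))
        values <- matrix(seq_len(n_genes * length(samples)),
                         nrow = n_genes)
    dimnames(values) <- list(paste0("g", seq_len(nrow(values))), samples)
    CountExperiment(values, cell_type = cell_type, study = study)
}

# two-group CountExperiment with NB counts at given per-group means
nb_two_group <- function(mu1, mu2, n_per_group = 10L, alpha = 0.1,
                         seed = 1L) {
    withr::local_seed(seed)
    g <- length(mu1)
    k1 <- matrix(rnbinom(g * n_per_group, mu = mu1, size = 1 / alpha),
                 nrow = g)
    k2 <- matrix(rnbinom(g * n_per_group, mu = mu2, size = 1 / alpha),
                 nrow = g)
    m <- cbind(k1, k2)
    dimnames(m) <- list(sprintf("g%04d", seq_len(g)),
                        sprintf("s%02d", seq_len(2 * n_per_group)))
    groups <- rep(c("A", "B"), each = n_per_group)
    list(ce = CountExperiment(m, cell_type = groups,
                              study = rep("x", 2 * n_per_group)),
         groups = groups)
}

normalize_symbols_oracle <- function(x) toupper(trimws(x))

# naive per-gene log2 ratio of group means on the normalized-count scale,
# using DESeq2's size-factor estimator as the independent normalizer
group_log2fc_oracle <- function(ce, query, baseline) {
    k <- counts(ce)
    sf <- DESeq2::estimateSizeFactorsForMatrix(k)
    x <- sweep(k, 2, sf, "/")
    ct <- cellType(ce)
    log2(rowMeans(x[, ct == query, drop = FALSE])) -
        log2(rowMeans(x[, ct == baseline, drop = FALSE]))
}

# residual sum of squares after optimal translation + orthogonal rotation
# (no scaling) mapping Y onto X — an independent Procrustes implementation
procrustes_ss <- function(X, Y) {
    Xc <- scale(X, scale = FALSE)
    Yc <- scale(Y, scale = FALSE)
    s <- svd(crossprod(Xc, Yc))
    R <- s$v %*% t(s$u)
    sum((Xc - Yc %*% R)^2)
}
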