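test_that("median-of-ratios size factors follow hand-computed values", {
    # identical columns -> all factors 1
    m <- toy_counts(matrix(rep(c(5L, 10L, 20L), 2), 3))
    expect_equal(unname(computeSizeFactors(m)), c(1, 1))

    # second column exactly double: factors (1/sqrt(2), sqrt(2))
    m2 <- toy_counts(matrix(c(10L, 20L, 30L, 20L, 40L, 60L), 3))
    expect_equal(unname(computeSizeFactors(m2)),
                 c(0.70711, 1.41421), tolerance = 1e-4)

    # permuting sample order permutes factors identically
    m3 <- toy_counts(matrix(c(20L, 40L, 60L, 10L, 20L, 30L), 3),
                     samples = c("s2", "s1"))
    f2 <- computeSizeFactors(m2)
    f3 <- computeSizeFactors(m3)
    expect_equal(f3[c("s1", "s2")], f2[c("s1", "s2")])

    # no reference-eligible gene -> error suggesting fallback
    m4 <- toy_counts(matrix(c(0L, 5L, 3L, 0L), 2))
    expect_error(computeSizeFactors(m4), "total-count")
})

test_that("size factors agree with the DESeq2 estimator on simulated data", {
    st <- simulateCounts(simulationConfig(n_genes = 500L, seed = 31L))
    ours <- computeSizeFactors(st$counts)
    ref <- DESeq2::estimateSizeFactorsForMatrix(counts(st$counts))
    expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("count normalization divides by factors and reaches a fixed point", {
    m <- toy_counts(matrix(c(20L, 8L, 40L, 16L), 2))
    f <- setNames(c(1, 1), c("s1", "s2"))
    expect_identical(normValues(normalizeCounts(m, f)),
                     matrix(c(20, 8, 40, 16), 2,
                            dimnames = dimnames(counts(m))))
    f2 <- setNames(c(2, 2), c("s1", "s2"))
    expect_equal(normValues(normalizeCounts(m, f2))["g1", "s1"], 10)
    expect_error(normalizeCounts(m, c(s1 = 2)), "s2")

    # doubled-column example: normalized column sums equal
    m2 <- toy_counts(matrix(c(10L, 20L, 30L, 20L, 40L, 60L), 3))
    v <- normValues(normalizeCounts(m2))
    expect_equal(colSums(v)[[1]], colSums(v)[[2]])

    # fixed point: re-estimating factors on normalized values gives a
    # constant vector (the original factors' geometric mean) near 1
    st <- simulateCounts(simulationConfig(n_genes = 300L, seed = 37L))
    v2 <- normValues(normalizeCounts(st$counts))
    lg <- log(v2[rowSums(v2 == 0) == 0, ])
    refac <- exp(apply(lg - rowMeans(lg), 2, median))
    expect_lt(max(refac) - min(refac), 1e-12)
    expect_equal(unname(refac), rep(1, ncol(v2)), tolerance = 0.05)
})

test_that("FPKM follows its defining formula and identities", {
    # count 10, length 1000 bp, column total 1e6 -> FPKM 10
    k <- matrix(c(10L, 999990L), 2, 1)
    dimnames(k) <- list(c("gA", "gB"), "s1")
    ce <- CountExperiment(k, cell_type = "monocyte", study = "A")
    lens <- c(gA = 1000, gB = 500)
    v <- normValues(fpkm(ce, lens))
    expect_equal(v["gA", "s1"], 10)

    # zero count stays zero; missing length errors with the gene named
    k2 <- matrix(c(0L, 10L, 5L, 20L), 2,
                 dimnames = list(c("gA", "gB"), c("s1", "s2")))
    ce2 <- CountExperiment(k2, cell_type = c("a", "a"), study = c("A", "A"))
    expect_equal(normValues(fpkm(ce2, lens))["gA", "s1"], 0)
    expect_error(fpkm(ce2, c(gA = 1000)), "gB")

    # sum_g FPKM * length = 1e9 for every sample
    st <- simulateCounts(simulationConfig(n_genes = 200L, seed = 41L))
    lens2 <- setNames(sample(500:5000, 200, replace = TRUE), rownames(st$counts))
    fv <- normValues(fpkm(st$counts, lens2))
    expect_equal(unname(colSums(fv * lens2)), rep(1e9, ncol(fv)))

    # agrees with the edgeR implementation given the same column totals
    ref <- edgeR::rpkm(counts(st$counts), gene.length = lens2,
                       lib.size = colSums(counts(st$counts)))
    expect_equal(unname(fv), unname(ref), tolerance = 1e-12)

    # doubling a column leaves its FPKM unchanged
    k3 <- counts(ce2)
    k3[, 1] <- k3[, 1] * 2L
    ce3 <- CountExperiment(k3, cell_type = c("a", "a"), study = c("A", "A"))
    expect_equal(normValues(fpkm(ce3, lens))[, 1],
                 normValues(fpkm(ce2, lens))[, 1])
})

test_that("VST is monotone, anchored at zero, and log2-like for large counts", {
    expect_equal(microgliaID:::vst_raw(0, 0.1), 0)
    for (alpha in c(0.01, 0.1, 1)) {
        x <- sort(runif(50, 0, 1e4))
        expect_true(all(diff(microgliaID:::vst_raw(x, alpha)) > 0))
    }
    # log2 slope in the large-count limit: vst(2x) - vst(x) -> 1
    v2x <- microgliaID:::vst_raw(2e6, 0.1) - microgliaID:::vst_raw(1e6, 0.1)
    expect_lt(abs(v2x - 1), 1e-3)
    expect_error(vstTransform(toy_counts(), dispersion = -1), "dispersion")

    # rank preservation within each sample
    st <- simulateCounts(simulationConfig(n_genes = 100L, seed = 43L))
    f <- computeSizeFactors(st$counts)
    vt <- normValues(vstTransform(st$counts, 0.1, f))
    nc <- normValues(normalizeCounts(st$counts, f))
    for (j in c(1L, ncol(vt)))
        expect_identical(order(vt[, j]), order(nc[, j]))
})

test_that("batch removal equalizes batch means and preserves structure", {
    # single batch: output equals input
    st <- simulateCounts(simulationConfig(
        n_genes = 100L, samples_per_group = c(monocyte = 4L, iMG = 4L),
        studies = c(monocyte = "test", iMG = "test"), seed = 47L))
    lg <- logTransform(st$counts)
    expect_equal(normValues(correctBatchEffect(lg)), normValues(lg))

    # two batches offset by a constant per gene, same condition mix
    set.seed(1)
    base <- matrix(rnorm(50 * 8, 8, 1), 50,
                   dimnames = list(paste0("g", 1:50), paste0("s", 1:8)))
    delta <- rnorm(50, 2, 0.5)
    vals <- base
    vals[, 5:8] <- vals[, 5:8] + delta
    ce <- CountExperiment(matrix(0L, 50, 8, dimnames = dimnames(vals)),
                          cell_type = rep(c("a", "b"), 4),
                          study = rep(c("A", "B"), each = 4))
    ne <- NormalizedExperiment(vals, ce, list(name = "log2"))
    out <- normValues(correctBatchEffect(ne))
    batch_means_A <- rowMeans(out[, 1:4])
    batch_means_B <- rowMeans(out[, 5:8])
    expect_lt(max(abs(batch_means_A - batch_means_B)), 1e-9)
    # grand mean per gene unchanged
    expect_lt(max(abs(rowMeans(out) - rowMeans(vals))), 1e-9)

    # planted condition effect survives batch removal
    cond_fc <- rowMeans(out[, ce$cell_type == "b"]) -
        rowMeans(out[, ce$cell_type == "a"])
    truth_fc <- rowMeans(base[, c(2, 4, 6, 8)]) -
        rowMeans(base[, c(1, 3, 5, 7)])
    expect_equal(cond_fc, truth_fc, tolerance = 1e-9)

    # batch confounded with condition errors
    ce2 <- CountExperiment(matrix(0L, 50, 8, dimnames = dimnames(vals)),
                           cell_type = rep(c("a", "b"), each = 4),
                           study = rep(c("A", "B"), each = 4))
    ne2 <- NormalizedExperiment(vals, ce2, list(name = "log2"))
    expect_error(correctBatchEffect(ne2), "confounded")
})

test_that("unit-interval rescaling is affine, conventional and idempotent", {
    vals <- matrix(c(2, 4, 6, 5, 5, 5), 2, byrow = TRUE,
                   dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
    ce <- CountExperiment(matrix(0L, 2, 3, dimnames = dimnames(vals)),
                          cell_type = rep("a", 3), study = rep("A", 3))
    ne <- NormalizedExperiment(vals, ce, list(name = "log2"))
    r <- normValues(rescaleUnitInterval(ne))
    expect_equal(unname(r["g1", ]), c(0, 0.5, 1))
    expect_equal(unname(r["g2", ]), c(0, 0, 0))  # constant-gene convention
    r2 <- normValues(rescaleUnitInterval(rescaleUnitInterval(ne)))
    expect_equal(r2["g1", ], r["g1", ])
})
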