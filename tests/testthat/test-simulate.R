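test_that("identical seeds give bit-identical simulations", {
    cfg <- simulationConfig(n_genes = 300L, seed = 7L)
    a <- simulateCounts(cfg)
    b <- simulateCounts(cfg)
    expect_identical(counts(a$counts), counts(b$counts))
    expect_identical(a$truth_signature, b$truth_signature)
    c2 <- simulateCounts(simulationConfig(n_genes = 300L, seed = 8L))
    expect_false(identical(counts(a$counts), counts(c2$counts)))
})

test_that("invalid configuration fields are rejected by name", {
    expect_error(simulationConfig(dispersion = 0), "dispersion")
    expect_error(simulationConfig(n_signature = 5000), "n_signature")
    expect_error(simulationConfig(batch_log2shift_sd = -1),
                 "batch_log2shift_sd")
    expect_error(simulationConfig(library_size_range = c(2, 1)),
                 "library_size_range")
    expect_error(simulationConfig(samples_per_group = c(monocyte = 0L)),
                 "samples_per_group")
})

test_that("expected column sums match drawn library sizes", {
    # many samples of one population: column sums average to the target
    cfg <- simulationConfig(n_genes = 1000L, seed = 11L,
                            samples_per_group = c(monocyte = 100L),
                            studies = c(monocyte = "test"),
                            library_size_range = c(1e6, 1e6))
    st <- simulateCounts(cfg)
    ratios <- colSums(counts(st$counts)) / 1e6
    expect_lt(abs(mean(ratios) - 1), 0.02)
    expect_true(all(abs(ratios - 1) < 0.3))
})

test_that("counts follow the NB mean-variance relation mu + alpha*mu^2", {
    # many replicate samples of one population -> per-gene sample variance
    alpha <- 0.2
    cfg <- simulationConfig(
        n_genes = 400L, n_signature = 0L, marker_frac = 0,
        batch_log2shift_sd = 0, dispersion = alpha,
        samples_per_group = c(monocyte = 1000L),
        studies = c(monocyte = "test"),
        library_size_range = c(1e6, 1e6), seed = 13L)
    k <- counts(simulateCounts(cfg)$counts)
    mu <- rowMeans(k)
    v <- apply(k, 1, var)
    expected <- mu + alpha * mu^2
    # pooled ratio of observed to NB-model variance is near 1
    expect_lt(abs(median(v / expected) - 1), 0.15)
    # and clearly overdispersed relative to Poisson
    expect_gt(median(v / mu), 5)
})

test_that("null simulation yields group log2 fold changes centered on zero", {
    cfg <- simulationConfig(
        n_genes = 2000L, n_signature = 100L, signature_log2fc = 0,
        batch_log2shift_sd = 0, marker_frac = 0,
        dispersion = 0.05, baseline_mean = 200,
        samples_per_group = c(monocyte = 20L, iMG = 20L),
        studies = c(monocyte = "test", iMG = "test"), seed = 17L)
    st <- simulateCounts(cfg)
    lfc <- group_log2fc_oracle(st$counts, "iMG", "monocyte")
    expect_lt(abs(mean(lfc)), 0.02)
    expect_lt(mean(abs(lfc)), 0.1)
})

test_that("planted signature effect is recovered within two standard errors", {
    cfg <- simulationConfig(
        n_genes = 2000L, n_signature = 150L, signature_log2fc = 2,
        batch_log2shift_sd = 0, marker_frac = 0,
        samples_per_group = c(monocyte = 20L, iMG = 20L),
        studies = c(monocyte = "test", iMG = "test"), seed = 19L)
    st <- simulateCounts(cfg)
    lfc <- group_log2fc_oracle(st$counts, "iMG", "monocyte")
    sig <- st$truth_signature
    null_genes <- setdiff(names(lfc), sig)
    # center on the known-null genes: a one-sided signature carrying ~7%
    # of the library shifts every ratio-based normalizer slightly, and
    # that compositional offset is common to all genes
    est <- mean(lfc[sig]) - median(lfc[null_genes])
    se <- sd(lfc[sig]) / sqrt(length(sig))
    expect_lt(abs(est - 2), 2 * se + 0.02)
    # the uncentered estimate is still close on the absolute scale
    expect_lt(abs(mean(lfc[sig]) - 2), 0.15)
})

test_that("simulated counts round-trip through the TSV writers", {
    st <- simulateCounts(simulationConfig(n_genes = 50L, seed = 23L))
    prefix <- file.path(withr::local_tempdir(), "sim")
    paths <- writeCounts(st$counts, prefix)
    back <- readCounts(paths["counts"], paths["meta"])
    expect_identical(counts(back), counts(st$counts))
    expect_identical(cellType(back), cellType(st$counts))
    expect_identical(study(back), study(st$counts))
})

test_that("CT table simulation honors the planted delta-CT structure", {
    # zero noise, equal delta CT -> downstream fold exactly 1
    t0 <- simulateCtTable(3L, c(control = 5, treated = 5), noise_sd = 0,
                          seed = 1L)
    expect_equal(ddctFoldChange(t0, "treated", "control")$mean, 1)
    # treated delta CT lower by 2 cycles -> fold exactly 4
    t1 <- simulateCtTable(3L, c(control = 5, treated = 3), noise_sd = 0,
                          seed = 1L)
    expect_equal(ddctFoldChange(t1, "treated", "control")$mean, 4)
    # seed determinism
    a <- simulateCtTable(4L, c(control = 5, treated = 2), noise_sd = 0.3,
                         seed = 9L)
    b <- simulateCtTable(4L, c(control = 5, treated = 2), noise_sd = 0.3,
                         seed = 9L)
    expect_identical(a, b)
    expect_error(simulateCtTable(3L, c(a = 1), noise_sd = -1), "noise_sd")
})
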