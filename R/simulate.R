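#' Simulation configuration for synthetic multi-cell-type RNA-seq counts
#'
#' Builds and validates the parameter set for [simulateCounts()]. The
#' defaults emulate the study design the pipeline targets: a test study with
#' three monocyte, three induced-macrophage (iMac) and four induced-microglia
#' (iMG) libraries, and a reference study contributing brain microglia and
#' monocytes, with a planted microglial signature gene set, per-cell-type
#' marker programs, per-study multiplicative batch effects and heterogeneous
#' library sizes.
#'
#' Counts are negative binomial with variance \eqn{\mu + \alpha \mu^2}
#' (\code{dispersion} is \eqn{\alpha}); the same parameterization is used by
#' the differential-expression module. Library sizes are drawn uniformly on
#' \code{library_size_range} and per-sample gene weights are renormalized so
#' each column's expected sum equals its drawn library size.
#'
#' @param n_genes number of genes.
#' @param n_signature number of planted microglial signature genes
#'   (must be <= n_genes). Signature genes carry \code{signature_log2fc} in
#'   iMG and reference microglia relative to monocytes, and half that effect
#'   in iMacs (macrophages share part of the microglial program).
#' @param samples_per_group named integer vector, samples per cell type.
#'   Allowed labels: monocyte, iMac, iMG, ref_microglia, ref_monocyte.
#' @param studies named character vector mapping each cell type to a study
#'   (batch) label; at least two distinct studies by default.
#' @param baseline_mean mean expression scale; per-gene baselines are
#'   log-normal around this value.
#' @param dispersion NB dispersion alpha (> 0).
#' @param signature_log2fc planted log2 fold change of signature genes in
#'   microglia-like cell types vs monocytes.
#' @param batch_log2shift_sd SD (log2 scale) of the per-gene per-study
#'   multiplicative batch shift; 0 disables batch effects.
#' @param marker_frac fraction of genes given to each cell type as its own
#'   marker program (distinguishes otherwise-identical populations such as
#'   test and reference monocytes); 0 disables markers.
#' @param marker_log2sd SD (log2) of marker-program effects.
#' @param library_size_range length-2 numeric, uniform range of expected
#'   library sizes.
#' @param seed integer seed; a single global stream drives every draw.
#' @return validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(
        n_genes = 2000L,
        n_signature = max(1L, min(150L, n_genes %/% 10L)),
        samples_per_group = c(monocyte = 3L, iMac = 3L, iMG = 4L,
                              ref_microglia = 4L, ref_monocyte = 3L),
        studies = c(monocyte = "test", iMac = "test", iMG = "test",
                    ref_microglia = "reference", ref_monocyte = "reference"),
        baseline_mean = 100,
        dispersion = 0.1,
        signature_log2fc = 2,
        batch_log2shift_sd = 0.25,
        marker_frac = 0.05,
        marker_log2sd = 1.5,
        library_size_range = c(8e5, 1.2e6),
        seed = 1L) {
    cfg <- list(n_genes = as.integer(n_genes),
                n_signature = as.integer(n_signature),
                samples_per_group = samples_per_group,
                studies = studies,
                baseline_mean = baseline_mean,
                dispersion = dispersion,
                signature_log2fc = signature_log2fc,
                batch_log2shift_sd = batch_log2shift_sd,
                marker_frac = marker_frac,
                marker_log2sd = marker_log2sd,
                library_size_range = as.numeric(library_size_range),
                seed = as.integer(seed))
    class(cfg) <- "SimulationConfig"
    validate_sim_config(cfg)
    cfg
}

.allowed_cell_types <- c("monocyte", "iMac", "iMG",
                         "ref_microglia", "ref_monocyte")

validate_sim_config <- function(cfg) {
    if (!is.finite(cfg$n_genes) || cfg$n_genes < 1L)
        stop_config("n_genes", "must be a positive integer")
    if (cfg$n_signature < 0L || cfg$n_signature > cfg$n_genes)
        stop_config("n_signature", "must satisfy 0 <= n_signature <= n_genes")
    spg <- cfg$samples_per_group
    if (is.null(names(spg)) || any(!names(spg) %in% .allowed_cell_types))
        stop_config("samples_per_group",
                    paste("names must be among",
                          paste(.allowed_cell_types, collapse = ", ")))
    if (any(spg < 1L))
        stop_config("samples_per_group", "all counts must be >= 1")
    if (any(!names(spg) %in% names(cfg$studies)))
        stop_config("studies", "every cell type needs a study label")
    if (!is.finite(cfg$baseline_mean) || cfg$baseline_mean <= 0)
        stop_config("baseline_mean", "must be positive")
    if (!is.finite(cfg$dispersion) || cfg$dispersion <= 0)
        stop_config("dispersion", "must be positive")
    if (cfg$batch_log2shift_sd < 0)
        stop_config("batch_log2shift_sd", "must be non-negative")
    if (cfg$marker_frac < 0 || cfg$marker_frac > 1)
        stop_config("marker_frac", "must be in [0, 1]")
    lsr <- cfg$library_size_range
    if (length(lsr) != 2L || any(lsr <= 0) || lsr[1] > lsr[2])
        stop_config("library_size_range",
                    "must be two positive values, low <= high")
    invisible(cfg)
}

# NB counts for a genes x samples mean matrix; variance mu + alpha mu^2
nb_draw <- function(mu, alpha) {
    k <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / alpha),
                nrow = nrow(mu), dimnames = dimnames(mu))
    storage.mode(k) <- "integer"
    k
}

# expected counts: per-sample weights renormalized to the drawn library size
mu_from_effects <- function(baseline, effect_log2, lib_sizes) {
    w <- baseline * 2^effect_log2
    sweep(w, 2, lib_sizes / colSums(w), `*`)
}

#' Simulate a synthetic multi-cell-type count study
#'
#' Draws negative-binomial counts with the planted structure described in
#' [simulationConfig()]: a microglial signature shared by iMG and reference
#' microglia, per-cell-type marker programs, per-gene per-study batch shifts
#' and uniform library sizes. Identical seeds give bit-identical output; the
#' caller's RNG state is left untouched.
#'
#' @param config a \code{SimulationConfig}.
#' @return a \code{SyntheticStudy} list with elements
#'   \describe{
#'     \item{counts}{a [CountExperiment-class] (cell_type and study in
#'       colData; per-gene truth in rowData).}
#'     \item{truth_signature}{character, ids of the planted signature genes.}
#'     \item{truth_log2fc}{named numeric, planted iMG-vs-monocyte log2 fold
#'       change per gene (0 where neither population is simulated).}
#'     \item{truth_batch}{named character, study label per sample.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' st <- simulateCounts(simulationConfig(n_genes = 200, seed = 7))
#' st$counts
#' @export
simulateCounts <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    validate_sim_config(config)
    withr::local_seed(config$seed)

    genes <- sprintf("GENE%05d", seq_len(config$n_genes))
    types <- names(config$samples_per_group)
    baseline <- stats::rlnorm(config$n_genes,
                              meanlog = log(config$baseline_mean) - 0.5,
                              sdlog = 1)

    sig <- sort(sample(genes, config$n_signature))
    effect <- matrix(0, config$n_genes, length(types),
                     dimnames = list(genes, types))
    sig_strength <- c(iMG = 1, ref_microglia = 1, iMac = 0.5,
                      monocyte = 0, ref_monocyte = 0)
    for (t in types)
        effect[sig, t] <- config$signature_log2fc * sig_strength[[t]]

    n_marker <- round(config$marker_frac * config$n_genes)
    if (n_marker > 0) {
        non_sig <- setdiff(genes, sig)
        for (t in types) {
            mk <- sample(non_sig, min(n_marker, length(non_sig)))
            effect[mk, t] <- effect[mk, t] +
                stats::rnorm(length(mk), 0, config$marker_log2sd)
        }
    }

    study_of <- config$studies[types]
    studies <- unique(unname(study_of))
    batch <- matrix(stats::rnorm(config$n_genes * length(studies), 0,
                                 config$batch_log2shift_sd),
                    config$n_genes, length(studies),
                    dimnames = list(genes, studies))

    cell_type <- rep(types, times = config$samples_per_group)
    sample_study <- unname(study_of[cell_type])
    sample_ids <- unlist(lapply(types, function(t)
        sprintf("%s_%s_%d", t, study_of[[t]],
                seq_len(config$samples_per_group[[t]]))))
    lib <- stats::runif(length(sample_ids),
                        config$library_size_range[1],
                        config$library_size_range[2])

    eff_per_sample <- effect[, cell_type, drop = FALSE] +
        batch[, sample_study, drop = FALSE]
    colnames(eff_per_sample) <- sample_ids
    mu <- mu_from_effects(baseline, eff_per_sample, lib)
    k <- nb_draw(mu, config$dispersion)

    truth_fc <- if (all(c("iMG", "monocyte") %in% types))
        effect[, "iMG"] - effect[, "monocyte"] else stats::setNames(
            rep(0, config$n_genes), genes)

    ce <- CountExperiment(k, cell_type = cell_type, study = sample_study)
    SummarizedExperiment::rowData(ce)$signature <- genes %in% sig
    SummarizedExperiment::rowData(ce)$truth_log2fc <- unname(truth_fc)

    structure(list(counts = ce,
                   truth_signature = sig,
                   truth_log2fc = truth_fc,
                   truth_batch = stats::setNames(sample_study, sample_ids),
                   config = config),
              class = "SyntheticStudy")
}

#' Simulate a paired test/reference dataset with planted concordance
#'
#' Generates two single-study datasets (monocyte + iMG in the test study,
#' monocyte + microglia in the reference study) sharing a planted signature
#' in which a chosen number of genes change concordantly in both datasets,
#' a chosen number change discordantly (opposite signs), and the remainder
#' are null. Used to exercise the consistency-score cascade against known
#' truth.
#'
#' @param n_genes total genes.
#' @param n_signature signature size.
#' @param n_concordant signature genes with the same-signed planted
#'   \code{effect} in both datasets (sign alternates across genes).
#' @param n_discordant signature genes with opposite-signed effects.
#' @param effect magnitude of the planted log2 fold change.
#' @param samples_per_group samples in each of the four cell-type groups.
#' @param baseline_mean,dispersion,library_size_range as in
#'   [simulationConfig()].
#' @param seed integer seed.
#' @return list with \code{test} and \code{ref} [CountExperiment-class]
#'   objects, the \code{signature} gene ids, and the \code{concordant} and
#'   \code{discordant} truth subsets.
#' @export
simulatePairedSignature <- function(n_genes = 2000L, n_signature = 200L,
                                    n_concordant = 80L, n_discordant = 40L,
                                    effect = 2, samples_per_group = 20L,
                                    baseline_mean = 100, dispersion = 0.1,
                                    library_size_range = c(8e5, 1.2e6),
                                    seed = 1L) {
    if (n_concordant + n_discordant > n_signature)
        stop_config("n_concordant",
                    "concordant + discordant must not exceed n_signature")
    if (n_signature > n_genes)
        stop_config("n_signature", "must satisfy n_signature <= n_genes")
    withr::local_seed(seed)

    genes <- sprintf("GENE%05d", seq_len(n_genes))
    baseline <- stats::rlnorm(n_genes, log(baseline_mean) - 0.5, 1)
    sig <- sort(sample(genes, n_signature))
    conc <- sig[seq_len(n_concordant)]
    disc <- sig[n_concordant + seq_len(n_discordant)]

    fx_test <- fx_ref <- stats::setNames(rep(0, n_genes), genes)
    sgn <- rep_len(c(1, -1), n_concordant)
    fx_test[conc] <- sgn * effect
    fx_ref[conc] <- sgn * effect
    sgn_d <- rep_len(c(1, -1), n_discordant)
    fx_test[disc] <- sgn_d * effect
    fx_ref[disc] <- -sgn_d * effect

    one_study <- function(fx, mg_label, study_label) {
        n <- samples_per_group
        cell_type <- rep(c(if (study_label == "test") "monocyte"
                           else "ref_monocyte", mg_label), each = n)
        ids <- sprintf("%s_%d", cell_type, sequence(c(n, n)))
        eff <- outer(fx, as.numeric(cell_type == mg_label))
        dimnames(eff) <- list(genes, ids)
        lib <- stats::runif(2 * n, library_size_range[1],
                            library_size_range[2])
        k <- nb_draw(mu_from_effects(baseline, eff, lib), dispersion)
        CountExperiment(k, cell_type = cell_type,
                        study = rep(study_label, 2 * n))
    }
    list(test = one_study(fx_test, "iMG", "test"),
         ref = one_study(fx_ref, "ref_microglia", "reference"),
         signature = sig, concordant = conc, discordant = disc,
         truth_log2fc_test = fx_test, truth_log2fc_ref = fx_ref)
}

#' Simulate a qPCR CT table
#'
#' Produces per-replicate threshold-cycle (CT) values for a target and a
#' housekeeping gene across conditions, with a specified per-condition
#' target-minus-housekeeping difference (delta CT). With \code{noise_sd = 0}
#' the downstream 2^-ddCT fold change is exact.
#'
#' @param n_replicates replicates per condition (>= 1).
#' @param target_delta_ct named numeric: condition label -> delta CT
#'   (CT_target - CT_housekeeping) in cycles.
#' @param noise_sd SD in cycles of independent Gaussian noise added to every
#'   CT value; must be non-negative.
#' @param seed integer seed.
#' @param housekeeping_ct baseline housekeeping CT (cycles).
#' @return data.frame with columns condition, replicate, gene
#'   ("target"/"housekeeping"), ct.
#' @export
simulateCtTable <- function(n_replicates, target_delta_ct, noise_sd = 0.2,
                            seed = 1L, housekeeping_ct = 15) {
    if (n_replicates < 1L)
        stop_config("n_replicates", "must be >= 1")
    if (noise_sd < 0)
        stop_config("noise_sd", "must be non-negative")
    if (is.null(names(target_delta_ct)))
        stop_config("target_delta_ct", "must be named by condition")
    withr::local_seed(seed)
    rows <- do.call(rbind, lapply(names(target_delta_ct), function(cond) {
        hk <- housekeeping_ct + stats::rnorm(n_replicates, 0, noise_sd)
        tg <- housekeeping_ct + target_delta_ct[[cond]] +
            stats::rnorm(n_replicates, 0, noise_sd)
        data.frame(condition = cond,
                   replicate = rep(seq_len(n_replicates), 2L),
                   gene = rep(c("housekeeping", "target"),
                              each = n_replicates),
                   ct = c(hk, tg))
    }))
    rownames(rows) <- NULL
    rows
}
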