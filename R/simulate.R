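## Decay-cluster step signs over the two transitions (GV->MII, MII->D3):
## -1 = degraded, 0 = stable, +1 = elevated.
CLUSTER_STEPS <- matrix(
    c(-1,  0,   # I    degraded then stable
       0, -1,   # II   stable then degraded
      -1, -1,   # III  continuous degradation
       0,  0,   # IV   stable throughout
       1,  0,   # V    elevated then stable
       0,  1,   # VI   stable then elevated (ZGA)
       1,  1,   # VII  continuous elevation
      -1,  1,   # VIII degraded then elevated
       1, -1),  # IX   elevated then degraded
    ncol = 2, byrow = TRUE,
    dimnames = list(CLUSTER_LEVELS, c("MII-GV", "D3-MII")))

#' Simulation configuration
#'
#' Parameters of the synthetic control/mutant GV-MII-D3 single-sample
#' experiment. Defaults describe the study conditions the pipeline targets:
#' nine decay clusters of 200 genes each with 4-fold (2 log2) transition
#' steps, negative-binomial dispersion 0.1, three samples per
#' stage-by-genotype cell, 5\% of each control-GV library from spike-ins, a
#' global 0.6x mRNA-dosage reduction in mutant GV oocytes, mutant decay steps
#' attenuated to 30\% of their control magnitude, and mutant day-3
#' zygotic-genome-activation (ZGA) elevation attenuated to 30\%.
#'
#' @param genes_per_cluster integer vector of length 9: genes in decay
#'   clusters I-IX.
#' @param n_samples samples per (stage, genotype) cell.
#' @param baseline_log2_mean,baseline_log2_sd log2 GV expression-rate
#'   distribution for control genes.
#' @param cluster_step_log2 magnitude of a degraded/elevated transition step
#'   (log2 units).
#' @param nb_dispersion negative-binomial dispersion alpha in
#'   \code{var = mu + alpha mu^2}.
#' @param library_size_mean,library_size_cv mean and coefficient of variation
#'   of the log-normal library size (reads).
#' @param n_spike_ins number of spike-in species.
#' @param spike_fraction fraction of each control-GV library expected from
#'   spike-ins.
#' @param mutant_gv_dosage_factor multiplier (< 1) on endogenous GV rates in
#'   mutants; models the reduced absolute mRNA dosage of mutant GV oocytes.
#' @param mutant_decay_attenuation fraction of each degradation step retained
#'   in mutants (0.3 means decay is strongly impaired).
#' @param mutant_zga_attenuation fraction of each MII-to-D3 elevation step
#'   realised in mutant day-3 embryos (impaired ZGA).
#' @param seed integer seed; all sampling flows through one seeded generator.
#'
#' @return A list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(genes_per_cluster = rep(200L, 9),
                             n_samples = 3,
                             baseline_log2_mean = 6,
                             baseline_log2_sd = 1.5,
                             cluster_step_log2 = 2,
                             nb_dispersion = 0.1,
                             library_size_mean = 1e6,
                             library_size_cv = 0.2,
                             n_spike_ins = 92,
                             spike_fraction = 0.05,
                             mutant_gv_dosage_factor = 0.6,
                             mutant_decay_attenuation = 0.3,
                             mutant_zga_attenuation = 0.3,
                             seed = 1L) {
    cfg <- list(genes_per_cluster = as.integer(genes_per_cluster),
                n_samples = as.integer(n_samples),
                baseline_log2_mean = baseline_log2_mean,
                baseline_log2_sd = baseline_log2_sd,
                cluster_step_log2 = cluster_step_log2,
                nb_dispersion = nb_dispersion,
                library_size_mean = library_size_mean,
                library_size_cv = library_size_cv,
                n_spike_ins = as.integer(n_spike_ins),
                spike_fraction = spike_fraction,
                mutant_gv_dosage_factor = mutant_gv_dosage_factor,
                mutant_decay_attenuation = mutant_decay_attenuation,
                mutant_zga_attenuation = mutant_zga_attenuation,
                seed = as.integer(seed))
    class(cfg) <- "SimulationConfig"
    validateSimulationConfig(cfg)
    cfg
}

validateSimulationConfig <- function(cfg) {
    stopifnot(length(cfg$genes_per_cluster) == 9)
    if (any(cfg$genes_per_cluster < 0))
        stop("genes_per_cluster must be non-negative", call. = FALSE)
    if (sum(cfg$genes_per_cluster) == 0)
        stop("at least one gene must be simulated", call. = FALSE)
    if (cfg$nb_dispersion <= 0)
        stop("nb_dispersion must be positive", call. = FALSE)
    if (cfg$n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
    if (cfg$spike_fraction <= 0 || cfg$spike_fraction >= 1)
        stop("spike_fraction must lie in (0, 1)", call. = FALSE)
    if (cfg$mutant_gv_dosage_factor <= 0)
        stop("mutant_gv_dosage_factor must be positive", call. = FALSE)
    for (p in c("mutant_decay_attenuation", "mutant_zga_attenuation"))
        if (cfg[[p]] < 0 || cfg[[p]] > 1)
            stop(p, " must lie in [0, 1]", call. = FALSE)
    if (cfg$library_size_mean <= 0 || cfg$library_size_cv <= 0)
        stop("library size parameters must be positive", call. = FALSE)
    invisible(cfg)
}

## Expected log2 rate per gene x stage for one genotype. Degradation steps
## in mutants keep only `decay_att` of their magnitude; elevation steps in
## the MII->D3 transition keep only `zga_att` (ZGA impairment is a day-3
## phenomenon, so GV->MII elevation is left intact).
build_log2_rates <- function(baseline, steps, step_size, mutant,
                             dosage_log2, decay_att, zga_att) {
    eff <- function(s, transition) {
        d <- s * step_size
        if (!mutant) return(d)
        if (s < 0) d * decay_att
        else if (s > 0 && transition == 2) d * zga_att
        else d
    }
    gv <- baseline + if (mutant) dosage_log2 else 0
    d1 <- mapply(eff, steps[, 1], 1)
    d2 <- mapply(eff, steps[, 2], 2)
    cbind(GV = gv, MII = gv + d1, D3 = gv + d1 + d2)
}

#' Simulate a control/mutant GV-MII-D3 experiment with ground truth
#'
#' Builds per-gene expected expression rates from the nine-cluster decay
#' taxonomy (baseline plus signed \code{cluster_step_log2} steps across the
#' GV-to-MII and MII-to-D3 transitions), applies the three mutant effects
#' (global GV dosage reduction, attenuated degradation steps, attenuated
#' day-3 elevation), adds spike-in species whose absolute rates are identical
#' in every sample, then draws counts per sample: a log-normal library size
#' is allocated across the relative rates and each gene's count is drawn from
#' a negative binomial with the configured dispersion around its expected
#' count. Identical seeds give identical output.
#'
#' @param config a [simulationConfig()].
#'
#' @return A list with elements:
#' \describe{
#'   \item{experiment}{[OocyteExperiment-class] of simulated counts.}
#'   \item{spike_ref}{spike-in reference data.frame (\code{spike_id},
#'     \code{nominal_amount}).}
#'   \item{gene_sets}{list with \code{ZGA} (cluster VI members) and
#'     \code{M-decay} (clusters I and III).}
#'   \item{truth}{list with \code{gene} (per-gene data.frame: id, cluster),
#'     \code{rate} (3-d array gene x stage x genotype of expected expression
#'     rates), and \code{sample} (per-sample data.frame with the true
#'     absolute endogenous dosage).}
#' }
#' @export
simulateExperiment <- function(config = simulationConfig()) {
    validateSimulationConfig(config)
    set.seed(config$seed)

    n_endo <- sum(config$genes_per_cluster)
    cluster <- factor(rep(CLUSTER_LEVELS, config$genes_per_cluster),
                      levels = CLUSTER_LEVELS)
    gene_ids <- sprintf("gene_%04d", seq_len(n_endo))
    spike_ids <- sprintf("ERCC-%05d", seq_len(config$n_spike_ins))

    baseline <- stats::rnorm(n_endo, config$baseline_log2_mean,
                             config$baseline_log2_sd)
    steps <- CLUSTER_STEPS[as.character(cluster), , drop = FALSE]
    dosage_log2 <- log2(config$mutant_gv_dosage_factor)

    rate <- array(NA_real_, dim = c(n_endo, 3, 2),
                  dimnames = list(gene_ids, STAGE_LEVELS, GENOTYPE_LEVELS))
    rate[, , "control"] <- 2^build_log2_rates(baseline, steps,
        config$cluster_step_log2, FALSE, 0, 1, 1)
    rate[, , "mutant"] <- 2^build_log2_rates(baseline, steps,
        config$cluster_step_log2, TRUE, dosage_log2,
        config$mutant_decay_attenuation, config$mutant_zga_attenuation)

    lengths <- exp(stats::runif(n_endo, log(500), log(5000)))
    spike_len <- rep(1000, config$n_spike_ins)

    ## Spike absolute rates: log-uniform spread, scaled so spikes are the
    ## configured fraction of the expected control-GV library.
    endo_gv_total <- sum(rate[, "GV", "control"])
    spike_raw <- exp(stats::runif(config$n_spike_ins, log(1), log(100)))
    spike_rate <- spike_raw / sum(spike_raw) *
        endo_gv_total * config$spike_fraction / (1 - config$spike_fraction)

    design <- expand.grid(rep = seq_len(config$n_samples),
                          genotype = GENOTYPE_LEVELS, stage = STAGE_LEVELS,
                          stringsAsFactors = FALSE)
    sample_ids <- sprintf("%s_%s_%d", design$stage, design$genotype,
                          design$rep)

    sdlog <- sqrt(log(1 + config$library_size_cv^2))
    meanlog <- log(config$library_size_mean) - sdlog^2 / 2

    n_total <- n_endo + config$n_spike_ins
    counts <- matrix(0, n_total, nrow(design),
                     dimnames = list(c(gene_ids, spike_ids), sample_ids))
    dosage <- numeric(nrow(design))
    for (j in seq_len(nrow(design))) {
        r <- c(rate[, design$stage[j], design$genotype[j]], spike_rate)
        lib <- stats::rlnorm(1, meanlog, sdlog)
        mu <- lib * r / sum(r)
        counts[, j] <- stats::rnbinom(n_total, mu = mu,
                                      size = 1 / config$nb_dispersion)
        dosage[j] <- sum(rate[, design$stage[j], design$genotype[j]])
    }

    exp <- OocyteExperiment(counts,
                            gene_length = c(lengths, spike_len),
                            is_spike_in = c(rep(FALSE, n_endo),
                                            rep(TRUE, config$n_spike_ins)),
                            stage = design$stage, genotype = design$genotype)

    gene_sets <- list(
        "ZGA" = gene_ids[cluster == "VI"],
        "M-decay" = gene_ids[cluster %in% c("I", "III")])
    attr(gene_sets[["ZGA"]], "description") <-
        "zygotic genome activation transcripts (simulated truth)"
    attr(gene_sets[["M-decay"]], "description") <-
        "maternal-decay transcripts degraded during maturation (simulated truth)"

    truth <- list(
        gene = data.frame(gene_id = c(gene_ids, spike_ids),
                          true_cluster = c(as.character(cluster),
                                           rep("spike", config$n_spike_ins)),
                          stringsAsFactors = FALSE),
        rate = rate,
        spike_rate = stats::setNames(spike_rate, spike_ids),
        sample = data.frame(sample_id = sample_ids,
                            stage = design$stage, genotype = design$genotype,
                            true_dosage = dosage, stringsAsFactors = FALSE))

    list(experiment = exp,
         spike_ref = data.frame(spike_id = spike_ids,
                                nominal_amount = spike_rate,
                                stringsAsFactors = FALSE),
         gene_sets = gene_sets, truth = truth, config = config)
}

#' Count simulated genes per decay cluster
#'
#' @param truth the \code{truth} element of a [simulateExperiment()] result.
#' @return named integer vector over clusters I-IX.
#' @export
truthClusterCounts <- function(truth) {
    cl <- truth$gene$true_cluster
    table(factor(cl[cl != "spike"], levels = CLUSTER_LEVELS))
}
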