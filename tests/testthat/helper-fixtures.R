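## Shared fixtures and independent oracles, all built in code.

## Two-group single-stage NB experiment with known per-gene means.
make_two_group_exp <- function(mu_ctrl, mu_mut, dispersion, n = 3, seed,
                               stage = "MII") {
    set.seed(seed)
    G <- length(mu_ctrl)
    cts <- cbind(
        matrix(rnbinom(G * n, mu = rep(mu_ctrl, n), size = 1 / dispersion), G),
        matrix(rnbinom(G * n, mu = rep(mu_mut, n), size = 1 / dispersion), G))
    rownames(cts) <- sprintf("g%04d", seq_len(G))
    colnames(cts) <- sprintf("s%d", seq_len(2 * n))
    OocyteExperiment(cts, gene_length = rep(1000, G),
                     is_spike_in = rep(FALSE, G),
                     stage = rep(stage, 2 * n),
                     genotype = rep(c("control", "mutant"), each = n))
}

## Tiny handcrafted experiment: 3 genes (one spike-in) x 2 samples.
toy_experiment <- function() {
    cts <- matrix(c(10, 10, 5,
                    20, 40, 10), nrow = 3,
                  dimnames = list(c("gA", "gB", "spike1"), c("s1", "s2")))
    OocyteExperiment(cts, gene_length = c(1000, 2000, 1000),
                     is_spike_in = c(FALSE, FALSE, TRUE),
                     stage = c("GV", "GV"),
                     genotype = c("control", "mutant"))
}

## CalibratedMatrix with exact TPM values: a filler row absorbs the
## remainder so every column sums to 1e6.
exact_calibrated <- function(tpm_rows, sample_names = NULL) {
    tpm_rows <- as.matrix(tpm_rows)
    filler <- 1e6 - colSums(tpm_rows)
    stopifnot(all(filler >= 0))
    m <- rbind(tpm_rows, filler = filler)
    if (!is.null(sample_names)) colnames(m) <- sample_names
    new("CalibratedMatrix", tpm = m,
        scaleFactor = stats::setNames(rep(1, ncol(m)), colnames(m)),
        pseudocount = 1, provenance = list(all_zero_samples = character()))
}

## Independent naive Benjamini-Hochberg: for each element, the minimum of
## m * p_(j) / j over all ranks j at or above its own, capped at 1.
bh_bruteforce <- function(p) {
    m <- length(p)
    o <- order(p)
    out <- numeric(m)
    for (pos in seq_len(m)) {
        i <- o[pos]
        out[i] <- min(1, min(vapply(pos:m, function(j) m * p[o[j]] / j,
                                    numeric(1))))
    }
    out
}

## Direct hypergeometric upper tail by PMF summation with choose().
hyper_bruteforce <- function(overlap, list_size, set_size, universe) {
    ks <- overlap:min(list_size, set_size)
    ks <- ks[list_size - ks <= universe - set_size]
    if (overlap == 0) return(1)
    if (length(ks) == 0) return(0)
    sum(choose(set_size, ks) * choose(universe - set_size, list_size - ks)) /
        choose(universe, list_size)
}

## Mean silhouette width of a 1-d embedding under a 2-group labelling.
silhouette_1d <- function(x, labels) {
    labels <- as.character(labels)
    stopifnot(length(unique(labels)) == 2)
    s <- vapply(seq_along(x), function(i) {
        own <- labels == labels[i]
        a <- mean(abs(x[i] - x[own & seq_along(x) != i]))
        b <- mean(abs(x[i] - x[!own]))
        (b - a) / max(a, b)
    }, numeric(1))
    mean(s)
}

## Map interactome calls to the planted class labels of
## simulateInteractome().
interactome_predicted_class <- function(calls) {
    ifelse(calls$is_shared & calls$is_reduced_binding, "reduced",
    ifelse(calls$is_shared, "shared",
    ifelse(calls$is_wt_interactor, "wt_only",
    ifelse(calls$is_mut_interactor, "mut_only", "background"))))
}

## Cluster-size configuration for a decay-dominated maternal transcriptome
## (degradation clusters I-III dominate, elevation clusters are small),
## scaled down for test runtimes.
decay_dominated_sizes <- function() {
    round(c(1467, 5657, 1671, 2105, 231, 231, 100, 100, 100) / 10)
}
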