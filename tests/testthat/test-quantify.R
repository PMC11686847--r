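test_that("TPM follows its defining formula", {
    # single gene: any positive count gives TPM 1e6
    e1 <- OocyteExperiment(matrix(7, 1, 1, dimnames = list("g1", "s1")),
                           gene_length = 500, is_spike_in = FALSE,
                           stage = "GV", genotype = "control")
    expect_equal(unname(tpm(computeTPM(e1))[1, 1]), 1e6)

    # counts (10, 10), lengths (1000, 2000): hand evaluation of the formula
    e2 <- OocyteExperiment(matrix(c(10, 10), 2, 1,
                                  dimnames = list(c("g1", "g2"), "s1")),
                           gene_length = c(1000, 2000),
                           is_spike_in = c(FALSE, FALSE),
                           stage = "GV", genotype = "control")
    expect_equal(unname(tpm(computeTPM(e2))[, 1]),
                 c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

    # scale invariance: doubling a sample's counts leaves its TPM unchanged
    cts <- matrix(c(3, 11, 5, 6, 22, 10), 3, 2,
                  dimnames = list(paste0("g", 1:3), c("s1", "s2")))
    e3 <- OocyteExperiment(cts, gene_length = c(600, 1200, 2400),
                           is_spike_in = rep(FALSE, 3),
                           stage = c("GV", "GV"),
                           genotype = c("control", "control"))
    m <- tpm(computeTPM(e3))
    expect_equal(m[, 1], m[, 2], tolerance = 1e-12)

    # column sums are 1e6 for non-degenerate samples
    sim <- simulateExperiment(simulationConfig(
        genes_per_cluster = rep(10L, 9), n_samples = 2, n_spike_ins = 6,
        seed = 12))
    expect_equal(unname(colSums(tpm(computeTPM(sim$experiment)))),
                 rep(1e6, 12), tolerance = 1e-6 * 1e6)
})

test_that("TPM handles degenerate inputs per contract", {
    cts <- matrix(c(5, 3, 0, 0), 2, 2,
                  dimnames = list(c("g1", "g2"), c("ok", "empty")))
    e <- OocyteExperiment(cts, gene_length = c(1000, 1000),
                          is_spike_in = c(FALSE, FALSE),
                          stage = c("GV", "GV"),
                          genotype = c("control", "control"))
    m <- computeTPM(e)
    expect_equal(unname(tpm(m)[, "empty"]), c(0, 0))
    expect_identical(m@provenance$all_zero_samples, "empty")
})

test_that("spike-in calibration matches its definition and is idempotent", {
    # columns sum to 1e6; spike totals (1e5, 2e5, 1e5) -> median 1e5
    tpm3 <- cbind(s1 = c(5.0e5, 4.0e5, 1e5),
                  s2 = c(4.4e5, 3.6e5, 2e5),
                  s3 = c(5.4e5, 3.6e5, 1e5))
    rownames(tpm3) <- c("gA", "gB", "spike1")
    cm <- new("CalibratedMatrix", tpm = tpm3,
              scaleFactor = stats::setNames(rep(1, 3), colnames(tpm3)),
              pseudocount = 1,
              provenance = list(all_zero_samples = character()))
    e <- OocyteExperiment(matrix(1, 3, 3, dimnames = dimnames(tpm3)),
                          gene_length = rep(1000, 3),
                          is_spike_in = c(FALSE, FALSE, TRUE),
                          stage = rep("GV", 3), genotype = rep("control", 3))
    cal <- spikeInCalibrate(cm, e)
    # median spike total is 1e5; s2's spike total is twice that -> k = 0.5
    expect_equal(unname(scaleFactors(cal)), c(1, 0.5, 1))
    # identical samples -> k = 1 everywhere
    same <- cm@tpm[, c(1, 1, 1)]
    colnames(same) <- paste0("r", 1:3)
    cm_same <- new("CalibratedMatrix", tpm = same,
                   scaleFactor = stats::setNames(rep(1, 3), colnames(same)),
                   pseudocount = 1,
                   provenance = list(all_zero_samples = character()))
    e_same <- OocyteExperiment(matrix(1, 3, 3, dimnames = dimnames(same)),
                               gene_length = rep(1000, 3),
                               is_spike_in = c(FALSE, FALSE, TRUE),
                               stage = rep("GV", 3),
                               genotype = rep("control", 3))
    expect_equal(unname(scaleFactors(spikeInCalibrate(cm_same, e_same))),
                 rep(1, 3))
    # recalibrating changes nothing further: spike TPM is unchanged by
    # calibration, so the factors are already settled
    recal <- spikeInCalibrate(cal, e)
    expect_equal(scaleFactors(recal), scaleFactors(cal), tolerance = 1e-9)
    # calibration preserves within-sample gene ratios
    expect_equal(calibrated(cal)["gA", ] / calibrated(cal)["gB", ],
                 tpm(cal)["gA", ] / tpm(cal)["gB", ], tolerance = 1e-12)
    # zero spike signal errors with the sample named
    cm@tpm["spike1", "s2"] <- 0
    expect_error(spikeInCalibrate(cm, e), "s2")
})

test_that("calibration recovers the planted mutant-GV dosage reduction", {
    sim <- simulateExperiment(simulationConfig(n_samples = 5, seed = 21))
    cal <- spikeInCalibrate(computeTPM(sim$experiment), sim$experiment,
                            sim$spike_ref)
    d <- totalDosage(cal, sim$experiment)
    gv <- d$tests[d$tests$stage == "GV", ]
    expect_lt(abs(gv$ratio - 0.6), 0.05)
    expect_lt(gv$p, 0.05)   # the reduction is detected as significant
})

test_that("control dosage ordering matches truth; decay-dominated designs
           decrease across stages", {
    # default equal cluster sizes: estimates must reproduce truth ordering
    sim <- simulateExperiment(simulationConfig(
        genes_per_cluster = rep(50L, 9), n_samples = 3, seed = 22))
    cal <- spikeInCalibrate(computeTPM(sim$experiment), sim$experiment,
                            sim$spike_ref)
    d <- totalDosage(cal, sim$experiment)
    tr <- sim$truth$sample
    truth_means <- vapply(c("GV", "MII", "D3"), function(s)
        mean(tr$true_dosage[tr$stage == s & tr$genotype == "control"]),
        numeric(1))
    est_means <- vapply(c("GV", "MII", "D3"), function(s)
        d$groups$mean[d$groups$stage == s & d$groups$genotype == "control"],
        numeric(1))
    expect_identical(order(est_means), order(truth_means))

    # decay-dominated cluster sizes: maternal decay
    # dominates and control totals fall monotonically GV -> MII -> D3
    simp <- simulateExperiment(simulationConfig(
        genes_per_cluster = decay_dominated_sizes(), n_samples = 3,
        seed = 23))
    trp <- simp$truth$sample
    truth_p <- vapply(c("GV", "MII", "D3"), function(s)
        mean(trp$true_dosage[trp$stage == s & trp$genotype == "control"]),
        numeric(1))
    expect_true(all(diff(truth_p) < 0))
    calp <- spikeInCalibrate(computeTPM(simp$experiment), simp$experiment,
                             simp$spike_ref)
    dp <- totalDosage(calp, simp$experiment)
    est_p <- vapply(c("GV", "MII", "D3"), function(s)
        dp$groups$mean[dp$groups$stage == s & dp$groups$genotype == "control"],
        numeric(1))
    expect_true(all(diff(est_p) < 0))
    # mutant GV sits below control GV
    expect_lt(dp$tests$ratio[dp$tests$stage == "GV"], 1)
})

test_that("expression bins count genes per stratum", {
    cm <- exact_calibrated(rbind(g1 = c(0.5), g2 = c(3), g3 = c(15),
                                 g4 = c(20)), "s1")
    e <- OocyteExperiment(matrix(1, 5, 1,
                                 dimnames = list(rownames(tpm(cm)), "s1")),
                          gene_length = rep(1000, 5),
                          is_spike_in = c(rep(FALSE, 4), TRUE),
                          stage = "GV", genotype = "control")
    b <- expressionBins(cm, e, bin_edges = c(0, 2, 10, Inf))
    # filler row is the spike -> 4 endogenous genes: TPMs 0.5, 3, 15, 20
    expect_equal(b$mean_genes, c(1, 1, 2))
    expect_error(expressionBins(cm, e, bin_edges = c(0, 10, 2)),
                 "increasing")
})

test_that("a reduced GV dosage depletes the high-expression bin", {
    sim <- simulateExperiment(simulationConfig(n_samples = 3, seed = 24))
    cal <- spikeInCalibrate(computeTPM(sim$experiment), sim$experiment,
                            sim$spike_ref)
    b <- expressionBins(cal, sim$experiment)
    hi <- b[b$bin == "[10,Inf)" & b$stage == "GV", ]
    expect_lt(hi$mean_genes[hi$genotype == "mutant"],
              hi$mean_genes[hi$genotype == "control"])
})

test_that("PCA coordinates behave as a spectral embedding should", {
    sim <- simulateExperiment(simulationConfig(
        genes_per_cluster = rep(30L, 9), n_samples = 3, seed = 25))
    cal <- spikeInCalibrate(computeTPM(sim$experiment), sim$experiment,
                            sim$spike_ref)
    pca <- pcaQC(cal, sim$experiment, n_top_variable = 200)
    expect_true(all(pca$variance_explained >= 0))
    expect_lte(sum(pca$variance_explained), 1 + 1e-8)

    # control GV and D3 are far apart: stage separates on PC1
    keep <- pca$coordinates$genotype == "control" &
            pca$coordinates$stage %in% c("GV", "D3")
    expect_gt(silhouette_1d(pca$coordinates$PC1[keep],
                            pca$coordinates$stage[keep]), 0.5)

    # duplicated sample lands on identical coordinates
    cts <- SummarizedExperiment::assay(sim$experiment, "counts")
    dup <- cbind(cts, dup = cts[, 1])
    e2 <- OocyteExperiment(dup, gene_length = geneLength(sim$experiment),
                           is_spike_in = isSpikeIn(sim$experiment),
                           stage = c(as.character(stage(sim$experiment)),
                                     as.character(stage(sim$experiment))[1]),
                           genotype = c(as.character(genotype(sim$experiment)),
                                        as.character(genotype(sim$experiment))[1]))
    cal2 <- computeTPM(e2)
    p2 <- pcaQC(cal2, e2, n_top_variable = 200)
    co <- p2$coordinates
    expect_equal(co$PC1[co$sample_id == "dup"], co$PC1[1], tolerance = 1e-8)
    expect_equal(co$PC2[co$sample_id == "dup"], co$PC2[1], tolerance = 1e-8)

    # asking for more genes than available uses all, with a warning
    expect_warning(pcaQC(cal, sim$experiment, n_top_variable = 1e6),
                   "using all")
})
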