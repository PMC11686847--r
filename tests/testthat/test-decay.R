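## Build a control-only CalibratedMatrix + experiment whose per-stage log2
## profile is exact: TPM = 2^v - 1 so log2(TPM + 1) = v.
profile_fixture <- function(log2_values) {
    # log2_values: genes x 3 matrix of (GV, MII, D3) log2 levels
    tpm_rows <- 2^log2_values - 1
    colnames(tpm_rows) <- c("GV_1", "MII_1", "D3_1")
    cm <- exact_calibrated(tpm_rows)
    e <- OocyteExperiment(
        matrix(1, nrow(tpm(cm)), 3, dimnames = dimnames(tpm(cm))),
        gene_length = rep(1000, nrow(tpm(cm))),
        is_spike_in = c(rep(FALSE, nrow(log2_values)), TRUE),
        stage = c("GV", "MII", "D3"), genotype = rep("control", 3))
    list(cm = cm, exp = e)
}

test_that("stage profiles are the median of log2(TPM + 1)", {
    # TPM 3 -> log2(4) = 2; single sample per cell equals that sample
    v <- rbind(gX = c(2, 4, 4))
    fx <- profile_fixture(v)
    prof <- stageProfiles(fx$cm, fx$exp, genotypes = "control")
    expect_equal(unname(prof@value["gX", , "control"]), c(2, 4, 4))
    expect_equal(unname(prof@delta["gX", , "control"]), c(2, 0))

    # median of three replicate samples: TPM (0, 10, 1000) -> log2(11)
    tpm_rows <- matrix(c(0, 10, 1000), 1, 3,
                       dimnames = list("gM", c("a", "b", "c")))
    cm <- exact_calibrated(tpm_rows)
    e <- OocyteExperiment(matrix(1, 2, 3, dimnames = dimnames(tpm(cm))),
                          gene_length = c(1000, 1000),
                          is_spike_in = c(FALSE, TRUE),
                          stage = rep("GV", 3), genotype = rep("control", 3))
    # GV-only data: requesting all three stages must error, listing cells
    expect_error(stageProfiles(cm, e, genotypes = "control"), "MII control")
    # so check the median through a full fixture instead
    v3 <- rbind(g1 = c(log2(11), log2(11), log2(11)))
    fx3 <- profile_fixture(v3)
    prof3 <- stageProfiles(fx3$cm, fx3$exp, genotypes = "control")
    expect_equal(unname(prof3@value["g1", "GV", "control"]), log2(11))
})

test_that("the nine-cluster truth table is reproduced exhaustively", {
    # all 9 delta combinations at three baselines: 27 cases
    deltas <- expand.grid(d1 = c(-2, 0, 2), d2 = c(-2, 0, 2))
    expected_by_key <- c("-2 0" = "I", "0 -2" = "II", "-2 -2" = "III",
                         "0 0" = "IV", "2 0" = "V", "0 2" = "VI",
                         "2 2" = "VII", "-2 2" = "VIII", "2 -2" = "IX")
    rows <- list(); expected <- character()
    for (b in c(6, 8, 10)) for (i in seq_len(nrow(deltas))) {
        gv <- b; mii <- b + deltas$d1[i]; d3 <- mii + deltas$d2[i]
        rows[[length(rows) + 1]] <- c(gv, mii, d3)
        expected <- c(expected,
                      expected_by_key[paste(deltas$d1[i], deltas$d2[i])])
    }
    m <- do.call(rbind, rows)
    rownames(m) <- sprintf("case_%02d", seq_len(nrow(m)))
    fx <- profile_fixture(m)
    prof <- stageProfiles(fx$cm, fx$exp, genotypes = "control")
    map <- classifyDecayClusters(prof, fx$cm, fx$exp)
    got <- as.character(map$cluster[match(rownames(m), map$gene_id)])
    expect_identical(got, unname(expected))
})

test_that("threshold boundaries are inclusive and the floor filters", {
    # |delta| exactly equal to fc_log2 counts as changed
    m <- rbind(at_minus1 = c(8, 7, 7),    # delta1 = -1 -> degraded -> I
               at_plus1  = c(8, 9, 9),    # delta1 = +1 -> elevated -> V
               just_in   = c(8, 7.01, 7.01))
    fx <- profile_fixture(m)
    prof <- stageProfiles(fx$cm, fx$exp, genotypes = "control")
    map <- classifyDecayClusters(prof, fx$cm, fx$exp, fc_log2 = 1)
    expect_equal(as.character(map$cluster[map$gene_id == "at_minus1"]), "I")
    expect_equal(as.character(map$cluster[map$gene_id == "at_plus1"]), "V")
    expect_equal(as.character(map$cluster[map$gene_id == "just_in"]), "IV")

    # genes never above the control TPM floor are filtered; spikes always
    low <- rbind(dim = c(1, 1, 1))   # TPM = 1 at every stage
    fx2 <- profile_fixture(low)
    prof2 <- stageProfiles(fx2$cm, fx2$exp, genotypes = "control")
    map2 <- classifyDecayClusters(prof2, fx2$cm, fx2$exp, expr_floor = 2)
    expect_equal(as.character(map2$cluster[map2$gene_id == "dim"]),
                 "filtered")
    expect_equal(as.character(map2$cluster[map2$gene_id == "filler"]),
                 "filtered")
    # every analysed gene gets exactly one label
    expect_false(anyNA(map2$cluster))
})

test_that("cluster assignment ignores a global scale through the deltas", {
    sim <- simulateExperiment(simulationConfig(
        genes_per_cluster = rep(30L, 9), n_samples = 2, seed = 31))
    cal <- spikeInCalibrate(computeTPM(sim$experiment), sim$experiment,
                            sim$spike_ref)
    prof <- stageProfiles(cal, sim$experiment)
    m1 <- classifyDecayClusters(prof, cal, sim$experiment)
    m2 <- classifyDecayClusters(prof, cal, sim$experiment)  # constant = 1
    expect_identical(m1$cluster, m2$cluster)
})

test_that("synthetic trajectories recover their clusters and show the
           planted mutant impairment", {
    sim <- simulateExperiment(simulationConfig(seed = 32))
    cal <- spikeInCalibrate(computeTPM(sim$experiment), sim$experiment,
                            sim$spike_ref)
    prof <- stageProfiles(cal, sim$experiment)
    map <- classifyDecayClusters(prof, cal, sim$experiment)
    truth <- sim$truth$gene$true_cluster
    keep <- map$cluster != "filtered" & truth != "spike"
    expect_gt(mean(as.character(map$cluster[keep]) == truth[keep]), 0.9)

    tr <- clusterTrajectories(map, prof)
    imp <- tr$impairment
    for (cl in c("I", "II", "III")) {
        expect_gt(imp$impairment[imp$cluster == cl], 0)
        expect_lt(imp$impairment_p[imp$cluster == cl], 0.01)
    }
    # ZGA cluster: mutant day-3 elevation falls short of control
    expect_gt(imp$elevation_deficit[imp$cluster == "VI"], 0)
    # identical profiles give zero impairment
    prof_same <- prof
    prof_same@value[, , "mutant"] <- prof@value[, , "control"]
    prof_same@delta[, , "mutant"] <- prof@delta[, , "control"]
    tr0 <- clusterTrajectories(map, prof_same)
    expect_true(all(abs(tr0$impairment$impairment) < 1e-12, na.rm = TRUE))
})

test_that("Sankey flows match a manual tally and conserve marginals", {
    mk <- function(ids, calls) {
        data.frame(gene_id = ids, log2_fc = 0, p = 1, padj = 1,
                   call = factor(calls, levels = c("up", "down", "ns")))
    }
    ids <- paste0("g", 1:5)
    deg <- list(GV = mk(ids, c("up", "up", "ns", "down", "ns")),
                MII = mk(ids, c("up", "ns", "ns", "down", "down")),
                D3 = mk(ids, c("ns", "ns", "up", "down", "down")))
    fl <- transitionSankey(deg)
    expect_equal(fl$GV_MII["up", "up"], 1)
    expect_equal(fl$GV_MII["up", "ns"], 1)
    expect_equal(fl$GV_MII["down", "down"], 1)
    expect_equal(fl$GV_MII["ns", "down"], 1)
    expect_equal(fl$GV_MII["ns", "ns"], 1)
    expect_equal(sum(fl$GV_MII), 5)
    # conservation: row sums = source status counts; col sums = destination
    expect_equal(unname(rowSums(fl$GV_MII)), c(2, 1, 2))
    expect_equal(unname(colSums(fl$GV_MII)), c(1, 2, 2))
    expect_equal(unname(rowSums(fl$MII_D3)), unname(colSums(fl$GV_MII)))

    # all-ns: all mass on ns -> ns
    nsdeg <- list(GV = mk(ids, rep("ns", 5)), MII = mk(ids, rep("ns", 5)),
                  D3 = mk(ids, rep("ns", 5)))
    fl0 <- transitionSankey(nsdeg)
    expect_equal(fl0$GV_MII["ns", "ns"], 5)
    expect_equal(sum(fl0$GV_MII), 5)

    # the common universe is the intersection; empty intersection errors
    deg$MII <- mk(paste0("h", 1:5), rep("ns", 5))
    expect_error(transitionSankey(deg), "universe")
})

test_that("quadrant labels partition the changed MII DEGs", {
    ids <- paste0("g", 1:8)
    delta1 <- c(-3, -3, 3, 3, -3, 3, 0.5, -3)
    calls <- c("up", "down", "up", "down", "ns", "ns", "up", "up")
    value <- array(0, c(8, 3, 1), dimnames = list(ids, c("GV", "MII", "D3"),
                                                  "control"))
    delta <- array(0, c(8, 2, 1), dimnames = list(ids, c("MII-GV", "D3-MII"),
                                                  "control"))
    delta[, "MII-GV", "control"] <- delta1
    prof <- new("StageProfile", value = value, delta = delta, pseudocount = 1)
    deg <- data.frame(gene_id = ids, log2_fc = c(2, -2, 2, -2, 0, 0, 2, 2),
                      p = 0.001, padj = 0.001,
                      call = factor(calls, levels = c("up", "down", "ns")))
    q <- quadrantAnalysis(deg, prof, fc_log2 = 1)
    expected <- c("degradation_escape", "deepened_decay", "amplified_rise",
                  "suppressed_rise", NA, NA, NA, "degradation_escape")
    expect_identical(q$genes$quadrant[match(ids, q$genes$gene_id)], expected)
    expect_equal(unname(q$counts["degradation_escape"]), 2)
    # assigned genes are exactly the changed DEGs
    changed <- calls != "ns" & abs(delta1) > 1
    expect_identical(!is.na(q$genes$quadrant), changed)
})

test_that("decay-impaired transcripts land in the degradation-escape
           quadrant on synthetic data", {
    sim <- simulateExperiment(simulationConfig(seed = 33))
    cal <- spikeInCalibrate(computeTPM(sim$experiment), sim$experiment,
                            sim$spike_ref)
    prof <- stageProfiles(cal, sim$experiment)
    deg_mii <- runDifferential(sim$experiment, "MII")
    q <- quadrantAnalysis(deg_mii, prof)
    esc <- q$genes$gene_id[!is.na(q$genes$quadrant) &
                           q$genes$quadrant == "degradation_escape"]
    truth <- sim$truth$gene
    # escapers are overwhelmingly genes whose control trajectory degrades
    # GV -> MII (clusters I, III and VIII)
    frac_decay <- mean(truth$true_cluster[match(esc, truth$gene_id)] %in%
                       c("I", "III", "VIII"))
    expect_gt(length(esc), 50)
    expect_gt(frac_decay, 0.9)
})
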