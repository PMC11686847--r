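## Maternal transcript decay taxonomy over GV -> MII -> D3, defined on
## control trajectories; mutant genes inherit the control-defined cluster so
## mutant trajectories can be overlaid on the same classes.

#' Per-gene stage summaries and transitions
#'
#' For every gene, stage and genotype, takes the median over replicate
#' samples of \code{log2(calibrated TPM + pseudocount)} and derives the two
#' transitions \code{MII - GV} and \code{D3 - MII} per genotype.
#'
#' @param mat a [CalibratedMatrix-class].
#' @param exp the matching [OocyteExperiment-class].
#' @param genotypes genotypes to profile (default both).
#' @return A [StageProfile-class].
#' @export
stageProfiles <- function(mat, exp, genotypes = GENOTYPE_LEVELS) {
    cal <- calibrated(mat)
    st <- as.character(stage(exp))
    gt <- as.character(genotype(exp))
    missing <- character()
    for (g in genotypes) for (s in STAGE_LEVELS)
        if (!any(st == s & gt == g)) missing <- c(missing, paste(s, g))
    if (length(missing))
        stop("no samples for cell(s): ", paste(missing, collapse = "; "),
             call. = FALSE)
    pc <- mat@pseudocount
    value <- array(NA_real_, dim = c(nrow(cal), 3, length(genotypes)),
                   dimnames = list(rownames(cal), STAGE_LEVELS, genotypes))
    for (g in genotypes) for (s in STAGE_LEVELS) {
        cols <- which(st == s & gt == g)
        value[, s, g] <- apply(log2(cal[, cols, drop = FALSE] + pc), 1,
                               stats::median)
    }
    delta <- array(NA_real_, dim = c(nrow(cal), 2, length(genotypes)),
                   dimnames = list(rownames(cal), c("MII-GV", "D3-MII"),
                                   genotypes))
    delta[, "MII-GV", ] <- value[, "MII", ] - value[, "GV", ]
    delta[, "D3-MII", ] <- value[, "D3", ] - value[, "MII", ]
    new("StageProfile", value = value, delta = delta, pseudocount = pc)
}

## status of one transition: -1 degraded, 0 stable, +1 elevated.
## |delta| exactly at the threshold counts as changed ("2-fold" is >= 2-fold).
transition_status <- function(delta, fc_log2) {
    ifelse(delta <= -fc_log2, -1L, ifelse(delta >= fc_log2, 1L, 0L))
}

status_to_cluster <- function(s1, s2) {
    key <- paste(s1, s2)
    map <- c("-1 0" = "I", "0 -1" = "II", "-1 -1" = "III", "0 0" = "IV",
             "1 0" = "V", "0 1" = "VI", "1 1" = "VII", "-1 1" = "VIII",
             "1 -1" = "IX")
    unname(map[key])
}

#' Classify control transcript trajectories into decay clusters I-IX
#'
#' Genes expressed in the control group (median calibrated TPM above
#' \code{expr_floor} at one or more stages) are classified by the status of
#' their two control transitions: degraded when the log2 change is at or
#' below \code{-fc_log2}, elevated at or above \code{+fc_log2}, stable
#' otherwise. The 3x3 status combinations define the clusters: I degraded
#' then stable, II stable then degraded, III continuously degraded, IV
#' stable, V elevated then stable, VI stable then elevated (the ZGA
#' cluster), VII continuously elevated, VIII degraded then elevated, IX
#' elevated then degraded. Genes failing the expression filter are labelled
#' \code{filtered}. Spike-in rows are always filtered out.
#'
#' @param profile a [StageProfile-class] containing the control genotype.
#' @param mat the [CalibratedMatrix-class] the profile came from.
#' @param exp the matching [OocyteExperiment-class].
#' @param fc_log2 transition threshold in log2 units (default 1, i.e.
#'   2-fold; the boundary is inclusive).
#' @param expr_floor control calibrated-TPM floor (default 2): keep genes
#'   with median control TPM > expr_floor at >= 1 stage.
#' @return data.frame \code{gene_id}, \code{cluster} (factor I-IX or
#'   \code{filtered}); filter parameters in attribute \code{"filter"}.
#' @export
classifyDecayClusters <- function(profile, mat, exp, fc_log2 = 1,
                                  expr_floor = 2) {
    cal <- calibrated(mat)
    st <- as.character(stage(exp))
    gt <- as.character(genotype(exp))
    ctrl_med <- sapply(STAGE_LEVELS, function(s) {
        cols <- which(st == s & gt == "control")
        apply(cal[, cols, drop = FALSE], 1, stats::median)
    })
    expressed <- apply(ctrl_med, 1, max) > expr_floor
    expressed[isSpikeIn(exp)] <- FALSE

    d <- profile@delta[, , "control"]
    s1 <- transition_status(d[, "MII-GV"], fc_log2)
    s2 <- transition_status(d[, "D3-MII"], fc_log2)
    cl <- ifelse(expressed, status_to_cluster(s1, s2), "filtered")
    out <- data.frame(gene_id = rownames(cal),
                      cluster = factor(cl, levels = c(CLUSTER_LEVELS,
                                                      "filtered")),
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "filter") <- list(rule = "median control calibrated TPM > floor at >= 1 stage",
                                expr_floor = expr_floor, fc_log2 = fc_log2)
    out
}

## Defining transitions per cluster: which of the two transitions carry a
## degradation (-1) or elevation (+1) in the cluster definition.
cluster_defining <- function(cluster, sign) {
    s <- CLUSTER_STEPS[cluster, ]
    which(s == sign)
}

#' Per-cluster median trajectories and mutant decay-impairment statistics
#'
#' For each cluster and genotype, the median over member genes of the stage
#' summaries gives the cluster trajectory. For clusters whose definition
#' includes a degradation step, the impairment statistic is the median over
#' member genes of \code{(mutant delta) - (control delta)} averaged over the
#' defining degrading transitions — positive when mutant decay is shallower
#' than control — with a one-sided Wilcoxon signed-rank test (alternative:
#' impairment > 0) paired over member genes. For clusters defined by
#' elevation, the analogous elevation deficit \code{(control delta) -
#' (mutant delta)} over the defining elevating transitions is reported.
#'
#' @param map cluster assignments from [classifyDecayClusters()].
#' @param profile a [StageProfile-class] with both genotypes.
#' @return list with \code{trajectories} (cluster, genotype, stage, median
#'   value, n genes) and \code{impairment} (cluster, statistic, p,
#'   elevation_deficit, elevation_p).
#' @export
clusterTrajectories <- function(map, profile) {
    genotypes <- dimnames(profile@value)[[3]]
    if (!all(GENOTYPE_LEVELS %in% genotypes))
        stop("profile must contain both genotypes", call. = FALSE)
    idx <- match(map$gene_id, dimnames(profile@value)[[1]])
    traj <- list(); imp <- list()
    for (cl in CLUSTER_LEVELS) {
        members <- idx[!is.na(map$cluster) & map$cluster == cl]
        if (length(members) == 0) {
            warning("cluster ", cl, " is empty; trajectory omitted")
            next
        }
        for (g in GENOTYPE_LEVELS)
            traj[[paste(cl, g)]] <- data.frame(
                cluster = cl, genotype = g, stage = STAGE_LEVELS,
                median_log2 = apply(profile@value[members, , g, drop = FALSE],
                                    2, stats::median),
                n_genes = length(members), stringsAsFactors = FALSE)

        ddiff <- profile@delta[members, , "mutant", drop = FALSE] -
                 profile@delta[members, , "control", drop = FALSE]
        deg_tr <- cluster_defining(cl, -1L)
        elev_tr <- cluster_defining(cl, 1L)
        stat <- p <- est <- ep <- NA_real_
        if (length(deg_tr)) {
            per_gene <- rowMeans(ddiff[, deg_tr, 1, drop = FALSE])
            stat <- stats::median(per_gene)
            p <- stats::wilcox.test(per_gene, alternative = "greater",
                                    exact = FALSE)$p.value
        }
        if (length(elev_tr)) {
            per_gene <- -rowMeans(ddiff[, elev_tr, 1, drop = FALSE])
            est <- stats::median(per_gene)
            ep <- stats::wilcox.test(per_gene, alternative = "greater",
                                     exact = FALSE)$p.value
        }
        imp[[cl]] <- data.frame(cluster = cl, n_genes = length(members),
                                impairment = stat, impairment_p = p,
                                elevation_deficit = est, elevation_p = ep,
                                stringsAsFactors = FALSE)
    }
    list(trajectories = do.call(rbind, c(traj, list(make.row.names = FALSE))),
         impairment = do.call(rbind, c(imp, list(make.row.names = FALSE))))
}

#' Expression-status transition flows across stages
#'
#' Given per-stage DEG tables ([callDegs()]) over the stages GV, MII and D3,
#' counts — on the common gene universe — how genes move between the status
#' categories up / down / ns across the GV-to-MII and MII-to-D3 transitions,
#' as in a Sankey diagram. Row sums of each flow matrix equal the source
#' stage's status counts on the universe.
#'
#' @param deg_by_stage named list of DEG tables; names must include
#'   \code{GV}, \code{MII}, \code{D3}.
#' @return list of two 3x3 matrices \code{GV_MII} and \code{MII_D3}
#'   (rows: source status; columns: destination status) plus the
#'   \code{universe} of genes used.
#' @export
transitionSankey <- function(deg_by_stage) {
    if (!all(STAGE_LEVELS %in% names(deg_by_stage)))
        stop("need DEG tables named GV, MII, D3", call. = FALSE)
    ids <- Reduce(intersect, lapply(deg_by_stage[STAGE_LEVELS],
                                    function(d) d$gene_id))
    if (length(ids) == 0)
        stop("empty gene universe across stages", call. = FALSE)
    status <- sapply(STAGE_LEVELS, function(s) {
        d <- deg_by_stage[[s]]
        as.character(d$call[match(ids, d$gene_id)])
    })
    lv <- c("up", "down", "ns")
    flow <- function(a, b)
        table(factor(status[, a], levels = lv),
              factor(status[, b], levels = lv))
    list(GV_MII = unclass(flow("GV", "MII")),
         MII_D3 = unclass(flow("MII", "D3")),
         universe = ids)
}

#' Quadrant analysis: developmental change vs mutant effect at MII
#'
#' Plots (conceptually) each gene at x = control GV-to-MII change
#' (\code{delta1}) and y = mutant-vs-control log2 fold change at MII.
#' Genes that are MII DEGs (call up or down) and developmentally changed
#' (\code{|delta1| > fc_log2}, strict) are assigned one of four quadrants.
#' The headline quadrant — transcripts upregulated in mutant MII oocytes
#' that should have been degraded across maturation (\code{delta1 <
#' -fc_log2}) — captures the failure of maternal mRNA clearance.
#'
#' @param deg_mii DEG table at MII (from [callDegs()]).
#' @param profile a [StageProfile-class] containing the control genotype.
#' @param fc_log2 developmental-change threshold (default 1).
#' @return list with \code{genes} (gene_id, delta1, log2_fc, call,
#'   quadrant) and \code{counts} (per-quadrant totals);
#'   quadrant labels: \code{degradation_escape} (up, delta1 < -fc),
#'   \code{amplified_rise} (up, delta1 > fc), \code{deepened_decay} (down,
#'   delta1 < -fc), \code{suppressed_rise} (down, delta1 > fc);
#'   unassigned genes get \code{NA}.
#' @export
quadrantAnalysis <- function(deg_mii, profile, fc_log2 = 1) {
    d1 <- profile@delta[, "MII-GV", "control"]
    ids <- intersect(deg_mii$gene_id, names(d1))
    x <- d1[ids]
    dm <- deg_mii[match(ids, deg_mii$gene_id), ]
    quad <- rep(NA_character_, length(ids))
    deg <- dm$call != "ns" & abs(x) > fc_log2
    quad[deg & dm$call == "up"   & x < -fc_log2] <- "degradation_escape"
    quad[deg & dm$call == "up"   & x >  fc_log2] <- "amplified_rise"
    quad[deg & dm$call == "down" & x < -fc_log2] <- "deepened_decay"
    quad[deg & dm$call == "down" & x >  fc_log2] <- "suppressed_rise"
    genes <- data.frame(gene_id = ids, delta1 = unname(x),
                        log2_fc = dm$log2_fc, call = as.character(dm$call),
                        quadrant = quad, stringsAsFactors = FALSE)
    lv <- c("degradation_escape", "amplified_rise", "deepened_decay",
            "suppressed_rise")
    list(genes = genes,
         counts = table(factor(quad, levels = lv)))
}
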