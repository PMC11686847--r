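#' Run the full maternal mRNA homeostasis pipeline
#'
#' Wires the analysis stages end to end on an in-memory experiment:
#' quantification (TPM + spike-in calibration), per-stage differential
#' expression between genotypes, decay-cluster classification with
#' trajectories, Sankey transition flows and the MII quadrant analysis,
#' gene-set overlaps of per-stage DEG lists, and — when a protein-intensity
#' table is supplied — the differential interactome calls. All result
#' tables are written through [writeResults()] with a JSON manifest; any
#' stage error aborts with the stage name. The pipeline is a pure function
#' of its inputs and thresholds: rerunning on the same inputs reproduces
#' identical outputs.
#'
#' @param exp an [OocyteExperiment-class].
#' @param spike_ref spike-in reference data.frame (required for
#'   calibration/dosage).
#' @param gene_sets named list of gene-id vectors (e.g. ZGA, M-decay);
#'   optional.
#' @param intensities optional protein-intensity matrix for the interactome
#'   stage.
#' @param out_dir output directory; when \code{NULL} nothing is written.
#' @param fc_log2,alpha DEG thresholds (defaults 1 and 0.05).
#' @param expr_floor decay-cluster expression filter (default 2 TPM).
#' @param enrich_log2,reduce_log2 interactome thresholds (defaults
#'   \code{log2(10)} and \code{log2(2/3)}).
#' @param seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return list of all stage results (\code{calibrated}, \code{dosage},
#'   \code{bins}, \code{pca}, \code{deg} per stage, \code{clusters},
#'   \code{trajectories}, \code{sankey}, \code{quadrant}, \code{overlaps},
#'   \code{interactome}, \code{manifest}).
#' @export
runPipeline <- function(exp, spike_ref, gene_sets = NULL, intensities = NULL,
                        out_dir = NULL, fc_log2 = 1, alpha = 0.05,
                        expr_floor = 2, enrich_log2 = log2(10),
                        reduce_log2 = log2(2 / 3), seed = NULL) {
    run_stage <- function(name, fun) {
        tryCatch(fun(), error = function(e)
            stop(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
    }
    if (missing(spike_ref) || is.null(spike_ref))
        stop("pipeline stage 'quantify' failed: spike-in reference is required",
             call. = FALSE)

    cal <- run_stage("quantify", function()
        spikeInCalibrate(computeTPM(exp), exp, spike_ref))
    dosage <- run_stage("dosage", function() totalDosage(cal, exp))
    bins <- run_stage("bins", function() expressionBins(cal, exp))
    pca <- run_stage("pca", function()
        pcaQC(cal, exp, n_top_variable = min(500, sum(!isSpikeIn(exp)))))

    deg <- run_stage("differential", function() {
        out <- lapply(STAGE_LEVELS, function(s)
            runDifferential(exp, s, fc_threshold = fc_log2, alpha = alpha))
        names(out) <- STAGE_LEVELS
        out
    })

    profile <- run_stage("profiles", function() stageProfiles(cal, exp))
    clusters <- run_stage("decay_clusters", function()
        classifyDecayClusters(profile, cal, exp, fc_log2 = fc_log2,
                              expr_floor = expr_floor))
    traj <- run_stage("trajectories", function()
        clusterTrajectories(clusters, profile))
    sankey <- run_stage("sankey", function() transitionSankey(deg))
    quadrant <- run_stage("quadrant", function()
        quadrantAnalysis(deg$MII, profile, fc_log2 = fc_log2))

    overlaps <- NULL
    if (!is.null(gene_sets)) {
        overlaps <- run_stage("genesets", function() {
            rows <- list()
            for (st in STAGE_LEVELS) {
                d <- deg[[st]]
                uni <- nrow(d)
                for (dir in c("up", "down")) {
                    lst <- d$gene_id[d$call == dir]
                    if (length(lst) == 0) next
                    for (sn in names(gene_sets))
                        rows[[paste(st, dir, sn)]] <- overlapPercentage(
                            lst, gene_sets[[sn]], set_name = sn,
                            list_name = paste0(st, "_", dir), universe = uni)
                }
            }
            do.call(rbind, c(rows, list(make.row.names = FALSE)))
        })
    }

    interactome <- NULL
    if (!is.null(intensities)) {
        interactome <- run_stage("interactome", function() {
            calls <- callInteractors(intensities, enrich_log2 = enrich_log2,
                                     reduce_log2 = reduce_log2)
            list(calls = calls, venn = vennSets(calls),
                 reduced = differentialBinding(calls))
        })
    }

    manifest <- NULL
    if (!is.null(out_dir)) {
        tables <- list(
            dosage_samples = dosage$samples,
            dosage_groups = dosage$groups,
            dosage_tests = dosage$tests,
            expression_bins = bins,
            pca_coordinates = pca$coordinates,
            decay_clusters = clusters,
            cluster_trajectories = traj$trajectories,
            cluster_impairment = traj$impairment,
            sankey_gv_mii = as.data.frame.table(sankey$GV_MII,
                                                responseName = "n"),
            sankey_mii_d3 = as.data.frame.table(sankey$MII_D3,
                                                responseName = "n"),
            quadrant_genes = quadrant$genes)
        for (st in STAGE_LEVELS)
            tables[[paste0("deg_", st)]] <- deg[[st]]
        if (!is.null(overlaps)) tables$geneset_overlaps <- overlaps
        if (!is.null(interactome))
            tables$interactome_calls <- interactome$calls
        manifest <- run_stage("write", function()
            writeResults(tables, out_dir,
                         parameters = list(fc_log2 = fc_log2, alpha = alpha,
                                           expr_floor = expr_floor,
                                           enrich_log2 = enrich_log2,
                                           reduce_log2 = reduce_log2),
                         seed = seed))
    }

    list(calibrated = cal, dosage = dosage, bins = bins, pca = pca,
         deg = deg, profile = profile, clusters = clusters,
         trajectories = traj, sankey = sankey, quadrant = quadrant,
         overlaps = overlaps, interactome = interactome,
         manifest = manifest)
}
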