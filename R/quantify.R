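#' Compute TPM from counts and effective lengths
#'
#' \code{tpm[g,s] = 1e6 * (count[g,s]/length[g]) / sum_g'(count[g',s]/length[g'])}.
#' All rows — endogenous genes and spike-ins — share the per-million
#' denominator, so spike rows carry absolute information into calibration.
#' An all-zero sample yields an all-zero column, flagged in the provenance
#' rather than erroring.
#'
#' @param exp an [OocyteExperiment-class].
#' @param pseudocount value recorded for downstream log2(x + pseudocount)
#'   transforms (default 1).
#' @return A [CalibratedMatrix-class] with all scale factors 1.
#' @export
computeTPM <- function(exp, pseudocount = 1) {
    len <- geneLength(exp)
    if (any(len <= 0)) stop("gene lengths must be positive", call. = FALSE)
    cts <- SummarizedExperiment::assay(exp, "counts")
    rpk <- cts / len
    denom <- colSums(rpk)
    zero <- denom == 0
    denom[zero] <- 1        # all-zero column stays all-zero
    tpm <- sweep(rpk, 2, denom, "/") * 1e6
    new("CalibratedMatrix", tpm = tpm,
        scaleFactor = stats::setNames(rep(1, ncol(tpm)), colnames(tpm)),
        pseudocount = pseudocount,
        provenance = list(all_zero_samples = colnames(tpm)[zero]))
}

#' Calibrate TPM to absolute dosage using spike-ins
#'
#' Spike-in species are added in identical absolute amounts to every sample,
#' so the per-sample spike TPM total is inversely proportional to the
#' sample's endogenous mRNA content. The calibration factor
#' \eqn{k_s = \mathrm{median}_s(\mathrm{spikeTPM}_s) / \mathrm{spikeTPM}_s}
#' (median sample as anchor, robust to a single degraded oocyte) rescales
#' each column so endogenous calibrated totals are comparable across samples
#' as absolute per-cell mRNA dosage.
#'
#' @param mat a [CalibratedMatrix-class] from [computeTPM()].
#' @param exp the matching [OocyteExperiment-class].
#' @param spike_ref optional spike-in reference data.frame
#'   (\code{spike_id}, \code{nominal_amount}); when given, every referenced
#'   spike id must be flagged \code{is_spike_in} in the experiment.
#' @return A new [CalibratedMatrix-class] with per-sample scale factors.
#' @export
spikeInCalibrate <- function(mat, exp, spike_ref = NULL) {
    spike <- isSpikeIn(exp)
    if (!any(spike)) stop("experiment contains no spike-in rows", call. = FALSE)
    if (!is.null(spike_ref)) {
        missing <- setdiff(spike_ref$spike_id, rownames(exp)[spike])
        if (length(missing))
            stop("spike ids in reference not flagged in experiment: ",
                 paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    # totals on the current (calibrated) scale, so recalibration is a no-op
    spike_tot <- colSums(calibrated(mat)[spike, , drop = FALSE])
    zero <- spike_tot <= 0
    if (any(zero))
        stop("sample(s) with zero spike-in signal: ",
             paste(colnames(tpm(mat))[zero], collapse = ", "), call. = FALSE)
    anchor <- stats::median(spike_tot)
    k <- anchor / spike_tot
    prov <- mat@provenance
    prov$calibration <- list(method = "spike-in median anchor",
                             anchor_spike_tpm = anchor,
                             n_spikes = sum(spike))
    new("CalibratedMatrix", tpm = tpm(mat),
        scaleFactor = mat@scaleFactor * k,
        pseudocount = mat@pseudocount, provenance = prov)
}

group_key <- function(exp) {
    interaction(stage(exp), genotype(exp), sep = ".", drop = FALSE)
}

#' Per-sample absolute mRNA dosage and group comparisons
#'
#' Sums calibrated TPM over endogenous (non-spike) rows per sample, then
#' summarises each stage-by-genotype group (mean, SD, n) and compares
#' control with mutant within each stage by a two-sided Welch t-test on the
#' per-sample totals.
#'
#' @param mat a calibrated [CalibratedMatrix-class].
#' @param exp the matching [OocyteExperiment-class].
#' @return list with \code{samples} (per-sample totals), \code{groups}
#'   (per-group mean/SD/n) and \code{tests} (per-stage Welch comparison,
#'   one row per stage with both genotypes present).
#' @export
totalDosage <- function(mat, exp) {
    endo <- !isSpikeIn(exp)
    totals <- colSums(calibrated(mat)[endo, , drop = FALSE])
    samples <- data.frame(sample_id = colnames(exp),
                          stage = as.character(stage(exp)),
                          genotype = as.character(genotype(exp)),
                          total = unname(totals), stringsAsFactors = FALSE)
    grp <- split(samples$total, list(samples$stage, samples$genotype),
                 sep = ".")
    used <- vapply(grp, length, integer(1)) > 0
    groups <- do.call(rbind, lapply(names(grp)[used], function(g) {
        v <- grp[[g]]
        parts <- strsplit(g, ".", fixed = TRUE)[[1]]
        data.frame(stage = parts[1], genotype = parts[2], n = length(v),
                   mean = mean(v), sd = stats::sd(v), stringsAsFactors = FALSE)
    }))
    tests <- do.call(rbind, lapply(STAGE_LEVELS, function(st) {
        a <- samples$total[samples$stage == st & samples$genotype == "control"]
        b <- samples$total[samples$stage == st & samples$genotype == "mutant"]
        if (length(a) == 0 || length(b) == 0) return(NULL)
        if (length(a) < 2 || length(b) < 2 ||
            (stats::sd(a) == 0 && stats::sd(b) == 0)) {
            p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else NA_real_
        } else {
            p <- stats::t.test(b, a, var.equal = FALSE)$p.value
        }
        data.frame(stage = st, mean_control = mean(a), mean_mutant = mean(b),
                   ratio = mean(b) / mean(a), p = p, stringsAsFactors = FALSE)
    }))
    list(samples = samples, groups = groups, tests = tests)
}

#' Count genes per expression bin, averaged within groups
#'
#' Per sample, counts endogenous genes whose calibrated TPM falls in
#' \code{[edge_i, edge_{i+1})}; reports the mean count per
#' stage-by-genotype group. Default edges \code{c(0, 2, 10, Inf)} mirror the
#' low / moderate / highly-expressed (TPM > 10) strata used when comparing
#' expression distributions.
#'
#' @param mat a [CalibratedMatrix-class].
#' @param exp the matching [OocyteExperiment-class].
#' @param bin_edges strictly increasing numeric edges.
#' @return data.frame: stage, genotype, bin label, mean gene count.
#' @export
expressionBins <- function(mat, exp, bin_edges = c(0, 2, 10, Inf)) {
    if (any(diff(bin_edges) <= 0))
        stop("bin edges must be strictly increasing", call. = FALSE)
    endo <- !isSpikeIn(exp)
    cal <- calibrated(mat)[endo, , drop = FALSE]
    nb <- length(bin_edges) - 1
    labels <- vapply(seq_len(nb), function(i)
        sprintf("[%g,%g)", bin_edges[i], bin_edges[i + 1]), character(1))
    per_sample <- vapply(seq_len(ncol(cal)), function(j) {
        x <- cal[, j]
        vapply(seq_len(nb), function(i)
            sum(x >= bin_edges[i] & x < bin_edges[i + 1]), numeric(1))
    }, numeric(nb))
    per_sample <- matrix(per_sample, nrow = nb)
    key <- paste(stage(exp), genotype(exp), sep = ".")
    out <- do.call(rbind, lapply(unique(key), function(g) {
        cols <- which(key == g)
        parts <- strsplit(g, ".", fixed = TRUE)[[1]]
        data.frame(stage = parts[1], genotype = parts[2], bin = labels,
                   mean_genes = rowMeans(per_sample[, cols, drop = FALSE]),
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' PCA of samples on the most variable genes
#'
#' Principal components of \code{log2(calibrated + pseudocount)} over the
#' \code{n_top_variable} most variable endogenous genes, centred per gene.
#' Coordinates are deterministic up to sign.
#'
#' @param mat a [CalibratedMatrix-class].
#' @param exp the matching [OocyteExperiment-class].
#' @param n_top_variable number of genes ranked by variance (default 500);
#'   if fewer genes are available all are used, with a warning.
#' @return list with \code{coordinates} (sample, stage, genotype, PC1, PC2)
#'   and \code{variance_explained} (fraction per component).
#' @export
pcaQC <- function(mat, exp, n_top_variable = 500) {
    if (ncol(tpm(mat)) < 3) stop("PCA needs at least 3 samples", call. = FALSE)
    endo <- !isSpikeIn(exp)
    x <- log2(calibrated(mat)[endo, , drop = FALSE] + mat@pseudocount)
    v <- apply(x, 1, stats::var)
    n_use <- min(n_top_variable, nrow(x))
    if (n_use < n_top_variable)
        warning(sprintf("only %d endogenous genes available; using all", n_use))
    top <- order(v, decreasing = TRUE)[seq_len(n_use)]
    pc <- stats::prcomp(t(x[top, , drop = FALSE]), center = TRUE, scale. = FALSE)
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    coords <- data.frame(sample_id = colnames(x),
                         stage = as.character(stage(exp)),
                         genotype = as.character(genotype(exp)),
                         PC1 = pc$x[, 1],
                         PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0,
                         stringsAsFactors = FALSE)
    rownames(coords) <- NULL
    list(coordinates = coords, variance_explained = ve)
}
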