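## Small-n negative-binomial differential expression between genotypes
## within a stage. The machinery (size factors, moment dispersion with a
## trend shrink, Wald test via the delta method, Benjamini-Hochberg) is
## implemented here from first principles so every step is inspectable.

#' Median-of-ratios size factors
#'
#' For each sample, the median across genes of \code{count / geometric mean
#' across samples}, restricted to genes with all-nonzero counts; factors are
#' rescaled to geometric mean 1. When no gene is expressed in every sample
#' the library-size ratio is used instead.
#'
#' @param counts gene-by-sample count matrix.
#' @return positive numeric vector, one per sample.
#' @export
sizeFactorsMedianRatio <- function(counts) {
    counts <- as.matrix(counts)
    all_nz <- rowSums(counts == 0) == 0
    if (any(all_nz)) {
        sub <- counts[all_nz, , drop = FALSE]
        geo <- exp(rowMeans(log(sub)))
        sf <- apply(sub / geo, 2, stats::median)
    } else {
        lib <- colSums(counts)
        if (any(lib == 0)) stop("sample with zero total counts", call. = FALSE)
        sf <- lib
    }
    sf <- sf / exp(mean(log(sf)))
    stats::setNames(sf, colnames(counts))
}

#' Method-of-moments NB dispersion with trend shrinkage
#'
#' Per gene, scaled counts \code{k = count / size factor} are pooled across
#' groups after centring each group at its mean; the raw dispersion is
#' \code{max(0, (s^2 - mu) / mu^2)} with \code{s^2} the pooled within-group
#' variance and \code{mu} the overall scaled mean. Raw values are then shrunk
#' half-way toward a mean-dispersion trend \code{a + b/mu} (least-squares on
#' genes with positive raw estimates, coefficients clamped non-negative,
#' falling back to the mean raw dispersion when the fit is degenerate) and
#' floored at 1e-8. All-zero genes get dispersion 0 and are flagged.
#'
#' @param counts gene-by-sample count matrix.
#' @param size_factors per-sample positive size factors.
#' @param group factor of group membership per sample (e.g. genotype); a
#'   single group is allowed.
#' @return data.frame: gene_id, mean (scaled), dispersion_raw, dispersion
#'   (shrunk), zero_expression flag.
#' @export
estimateDispersion <- function(counts, size_factors,
                               group = rep("all", ncol(counts))) {
    counts <- as.matrix(counts)
    if (ncol(counts) < 2) stop("need at least 2 samples", call. = FALSE)
    group <- as.factor(group)
    k <- sweep(counts, 2, size_factors, "/")
    mu <- rowMeans(k)
    resid <- k
    for (g in levels(group)) {
        cols <- which(group == g)
        resid[, cols] <- k[, cols, drop = FALSE] -
            rowMeans(k[, cols, drop = FALSE])
    }
    df <- ncol(counts) - nlevels(group)
    if (df < 1) stop("no residual degrees of freedom", call. = FALSE)
    s2 <- rowSums(resid^2) / df
    zero <- mu == 0
    raw <- ifelse(zero, 0, pmax(0, (s2 - mu) / mu^2))

    trend <- fit_dispersion_trend(mu[!zero], raw[!zero])
    shrunk <- raw
    shrunk[!zero] <- pmax(1e-8, 0.5 * raw[!zero] + 0.5 * trend(mu[!zero]))
    data.frame(gene_id = rownames(counts), mean = mu,
               dispersion_raw = raw, dispersion = shrunk,
               zero_expression = zero, stringsAsFactors = FALSE)
}

fit_dispersion_trend <- function(mu, raw) {
    use <- raw > 0 & mu > 0
    fallback <- function(m) rep(mean(raw), length(m))
    if (sum(use) < 10) return(fallback)
    fit <- try(stats::lm(raw[use] ~ I(1 / mu[use])), silent = TRUE)
    if (inherits(fit, "try-error")) return(fallback)
    a <- max(0, stats::coef(fit)[1])
    b <- max(0, stats::coef(fit)[2])
    if (!is.finite(a) || !is.finite(b)) return(fallback)
    function(m) a + b / m
}

#' NB Wald test for genotype effect within a stage
#'
#' Restricted to the samples of one stage, computes size factors, scaled
#' group means and a Wald statistic: \code{log2_fc = log2((mu_mut + 0.5) /
#' (mu_ctrl + 0.5))} with the 0.5 pseudocount stabilising zeros at n of 3 or
#' fewer; its variance follows from the NB relation \code{var = mu + alpha
#' mu^2} propagated to the log-ratio by the delta method; p is two-sided
#' normal. Genes with zero counts in both groups get fc 0 and p 1.
#'
#' @param exp an [OocyteExperiment-class].
#' @param stage one of \code{"GV"}, \code{"MII"}, \code{"D3"}.
#' @param dispersion optional per-gene dispersion vector (in row order of
#'   \code{exp}); estimated from the stage's samples when omitted.
#' @param include_spike_ins keep spike-in rows in the test (default FALSE).
#' @return data.frame: gene_id, mean_control, mean_mutant (scaled means),
#'   log2_fc, se, p.
#' @export
nbWaldTest <- function(exp, stage, dispersion = NULL,
                       include_spike_ins = FALSE) {
    stage <- match.arg(stage, STAGE_LEVELS)
    sel <- which(as.character(SummarizedExperiment::colData(exp)$stage) == stage)
    if (length(sel) == 0) stop("no samples at stage ", stage, call. = FALSE)
    gt <- as.character(genotype(exp))[sel]
    if (!all(GENOTYPE_LEVELS %in% gt))
        stop("both genotypes required at stage ", stage, call. = FALSE)
    keep <- if (include_spike_ins) rep(TRUE, nrow(exp)) else !isSpikeIn(exp)
    cts <- SummarizedExperiment::assay(exp, "counts")[keep, sel, drop = FALSE]
    sf <- sizeFactorsMedianRatio(cts)
    if (is.null(dispersion)) {
        disp_tab <- estimateDispersion(cts, sf, group = gt)
        dispersion <- disp_tab$dispersion
    } else {
        dispersion <- dispersion[keep]
    }
    k <- sweep(cts, 2, sf, "/")
    ctrl <- which(gt == "control"); mut <- which(gt == "mutant")
    mu_c <- rowMeans(k[, ctrl, drop = FALSE])
    mu_m <- rowMeans(k[, mut, drop = FALSE])
    lfc <- log2((mu_m + 0.5) / (mu_c + 0.5))
    ## Var of a group's scaled mean: (1/n^2) sum_i (mu/sf_i + alpha mu^2)
    var_mean <- function(mu, cols) {
        n <- length(cols)
        mu * sum(1 / sf[cols]) / n^2 + dispersion * mu^2 / n
    }
    v_c <- var_mean(mu_c, ctrl)
    v_m <- var_mean(mu_m, mut)
    se <- sqrt(v_m / (mu_m + 0.5)^2 + v_c / (mu_c + 0.5)^2) / log(2)
    z <- ifelse(se > 0, lfc / se, 0)
    p <- ifelse(se > 0, 2 * stats::pnorm(-abs(z)), 1)
    p[mu_c == 0 & mu_m == 0] <- 1
    data.frame(gene_id = rownames(cts), mean_control = mu_c,
               mean_mutant = mu_m, log2_fc = lfc, se = se, p = p,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts p ascending, sets \code{padj_(i) = min_(j>=i) m p_(j) / j} capped at
#' 1 and maps back to input order. \code{NA} inputs propagate \code{NA} and
#' are excluded from \code{m}.
#'
#' @param p numeric vector of p-values in \code{[0, 1]} (NA allowed).
#' @return adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]", call. = FALSE)
    out <- rep(NA_real_, length(p))
    ok <- which(!is.na(p))
    m <- length(ok)
    if (m == 0) return(out)
    o <- order(p[ok])
    ranked <- p[ok][o]
    adj <- pmin(1, rev(cummin(rev(m * ranked / seq_len(m)))))
    out[ok[o]] <- adj
    out
}

#' Call differentially expressed genes
#'
#' A gene is \code{up} iff \code{log2_fc > fc_threshold} and
#' \code{padj < alpha} (strict inequalities on both sides), \code{down}
#' symmetrically, otherwise \code{ns}. Thresholds are recorded as
#' attributes.
#'
#' @param table data.frame with columns \code{gene_id}, \code{log2_fc} and
#'   \code{p} (adjusted internally) or \code{padj}.
#' @param fc_threshold log2 fold-change threshold (default 1).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return the table with added \code{padj} and \code{call} columns; counts
#'   of up/down in attribute \code{"n_call"}.
#' @export
callDegs <- function(table, fc_threshold = 1, alpha = 0.05) {
    if (!is.finite(fc_threshold) || !is.finite(alpha))
        stop("thresholds must be finite", call. = FALSE)
    if (!("padj" %in% colnames(table))) table$padj <- bhAdjust(table$p)
    call <- rep("ns", nrow(table))
    sig <- !is.na(table$padj) & table$padj < alpha
    call[sig & table$log2_fc > fc_threshold] <- "up"
    call[sig & table$log2_fc < -fc_threshold] <- "down"
    table$call <- factor(call, levels = c("up", "down", "ns"))
    attr(table, "thresholds") <- list(fc_log2 = fc_threshold, alpha = alpha)
    attr(table, "n_call") <- table(table$call)
    table
}

#' Differential expression between genotypes at one stage
#'
#' Convenience wrapper: [nbWaldTest()] then [bhAdjust()] then [callDegs()].
#'
#' @inheritParams nbWaldTest
#' @inheritParams callDegs
#' @return a DEG table (see [callDegs()]).
#' @export
runDifferential <- function(exp, stage, fc_threshold = 1, alpha = 0.05) {
    callDegs(nbWaldTest(exp, stage), fc_threshold = fc_threshold,
             alpha = alpha)
}
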