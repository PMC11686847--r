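#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

STAGE_LEVELS    <- c("GV", "MII", "D3")
GENOTYPE_LEVELS <- c("control", "mutant")
CLUSTER_LEVELS  <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX")

#' Single-oocyte/embryo expression experiment
#'
#' An \code{OocyteExperiment} is a \linkS4class{SummarizedExperiment} holding a
#' gene-by-sample matrix of non-negative integer read counts for a
#' stage-by-genotype design. Endogenous genes and ERCC-style spike-ins live in
#' the same matrix, distinguished only by the \code{is_spike_in} row flag, so
#' that both share the same per-million denominator during quantification.
#' Row metadata carries the effective gene length in bases; column metadata
#' carries the developmental stage (GV, MII or D3) and genotype (control or
#' mutant).
#'
#' @slot ... inherited from \linkS4class{SummarizedExperiment}; the
#'   \code{counts} assay, \code{rowData} columns \code{gene_length} and
#'   \code{is_spike_in}, and \code{colData} columns \code{stage} and
#'   \code{genotype} are required and checked by the validity method.
#'
#' @seealso [OocyteExperiment()] for construction from plain vectors,
#'   [readExpressionExperiment()] for construction from files.
#' @export
setClass("OocyteExperiment", contains = "SummarizedExperiment")

setValidity("OocyteExperiment", function(object) {
    msgs <- character()
    if (!("counts" %in% SummarizedExperiment::assayNames(object)))
        msgs <- c(msgs, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(!is.finite(cts)))
            msgs <- c(msgs, "counts contain non-finite values")
        else {
            if (any(cts < 0))
                msgs <- c(msgs, "counts must be non-negative")
            if (any(cts != round(cts)))
                msgs <- c(msgs, "counts must be integers")
        }
    }
    rd <- rowData(object)
    cd <- colData(object)
    if (!all(c("gene_length", "is_spike_in") %in% colnames(rd)))
        msgs <- c(msgs, "rowData must contain 'gene_length' and 'is_spike_in'")
    else {
        if (any(!is.finite(rd$gene_length)) || any(rd$gene_length <= 0))
            msgs <- c(msgs, "gene_length must be positive and finite")
        if (!is.logical(rd$is_spike_in) || anyNA(rd$is_spike_in))
            msgs <- c(msgs, "is_spike_in must be logical without NA")
    }
    if (!all(c("stage", "genotype") %in% colnames(cd)))
        msgs <- c(msgs, "colData must contain 'stage' and 'genotype'")
    else {
        if (!all(as.character(cd$stage) %in% STAGE_LEVELS))
            msgs <- c(msgs, sprintf("unknown stage label(s): %s",
                paste(setdiff(unique(as.character(cd$stage)), STAGE_LEVELS),
                      collapse = ", ")))
        if (!all(as.character(cd$genotype) %in% GENOTYPE_LEVELS))
            msgs <- c(msgs, sprintf("unknown genotype label(s): %s",
                paste(setdiff(unique(as.character(cd$genotype)), GENOTYPE_LEVELS),
                      collapse = ", ")))
    }
    ids <- rownames(object)
    if (is.null(ids) || anyDuplicated(ids))
        msgs <- c(msgs, sprintf("duplicate or missing gene ids: %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    sids <- colnames(object)
    if (is.null(sids) || anyDuplicated(sids))
        msgs <- c(msgs, sprintf("duplicate or missing sample ids: %s",
            paste(unique(sids[duplicated(sids)]), collapse = ", ")))
    if (length(msgs)) msgs else TRUE
})

#' Construct an OocyteExperiment
#'
#' @param counts gene-by-sample matrix of non-negative integer counts with
#'   row and column names.
#' @param gene_length numeric vector of positive effective lengths (bases),
#'   one per gene.
#' @param is_spike_in logical vector flagging spike-in rows.
#' @param stage character/factor per sample, levels \code{GV}, \code{MII},
#'   \code{D3}.
#' @param genotype character/factor per sample, levels \code{control},
#'   \code{mutant}.
#'
#' @return A validated [OocyteExperiment-class] object.
#' @examples
#' cts <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' oe <- OocyteExperiment(cts, gene_length = c(1000, 1500, 2000),
#'                        is_spike_in = c(FALSE, FALSE, TRUE),
#'                        stage = c("GV", "GV"),
#'                        genotype = c("control", "mutant"))
#' @export
OocyteExperiment <- function(counts, gene_length, is_spike_in, stage, genotype) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    se <- SummarizedExperiment(
        assays  = list(counts = counts),
        rowData = DataFrame(gene_length = as.numeric(gene_length),
                            is_spike_in = as.logical(is_spike_in),
                            row.names = rownames(counts)),
        colData = DataFrame(stage    = factor(stage, levels = STAGE_LEVELS),
                            genotype = factor(genotype, levels = GENOTYPE_LEVELS),
                            row.names = colnames(counts)))
    new("OocyteExperiment", se)
}

#' @describeIn OocyteExperiment-class developmental stage per sample (factor).
#' @param object,x an \code{OocyteExperiment}.
#' @export
setGeneric("stage", function(x) standardGeneric("stage"))

#' @export
setMethod("stage", "OocyteExperiment", function(x) colData(x)$stage)

#' @describeIn OocyteExperiment-class genotype per sample (factor).
#' @export
setGeneric("genotype", function(x) standardGeneric("genotype"))

#' @export
setMethod("genotype", "OocyteExperiment", function(x) colData(x)$genotype)

#' @describeIn OocyteExperiment-class logical spike-in flag per gene.
#' @export
setGeneric("isSpikeIn", function(x) standardGeneric("isSpikeIn"))

#' @export
setMethod("isSpikeIn", "OocyteExperiment", function(x) rowData(x)$is_spike_in)

#' @describeIn OocyteExperiment-class effective gene length in bases.
#' @export
setGeneric("geneLength", function(x) standardGeneric("geneLength"))

#' @export
setMethod("geneLength", "OocyteExperiment", function(x) rowData(x)$gene_length)

#' @export
setMethod("show", "OocyteExperiment", function(object) {
    cat(sprintf("OocyteExperiment: %d genes (%d spike-ins) x %d samples\n",
                nrow(object), sum(isSpikeIn(object)), ncol(object)))
    tab <- table(stage = stage(object), genotype = genotype(object))
    print(tab)
    invisible(NULL)
})

#' Spike-in calibrated TPM matrix
#'
#' Holds the TPM quantification of an [OocyteExperiment-class] together with
#' the per-sample spike-in scale factors \eqn{k_s} used to place samples on a
#' common absolute-dosage scale. Raw TPM columns (endogenous plus spike rows)
#' sum to \eqn{10^6}; the calibrated matrix is \code{tpm * k_s} column-wise,
#' so calibrated endogenous totals are comparable across samples as absolute
#' per-cell mRNA dosage.
#'
#' @slot tpm gene-by-sample matrix of raw TPM values.
#' @slot scaleFactor per-sample positive calibration factor (all 1 before
#'   calibration).
#' @slot pseudocount value added before any log2 transform downstream
#'   (default 1).
#' @slot provenance list recording how the matrix was produced (degenerate
#'   all-zero samples, calibration anchor, parameters).
#' @export
setClass("CalibratedMatrix",
         representation(tpm = "matrix", scaleFactor = "numeric",
                        pseudocount = "numeric", provenance = "list"))

setValidity("CalibratedMatrix", function(object) {
    msgs <- character()
    if (length(object@scaleFactor) != ncol(object@tpm))
        msgs <- c(msgs, "one scale factor per sample required")
    if (any(!is.finite(object@scaleFactor)) || any(object@scaleFactor <= 0))
        msgs <- c(msgs, "scale factors must be positive and finite")
    cs <- colSums(object@tpm)
    zero_ok <- object@provenance$all_zero_samples
    bad <- abs(cs - 1e6) > 1 & !(colnames(object@tpm) %in% zero_ok)
    if (any(bad))
        msgs <- c(msgs, sprintf("TPM columns do not sum to 1e6: %s",
                                paste(colnames(object@tpm)[bad], collapse = ", ")))
    if (length(msgs)) msgs else TRUE
})

#' @describeIn CalibratedMatrix-class raw TPM matrix.
#' @param object,x a \code{CalibratedMatrix}.
#' @export
setGeneric("tpm", function(x) standardGeneric("tpm"))

#' @export
setMethod("tpm", "CalibratedMatrix", function(x) x@tpm)

#' @describeIn CalibratedMatrix-class per-sample calibration factors.
#' @export
setGeneric("scaleFactors", function(x) standardGeneric("scaleFactors"))

#' @export
setMethod("scaleFactors", "CalibratedMatrix", function(x) x@scaleFactor)

#' @describeIn CalibratedMatrix-class calibrated matrix
#'   (\code{tpm * scaleFactor} column-wise).
#' @export
setGeneric("calibrated", function(x) standardGeneric("calibrated"))

#' @export
setMethod("calibrated", "CalibratedMatrix",
          function(x) sweep(x@tpm, 2, x@scaleFactor, "*"))

#' @export
setMethod("show", "CalibratedMatrix", function(object) {
    cal <- !is.null(object@provenance$calibration)
    cat(sprintf("CalibratedMatrix: %d genes x %d samples (%s)\n",
                nrow(object@tpm), ncol(object@tpm),
                if (cal) "spike-in calibrated" else "raw TPM, k = 1"))
    cat(sprintf("  scale factors: [%.4g, %.4g]\n",
                min(object@scaleFactor), max(object@scaleFactor)))
    invisible(NULL)
})

#' Per-gene stage-by-genotype expression profile
#'
#' Summarises expression per gene, stage and genotype as the median over
#' replicate samples of \code{log2(calibrated TPM + 1)}, plus the two stage
#' transitions \eqn{\Delta_1 = MII - GV} and \eqn{\Delta_2 = D3 - MII} per
#' genotype. This is the substrate of the decay-cluster taxonomy.
#'
#' @slot value 3-d array gene x stage x genotype of median log2(x+1) values.
#' @slot delta 3-d array gene x transition (\code{MII-GV}, \code{D3-MII}) x
#'   genotype.
#' @slot pseudocount value added before the log2 transform.
#' @export
setClass("StageProfile",
         representation(value = "array", delta = "array",
                        pseudocount = "numeric"))

#' @export
setMethod("show", "StageProfile", function(object) {
    cat(sprintf("StageProfile: %d genes, stages %s, genotypes %s\n",
                dim(object@value)[1],
                paste(dimnames(object@value)[[2]], collapse = "/"),
                paste(dimnames(object@value)[[3]], collapse = "/")))
    invisible(NULL)
})
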