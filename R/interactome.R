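## Differential AP-MS interactome calling. A bait pulldown is compared to a
## vector control and a mutant bait: proteins enriched > 10-fold over vector
## are interactors; wild-type interactors whose mutant/wild-type intensity
## ratio drops to 2/3 or less (>= 30% reduction) form the reduced-binding
## set.

#' Call bait interactors from a protein-intensity table
#'
#' Computes \code{log2fc_x_vec = log2((I_x + pseudo) / (I_vec + pseudo))}
#' for x in \{WT, Mut\} and calls a protein an interactor of x when the
#' enrichment strictly exceeds \code{enrich_log2} (positive direction only:
#' bait pulldown enrichment is one-sided). Replicates, if any, must be
#' averaged beforehand (geometric mean of positive values is the
#' convention); the pseudocount guards zero intensities.
#'
#' @param intensities numeric matrix, proteins x conditions; columns must
#'   include \code{Vector}, \code{WT}, \code{Mut}.
#' @param enrich_log2 enrichment threshold (default \code{log2(10)},
#'   ten-fold).
#' @param reduce_log2 mutant-vs-wild-type reduction threshold (default
#'   \code{log2(2/3)}, i.e. a 30\% reduction).
#' @param pseudo small positive intensity offset (default 0.01).
#' @return data.frame per protein: the three log2 fold changes,
#'   \code{is_wt_interactor}, \code{is_mut_interactor}, \code{is_shared},
#'   \code{is_reduced_binding}; thresholds in attribute
#'   \code{"thresholds"}.
#' @export
callInteractors <- function(intensities, enrich_log2 = log2(10),
                            reduce_log2 = log2(2 / 3), pseudo = 0.01) {
    m <- as.matrix(intensities)
    need <- c("Vector", "WT", "Mut")
    if (!all(need %in% colnames(m)))
        stop("conditions Vector, WT, Mut required", call. = FALSE)
    if (any(m < 0)) stop("intensities must be non-negative", call. = FALSE)
    lf <- function(a, b) log2((m[, a] + pseudo) / (m[, b] + pseudo))
    out <- data.frame(
        protein_id = rownames(m),
        log2fc_wt_vec = lf("WT", "Vector"),
        log2fc_mut_vec = lf("Mut", "Vector"),
        log2fc_mut_wt = lf("Mut", "WT"),
        stringsAsFactors = FALSE, row.names = NULL)
    out$is_wt_interactor  <- out$log2fc_wt_vec > enrich_log2
    out$is_mut_interactor <- out$log2fc_mut_vec > enrich_log2
    out$is_shared <- out$is_wt_interactor & out$is_mut_interactor
    out$is_reduced_binding <- out$is_wt_interactor &
        out$log2fc_mut_wt <= reduce_log2
    attr(out, "thresholds") <- list(enrich_log2 = enrich_log2,
                                    reduce_log2 = reduce_log2,
                                    pseudo = pseudo)
    out
}

#' Reduced-binding proteins
#'
#' Wild-type interactors whose mutant/wild-type ratio is at or below
#' \code{2^reduce_log2} (inclusive boundary: "at least a 30\% reduction"
#' includes exactly 30\%). Non-interactors are never called reduced,
#' whatever their ratio.
#'
#' @param calls output of [callInteractors()].
#' @param reduce_log2 optional override of the threshold recorded in
#'   \code{calls}.
#' @return character vector of reduced-binding protein ids.
#' @export
differentialBinding <- function(calls, reduce_log2 = NULL) {
    if (is.null(reduce_log2)) {
        calls$protein_id[calls$is_reduced_binding]
    } else {
        calls$protein_id[calls$is_wt_interactor &
                         calls$log2fc_mut_wt <= reduce_log2]
    }
}

#' Interactor set partition (Venn counts)
#'
#' Partitions the union of wild-type and mutant interactors into WT-only,
#' Mut-only and shared, plus the intersection of the shared set with the
#' reduced-binding set. Sizes sum to the union by construction.
#'
#' @param calls output of [callInteractors()].
#' @return named integer vector: \code{wt_only}, \code{mut_only},
#'   \code{shared}, \code{shared_reduced}.
#' @export
vennSets <- function(calls) {
    c(wt_only = sum(calls$is_wt_interactor & !calls$is_mut_interactor),
      mut_only = sum(calls$is_mut_interactor & !calls$is_wt_interactor),
      shared = sum(calls$is_shared),
      shared_reduced = sum(calls$is_shared & calls$is_reduced_binding))
}

#' Simulate an AP-MS intensity table with planted truth
#'
#' Plants five protein categories with known calls under the default
#' thresholds — background (no enrichment), WT-only and Mut-only interactors
#' (50-fold enrichment in one pulldown), shared interactors with preserved
#' binding (Mut/WT 1.2) and shared interactors with reduced binding
#' (Mut/WT 0.4) — then perturbs every intensity with multiplicative
#' log-normal noise.
#'
#' @param n_per_class proteins per category (default 50).
#' @param noise_sdlog sdlog of the log-normal noise (0 = noiseless;
#'   0.2 is about 20\% intensity noise).
#' @param seed integer seed.
#' @return list with \code{intensities} (matrix with Vector/WT/Mut columns)
#'   and \code{truth} (protein_id, class).
#' @export
simulateInteractome <- function(n_per_class = 50, noise_sdlog = 0,
                                seed = 1L) {
    set.seed(seed)
    classes <- c("background", "wt_only", "mut_only", "shared", "reduced")
    base <- list(
        background = c(Vector = 10, WT = 10, Mut = 10),
        wt_only    = c(Vector = 10, WT = 500, Mut = 10),
        mut_only   = c(Vector = 10, WT = 10, Mut = 500),
        shared     = c(Vector = 10, WT = 500, Mut = 600),
        reduced    = c(Vector = 10, WT = 500, Mut = 200))
    ids <- unlist(lapply(classes, function(cl)
        sprintf("%s_%03d", cl, seq_len(n_per_class))))
    m <- do.call(rbind, lapply(classes, function(cl)
        matrix(rep(base[[cl]], each = n_per_class), ncol = 3,
               dimnames = list(NULL, names(base[[cl]])))))
    rownames(m) <- ids
    if (noise_sdlog > 0)
        m <- m * matrix(stats::rlnorm(length(m), 0, noise_sdlog), nrow(m))
    list(intensities = m,
         truth = data.frame(protein_id = ids,
                            class = rep(classes, each = n_per_class),
                            stringsAsFactors = FALSE))
}
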