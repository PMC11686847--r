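#' Overlap of a gene list with a gene set
#'
#' Reports \code{percent = 100 * |list intersect set| / |list|} (the style
#' used when quoting, e.g., the fraction of day-3 downregulated genes that
#' are ZGA genes), with a display-rounded integer percent
#' (half-away-from-zero) alongside the exact value, and optionally an
#' upper-tail hypergeometric enrichment p when a universe size is supplied.
#'
#' @param deg_list character vector of gene ids (non-empty).
#' @param gene_set character vector of set member ids.
#' @param set_name,list_name labels carried into the output.
#' @param universe optional universe size (integer) or vector of universe
#'   gene ids; when given, \code{p_hyper} is computed via
#'   [hypergeometricTest()] with the set clipped to the universe if ids are
#'   supplied.
#' @return one-row data.frame: set_name, list_name, overlap, list_size,
#'   set_size, universe, percent (exact), percent_display (integer),
#'   p_hyper.
#' @export
overlapPercentage <- function(deg_list, gene_set, set_name = "set",
                              list_name = "list", universe = NULL) {
    deg_list <- unique(as.character(deg_list))
    gene_set <- unique(as.character(gene_set))
    if (length(deg_list) == 0) stop("empty gene list", call. = FALSE)
    ov <- length(intersect(deg_list, gene_set))
    pct <- 100 * ov / length(deg_list)
    p <- NA_real_
    uni <- NA_integer_
    if (!is.null(universe)) {
        if (is.character(universe)) {
            gene_set <- intersect(gene_set, universe)
            deg_list_u <- intersect(deg_list, universe)
            uni <- length(universe)
            p <- hypergeometricTest(length(intersect(deg_list_u, gene_set)),
                                    length(deg_list_u), length(gene_set), uni)
        } else {
            uni <- as.integer(universe)
            p <- hypergeometricTest(ov, length(deg_list), length(gene_set),
                                    uni)
        }
    }
    data.frame(set_name = set_name, list_name = list_name, overlap = ov,
               list_size = length(deg_list), set_size = length(gene_set),
               universe = uni, percent = pct,
               percent_display = floor(pct + 0.5), p_hyper = p,
               stringsAsFactors = FALSE)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' \code{P[X >= overlap]} where \code{X ~ Hypergeometric(universe, set_size,
#' list_size)}: drawing \code{list_size} genes without replacement from a
#' universe containing \code{set_size} marked genes. Computed by summing the
#' PMF in log space (log-binomial coefficients combined by log-sum-exp), so
#' it stays accurate for extreme tails.
#'
#' @param overlap observed intersection size.
#' @param list_size size of the drawn list.
#' @param set_size number of marked genes in the universe.
#' @param universe universe size.
#' @return the upper-tail probability; 1 when \code{overlap} is 0.
#' @export
hypergeometricTest <- function(overlap, list_size, set_size, universe) {
    if (overlap > min(list_size, set_size) ||
        min(list_size, set_size) > universe ||
        overlap < 0 || list_size < 0 || set_size < 0 ||
        list_size > universe || set_size > universe)
        stop("inconsistent counts for hypergeometric test", call. = FALSE)
    if (overlap == 0) return(1)
    k <- seq(overlap, min(list_size, set_size))
    # support constraint: list_size - k <= universe - set_size
    k <- k[list_size - k <= universe - set_size]
    if (length(k) == 0) return(0)
    logp <- lchoose(set_size, k) + lchoose(universe - set_size,
                                           list_size - k) -
            lchoose(universe, list_size)
    m <- max(logp)
    min(1, exp(m + log(sum(exp(logp - m)))))
}
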