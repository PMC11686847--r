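## Tabular interchange: UTF-8, tab-separated, '#' comment lines ignored,
## first column is the id column. Floating output keeps full round-trip
## precision (format with 17 significant digits, trimmed).

read_tsv_table <- function(path, what = "table") {
    if (!file.exists(path))
        stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
    df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
    if (ncol(df) < 1 || nrow(df) < 0)
        stop(sprintf("%s file is empty: %s", what, path), call. = FALSE)
    df
}

fmt_num <- function(x) {
    if (is.numeric(x) && !all(x == round(x) & abs(x) < 2^52, na.rm = TRUE))
        vapply(x, function(v) {
            if (is.na(v)) NA_character_ else format(v, digits = 17, trim = TRUE,
                                                    scientific = NA)
        }, character(1))
    else x
}

write_tsv_table <- function(df, path) {
    out <- as.data.frame(df, stringsAsFactors = FALSE)
    out[] <- lapply(out, fmt_num)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = TRUE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read an expression experiment from count and metadata tables
#'
#' Reads a gene-by-sample count matrix plus gene and sample metadata tables
#' and assembles a validated [OocyteExperiment-class]. All tables are UTF-8
#' tab-separated with a header; lines starting with \code{#} are ignored; the
#' first column is the id column. The gene metadata table must provide
#' \code{gene_length} (positive, bases) and \code{is_spike_in}
#' (\code{TRUE}/\code{FALSE}); the sample metadata table must provide
#' \code{stage} (GV/MII/D3) and \code{genotype} (control/mutant). Spike-in
#' rows are retained in the matrix and only flagged, never dropped.
#'
#' @param counts_path path to the count matrix (first column gene id, one
#'   column per sample).
#' @param gene_meta_path path to the gene metadata table.
#' @param sample_meta_path path to the sample metadata table.
#'
#' @return An [OocyteExperiment-class].
#' @export
readExpressionExperiment <- function(counts_path, gene_meta_path,
                                     sample_meta_path) {
    cts_df <- read_tsv_table(counts_path, "counts")
    gm     <- read_tsv_table(gene_meta_path, "gene metadata")
    sm     <- read_tsv_table(sample_meta_path, "sample metadata")

    gene_ids <- as.character(cts_df[[1]])
    if (anyDuplicated(gene_ids))
        stop("duplicate gene ids in counts: ",
             paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
             call. = FALSE)
    sample_ids <- colnames(cts_df)[-1]
    if (anyDuplicated(sample_ids))
        stop("duplicate sample ids in counts: ",
             paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
             call. = FALSE)
    cts <- as.matrix(cts_df[, -1, drop = FALSE])
    if (!is.numeric(cts))
        stop("counts matrix contains non-numeric entries", call. = FALSE)
    bad <- which(cts < 0 | cts != round(cts) | !is.finite(cts), arr.ind = TRUE)
    if (nrow(bad) > 0)
        stop(sprintf("negative or non-integer count at gene '%s', sample '%s'",
                     gene_ids[bad[1, 1]], sample_ids[bad[1, 2]]), call. = FALSE)
    rownames(cts) <- gene_ids

    gm_ids <- as.character(gm[[1]])
    if (anyDuplicated(gm_ids))
        stop("duplicate gene ids in gene metadata: ",
             paste(unique(gm_ids[duplicated(gm_ids)]), collapse = ", "),
             call. = FALSE)
    missing_g <- setdiff(gene_ids, gm_ids)
    if (length(missing_g))
        stop("genes in counts absent from gene metadata: ",
             paste(utils::head(missing_g, 5), collapse = ", "), call. = FALSE)
    extra_g <- setdiff(gm_ids, gene_ids)
    if (length(extra_g))
        stop("genes in gene metadata absent from counts: ",
             paste(utils::head(extra_g, 5), collapse = ", "), call. = FALSE)
    for (col in c("gene_length", "is_spike_in"))
        if (!(col %in% colnames(gm)))
            stop("gene metadata lacks required column '", col, "'", call. = FALSE)
    gm <- gm[match(gene_ids, gm_ids), ]

    sm_ids <- as.character(sm[[1]])
    if (anyDuplicated(sm_ids))
        stop("duplicate sample ids in sample metadata: ",
             paste(unique(sm_ids[duplicated(sm_ids)]), collapse = ", "),
             call. = FALSE)
    missing_s <- setdiff(sample_ids, sm_ids)
    if (length(missing_s))
        stop("samples in counts absent from sample metadata: ",
             paste(missing_s, collapse = ", "), call. = FALSE)
    extra_s <- setdiff(sm_ids, sample_ids)
    if (length(extra_s))
        stop("samples in sample metadata absent from counts: ",
             paste(extra_s, collapse = ", "), call. = FALSE)
    for (col in c("stage", "genotype"))
        if (!(col %in% colnames(sm)))
            stop("sample metadata lacks required column '", col, "'",
                 call. = FALSE)
    sm <- sm[match(sample_ids, sm_ids), ]

    bad_stage <- setdiff(unique(as.character(sm$stage)), STAGE_LEVELS)
    if (length(bad_stage))
        stop("unknown stage label(s): ", paste(bad_stage, collapse = ", "),
             call. = FALSE)
    bad_gt <- setdiff(unique(as.character(sm$genotype)), GENOTYPE_LEVELS)
    if (length(bad_gt))
        stop("unknown genotype label(s): ", paste(bad_gt, collapse = ", "),
             call. = FALSE)

    spike <- gm$is_spike_in
    if (is.character(spike)) spike <- toupper(spike) %in% c("TRUE", "T", "1")
    if (is.numeric(spike)) spike <- spike != 0

    OocyteExperiment(cts, gene_length = gm$gene_length, is_spike_in = spike,
                     stage = as.character(sm$stage),
                     genotype = as.character(sm$genotype))
}

#' Read a spike-in reference table
#'
#' Two-column tab-separated table: spike id, nominal amount (arbitrary
#' concentration units with identical meaning across samples).
#'
#' @param path path to the table.
#' @return data.frame with columns \code{spike_id}, \code{nominal_amount}.
#' @export
readSpikeInReference <- function(path) {
    df <- read_tsv_table(path, "spike-in reference")
    if (ncol(df) < 2)
        stop("spike-in reference needs columns spike_id, nominal_amount",
             call. = FALSE)
    out <- data.frame(spike_id = as.character(df[[1]]),
                      nominal_amount = as.numeric(df[[2]]),
                      stringsAsFactors = FALSE)
    if (anyDuplicated(out$spike_id))
        stop("duplicate spike ids: ",
             paste(unique(out$spike_id[duplicated(out$spike_id)]),
                   collapse = ", "), call. = FALSE)
    if (any(!is.finite(out$nominal_amount)) || any(out$nominal_amount <= 0))
        stop("spike-in nominal amounts must be positive", call. = FALSE)
    out
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' \code{name}, \code{description}, then one or more member gene ids.
#' Duplicate members within a line are collapsed; order of lines is
#' preserved.
#'
#' @param path path to the GMT file.
#' @return Named list of character vectors of member ids, one per set;
#'   each element carries the description in attribute \code{"description"}.
#' @export
readGeneSets <- function(path) {
    if (!file.exists(path))
        stop("gene-set file not found: ", path, call. = FALSE)
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    sets <- list()
    for (i in seq_along(lines)) {
        fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
        if (length(fields) < 3)
            stop(sprintf("GMT parse error at line %d: fewer than 3 fields", i),
                 call. = FALSE)
        members <- unique(fields[-(1:2)])
        members <- members[nzchar(members)]
        if (length(members) == 0)
            stop(sprintf("GMT parse error at line %d: empty member list", i),
                 call. = FALSE)
        s <- members
        attr(s, "description") <- fields[2]
        sets[[fields[1]]] <- s
    }
    sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors (as from [readGeneSets()]).
#' @param path destination path.
#' @return the path, invisibly.
#' @export
writeGeneSets <- function(sets, path) {
    lines <- vapply(names(sets), function(nm) {
        desc <- attr(sets[[nm]], "description")
        if (is.null(desc)) desc <- nm
        paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}

#' Read a protein-intensity table
#'
#' Tab-separated protein-by-condition intensity table; first column protein
#' id, remaining columns conditions (must include \code{Vector}, \code{WT}
#' and \code{Mut} for the differential interactome calls).
#'
#' @param path path to the table.
#' @return numeric matrix, proteins x conditions.
#' @export
readProteinIntensities <- function(path) {
    df <- read_tsv_table(path, "protein intensity")
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
        stop("duplicate protein ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "),
             call. = FALSE)
    if (anyDuplicated(colnames(df)[-1]))
        stop("duplicate condition labels", call. = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m) || any(!is.finite(m)))
        stop("intensities must be finite numbers", call. = FALSE)
    if (any(m < 0))
        stop("intensities must be non-negative", call. = FALSE)
    rownames(m) <- ids
    m
}

#' Write an experiment (counts + metadata) to disk
#'
#' Emits the three tables [readExpressionExperiment()] consumes:
#' \code{counts.tsv}, \code{genes.tsv}, \code{samples.tsv}.
#'
#' @param exp an [OocyteExperiment-class].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
writeExpressionExperiment <- function(exp, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    cts <- SummarizedExperiment::assay(exp, "counts")
    counts_df <- data.frame(gene_id = rownames(cts),
                            as.data.frame(cts, check.names = FALSE),
                            check.names = FALSE, stringsAsFactors = FALSE)
    genes_df <- data.frame(gene_id = rownames(exp),
                           gene_length = geneLength(exp),
                           is_spike_in = isSpikeIn(exp),
                           stringsAsFactors = FALSE)
    samples_df <- data.frame(sample_id = colnames(exp),
                             stage = as.character(stage(exp)),
                             genotype = as.character(genotype(exp)),
                             stringsAsFactors = FALSE)
    paths <- c(counts  = file.path(dir, "counts.tsv"),
               genes   = file.path(dir, "genes.tsv"),
               samples = file.path(dir, "samples.tsv"))
    write_tsv_table(counts_df, paths["counts"])
    write_tsv_table(genes_df, paths["genes"])
    write_tsv_table(samples_df, paths["samples"])
    invisible(paths)
}

#' Write result tables plus a run manifest
#'
#' Each table is written as a tab-separated text file with header, using
#' full round-trip precision for floating values. A JSON manifest listing
#' every file with its MD5 checksum, along with parameters, seed and package
#' version, is written alongside as \code{manifest.json}.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @param parameters optional named list recorded in the manifest.
#' @param seed optional seed recorded in the manifest.
#' @return the manifest as a list, invisibly; written files are
#'   \code{<name>.tsv} per table.
#' @export
writeResults <- function(tables, out_dir, parameters = list(), seed = NULL) {
    if (is.null(names(tables)) || any(!nzchar(names(tables))))
        stop("every result table must be named", call. = FALSE)
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir))
        stop("cannot create output directory: ", out_dir, call. = FALSE)
    files <- list()
    for (nm in names(tables)) {
        p <- file.path(out_dir, paste0(nm, ".tsv"))
        write_tsv_table(tables[[nm]], p)
        files[[nm]] <- list(path = basename(p),
                            md5 = unname(tools::md5sum(p)),
                            rows = nrow(tables[[nm]]))
    }
    manifest <- list(
        package = "oodyn",
        version = as.character(utils::packageVersion("oodyn")),
        r_version = paste(R.version$major, R.version$minor, sep = "."),
        seed = seed,
        parameters = parameters,
        files = files)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    invisible(manifest)
}
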