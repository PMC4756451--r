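NA_MARKERS <- c("", "NA", "NaN")

#' Read a beta (or detection-p / bead-count) matrix
#'
#' Expects a rectangular TSV (or CSV) with a header row of sample ids
#' and probe ids in the first column. Empty cells, \code{NA} and
#' \code{NaN} are read as missing.
#'
#' @param path file path.
#' @param sep field separator; \code{"\t"} by default.
#' @return numeric matrix, probes x samples, with dimnames.
#' @export
readBetaMatrix <- function(path, sep = "\t") {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            na.strings = NA_MARKERS, check.names = FALSE,
                            colClasses = NA, stringsAsFactors = FALSE,
                            row.names = NULL)
    if (anyDuplicated(df[[1]]))
        stop("duplicate probe ids in ", path)
    if (anyDuplicated(colnames(df)[-1]))
        stop("duplicate sample ids in ", path)
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric values in matrix ", path)
    rownames(m) <- as.character(df[[1]])
    m
}

#' Write a matrix in the TSV dialect used by the readers
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param idColumn name for the first (probe id) column.
#' @export
writeBetaMatrix <- function(m, path, idColumn = "probe_id") {
    df <- data.frame(rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1] <- idColumn
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
}

.validateSheet <- function(df) {
    miss <- setdiff(REQUIRED_SHEET_COLS, colnames(df))
    if (length(miss))
        stop("sample sheet columns missing: ", paste(miss, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample_id in sample sheet")
    bad <- which(!(df$status %in% STATUS_LEVELS))
    if (length(bad))
        stop("unknown status '", df$status[bad[1]], "' at sheet row ", bad[1])
    bad <- which(!is.na(df$sex) & !(df$sex %in% SEX_LEVELS))
    if (length(bad))
        stop("unknown sex '", df$sex[bad[1]], "' at sheet row ", bad[1])
    bad <- which(!(df$tissue %in% TISSUE_LEVELS))
    if (length(bad))
        stop("unknown tissue '", df$tissue[bad[1]], "' at sheet row ", bad[1])
    df$ga_weeks <- as.numeric(df$ga_weeks)
    df$ga_flagged <- !is.na(df$ga_weeks) &
        (df$ga_weeks < 10 | df$ga_weeks > 30)
    df
}

#' Read and validate a sample sheet
#'
#' Required columns: sample_id, individual_id, tissue (one of
#' chorionic_villi, kidney, spinal_cord, brain, muscle), status (CON, SB
#' or AN), sex (M/F), ga_weeks (gestational age in weeks), plate, chip,
#' row. Unknown enum values raise an error naming the offending row;
#' missing ga_weeks is flagged (column \code{ga_flagged}), not an error.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
readSampleSheet <- function(path) {
    df <- utils::read.csv(path, na.strings = NA_MARKERS,
                          stringsAsFactors = FALSE)
    .validateSheet(df)
}

#' Write a sample sheet as CSV
#' @param sheet data.frame
#' @param path output path
#' @export
writeSampleSheet <- function(sheet, path) {
    utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE, na = "NA")
}

.validateAnnotation <- function(df) {
    miss <- setdiff(REQUIRED_ANNOT_COLS, colnames(df))
    if (length(miss))
        stop("probe annotation columns missing: ", paste(miss, collapse = ", "))
    if (anyDuplicated(df$probe_id)) stop("duplicate probe_id in annotation")
    if (any(df$position < 1, na.rm = TRUE))
        stop("positions must be 1-based (>= 1)")
    bad <- which(!(df$island_relation %in% ISLAND_LEVELS))
    if (length(bad))
        stop("unknown island_relation '", df$island_relation[bad[1]],
             "' at annotation row ", bad[1])
    bad <- which(!(df$probe_class %in% PROBE_CLASSES))
    if (length(bad))
        stop("unknown probe_class '", df$probe_class[bad[1]],
             "' at annotation row ", bad[1])
    for (cc in c("enhancer", "polymorphic", "cross_hybridizing"))
        df[[cc]] <- as.logical(df[[cc]])
    df$gene_field[is.na(df$gene_field)] <- ""
    df$closest_tss_gene[is.na(df$closest_tss_gene)] <- ""
    df
}

#' Read and validate a probe annotation table
#'
#' TSV with columns probe_id, chrom, position (1-based CpG coordinate),
#' gene_field (semicolon-delimited gene names, possibly empty),
#' closest_tss_gene, island_relation (high_density_island / non_island /
#' shore_shelf_other), enhancer, polymorphic, cross_hybridizing
#' (logicals) and probe_class (cg / ch / rs).
#'
#' @param path TSV file path.
#' @return validated data.frame.
#' @export
readProbeAnnotation <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            na.strings = NA_MARKERS, quote = "",
                            stringsAsFactors = FALSE)
    .validateAnnotation(df)
}

#' Write a probe annotation table as TSV
#' @param annotation data.frame
#' @param path output path
#' @export
writeProbeAnnotation <- function(annotation, path) {
    utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
}

#' Assign a single gene (or NA) to each probe
#'
#' Precedence rule: (1) an empty gene field yields NA; (2) if all
#' semicolon-delimited entries agree, that gene; (3) otherwise the gene
#' with the closest transcription start site. Rule (3) with an empty
#' closest-TSS entry yields NA with a warning.
#'
#' @param annotation data.frame with \code{gene_field} and
#'   \code{closest_tss_gene} columns (and \code{probe_id} for names).
#' @return character vector of gene names (NA where unannotated), named
#'   by probe id when available.
#' @export
annotateProbeGene <- function(annotation) {
    gf <- annotation$gene_field
    gf[is.na(gf)] <- ""
    tss <- annotation$closest_tss_gene
    tss[is.na(tss)] <- ""
    out <- rep(NA_character_, length(gf))
    parts <- strsplit(gf, ";", fixed = TRUE)
    nuniq <- vapply(parts, function(p) length(unique(p[nzchar(p)])), 0L)
    one <- nuniq == 1L
    out[one] <- vapply(parts[one], function(p) unique(p[nzchar(p)]), "")
    multi <- nuniq > 1L
    out[multi] <- ifelse(nzchar(tss[multi]), tss[multi], NA_character_)
    if (any(multi & !nzchar(tss)))
        warning(sum(multi & !nzchar(tss)),
                " probe(s) with conflicting gene names and no closest-TSS",
                " gene; annotated as NA")
    if (!is.null(annotation$probe_id)) names(out) <- annotation$probe_id
    out
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate genes within a set are removed.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGeneSets <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(stats::setNames(list(), character(0)))
    out <- lapply(lines, function(l) {
        f <- strsplit(l, "\t", fixed = TRUE)[[1]]
        unique(f[-(1:2)][nzchar(f[-(1:2)])])
    })
    names(out) <- vapply(lines, function(l)
        strsplit(l, "\t", fixed = TRUE)[[1]][1], "", USE.NAMES = FALSE)
    out
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors
#' @param path output path
#' @export
writeGeneSets <- function(sets, path) {
    lines <- vapply(names(sets), function(nm)
        paste(c(nm, nm, sets[[nm]]), collapse = "\t"), "")
    writeLines(lines, path)
}
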