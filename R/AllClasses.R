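#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
#' @importFrom limma squeezeVar
#' @importFrom ape as.phylo write.tree
#' @importFrom mclust adjustedRandIndex
#' @importFrom stats median mad var sd quantile
NULL

REQUIRED_SHEET_COLS <- c("sample_id", "individual_id", "tissue", "status",
                         "sex", "ga_weeks", "plate", "chip", "row")
REQUIRED_ANNOT_COLS <- c("probe_id", "chrom", "position", "gene_field",
                         "closest_tss_gene", "island_relation", "enhancer",
                         "polymorphic", "cross_hybridizing", "probe_class")

STATUS_LEVELS  <- c("CON", "SB", "AN")
SEX_LEVELS     <- c("F", "M")
TISSUE_LEVELS  <- c("chorionic_villi", "kidney", "spinal_cord", "brain", "muscle")
ISLAND_LEVELS  <- c("high_density_island", "non_island", "shore_shelf_other")
PROBE_CLASSES  <- c("cg", "ch", "rs")

#' MethylationSet: a 450k-style methylation dataset
#'
#' Extends \linkS4class{SummarizedExperiment} with three aligned assays:
#' \code{beta} (proportion methylated, in \[0,1\] or \code{NA}),
#' \code{detectionP} (per probe-sample detection p value) and
#' \code{beadCount} (number of bead replicates). \code{colData} holds the
#' sample sheet (phenotype plus batch variables) and \code{rowData} the
#' probe annotation.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}
#' @export
setClass("MethylationSet", contains = "SummarizedExperiment")

setValidity("MethylationSet", function(object) {
    msg <- character(0)
    an <- assayNames(object)
    if (!("beta" %in% an))
        msg <- c(msg, "assay 'beta' is required")
    else {
        b <- assay(object, "beta")
        rng <- suppressWarnings(range(b, na.rm = TRUE))
        if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
            msg <- c(msg, "beta values must lie in [0, 1]")
    }
    miss <- setdiff(REQUIRED_SHEET_COLS, colnames(colData(object)))
    if (length(miss))
        msg <- c(msg, paste0("sample sheet columns missing: ",
                             paste(miss, collapse = ", ")))
    missA <- setdiff(REQUIRED_ANNOT_COLS, colnames(rowData(object)))
    if (length(missA))
        msg <- c(msg, paste0("probe annotation columns missing: ",
                             paste(missA, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Construct a MethylationSet
#'
#' @param beta numeric matrix, probes x samples, values in \[0,1\] or NA.
#' @param sampleSheet data.frame with one row per column of \code{beta};
#'   see \code{\link{readSampleSheet}} for the schema.
#' @param probeAnnotation data.frame with one row per row of \code{beta};
#'   see \code{\link{readProbeAnnotation}} for the schema.
#' @param detectionP,beadCount optional matrices of the same shape as
#'   \code{beta}. When absent they default to 0 and a large bead count,
#'   i.e. every probe-sample pair is treated as reliable.
#' @return A \linkS4class{MethylationSet}.
#' @export
MethylationSet <- function(beta, sampleSheet, probeAnnotation,
                           detectionP = NULL, beadCount = NULL) {
    beta <- as.matrix(beta)
    if (is.null(detectionP))
        detectionP <- matrix(0, nrow(beta), ncol(beta), dimnames = dimnames(beta))
    if (is.null(beadCount))
        beadCount <- matrix(99L, nrow(beta), ncol(beta), dimnames = dimnames(beta))
    if (!all(dim(detectionP) == dim(beta)) || !all(dim(beadCount) == dim(beta)))
        stop("detectionP/beadCount dimensions do not match beta")
    if (nrow(sampleSheet) != ncol(beta))
        stop("sample sheet rows (", nrow(sampleSheet),
             ") do not match beta columns (", ncol(beta), ")")
    if (nrow(probeAnnotation) != nrow(beta))
        stop("probe annotation rows (", nrow(probeAnnotation),
             ") do not match beta rows (", nrow(beta), ")")
    sampleSheet <- .validateSheet(as.data.frame(sampleSheet))
    probeAnnotation <- .validateAnnotation(as.data.frame(probeAnnotation))
    rownames(beta) <- probeAnnotation$probe_id
    colnames(beta) <- sampleSheet$sample_id
    dimnames(detectionP) <- dimnames(beadCount) <- dimnames(beta)
    se <- SummarizedExperiment(
        assays = list(beta = beta, detectionP = detectionP,
                      beadCount = beadCount),
        colData = DataFrame(sampleSheet, row.names = sampleSheet$sample_id),
        rowData = DataFrame(probeAnnotation,
                            row.names = probeAnnotation$probe_id))
    new("MethylationSet", se)
}

#' @describeIn MethylationSet beta-value assay
#' @param object,x a MethylationSet
#' @export
betaValues <- function(object) assay(object, "beta")

#' @describeIn MethylationSet M values (logit2 of clipped beta)
#' @param clip clipping bound passed to \code{\link{betaToM}}
#' @export
mValues <- function(object, clip = 0.001) betaToM(betaValues(object), clip = clip)

#' @describeIn MethylationSet detection p-value assay
#' @export
detectionP <- function(object) assay(object, "detectionP")

#' @describeIn MethylationSet bead-count assay
#' @export
beadCounts <- function(object) assay(object, "beadCount")

#' @describeIn MethylationSet sample sheet as a data.frame
#' @export
sampleSheet <- function(object) as.data.frame(colData(object))

#' @describeIn MethylationSet probe annotation as a data.frame
#' @export
probeAnnotation <- function(object) as.data.frame(rowData(object))

#' Replace the beta assay (keeping masks and metadata)
#'
#' @param object a MethylationSet
#' @param value numeric matrix of the same shape
#' @return the updated object
#' @export
`betaValues<-` <- function(object, value) {
    stopifnot(all(dim(value) == dim(object)))
    dimnames(value) <- dimnames(assay(object, "beta"))
    assay(object, "beta") <- value
    object
}

setMethod("show", "MethylationSet", function(object) {
    cat("MethylationSet:", nrow(object), "probes x", ncol(object), "samples\n")
    st <- table(colData(object)$status)
    cat("  status:", paste(names(st), st, sep = "=", collapse = " "), "\n")
    ti <- table(colData(object)$tissue)
    cat("  tissue:", paste(names(ti), ti, sep = "=", collapse = " "), "\n")
    nmiss <- sum(is.na(assay(object, "beta")))
    cat("  missing beta cells:", nmiss, "\n")
    invisible(NULL)
})

#' Per-probe differential-methylation results
#'
#' One row per probe per contrast: model coefficient on the M scale,
#' (possibly moderated) t statistic, residual degrees of freedom, p,
#' BH q, covariate-adjusted group mean beta values, deltabeta (case mean
#' minus CON mean) and the dual-criterion DM flag.
#'
#' @slot results data.frame of per-probe statistics
#' @slot params list of fitting/calling parameters
#' @export
setClass("DMResult",
         representation(results = "data.frame", params = "list"))

setValidity("DMResult", function(object) {
    need <- c("probe_id", "contrast", "coef", "t", "df", "p", "q",
              "mean_ref", "mean_case", "delta_beta", "dm")
    miss <- setdiff(need, colnames(object@results))
    if (length(miss))
        return(paste("missing result columns:", paste(miss, collapse = ", ")))
    db <- object@results$delta_beta
    if (any(abs(db) > 1 + 1e-8, na.rm = TRUE))
        return("delta_beta outside [-1, 1]")
    TRUE
})

#' @describeIn DMResult the per-probe results table
#' @param object a DMResult
#' @export
dmTable <- function(object) object@results

#' @describeIn DMResult probe ids flagged DM, optionally for one contrast
#' @param contrast contrast name such as "SB" (vs reference), or NULL for all
#' @export
dmHits <- function(object, contrast = NULL) {
    res <- object@results
    if (!is.null(contrast)) res <- res[res$contrast %in% contrast, ]
    unique(res$probe_id[!is.na(res$dm) & res$dm])
}

setMethod("show", "DMResult", function(object) {
    res <- object@results
    cat("DMResult:", length(unique(res$probe_id)), "probes,",
        length(unique(res$contrast)), "contrast(s)\n")
    for (ct in unique(res$contrast)) {
        r <- res[res$contrast == ct, ]
        cat(sprintf("  %s: %d tested, %d DM (FDR<%s & |deltabeta|>=%s)\n",
                    ct, sum(!is.na(r$p)), sum(r$dm, na.rm = TRUE),
                    format(object@params$fdr %||% NA),
                    format(object@params$delta %||% NA)))
    }
    invisible(NULL)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Report of the four-filter persistent-hit cascade
#'
#' Records, for each filter in order, the surviving probe set; survivor
#' sets are nested and counts non-increasing.
#'
#' @slot filters character vector of filter names in application order
#' @slot survivors list of character vectors, one per filter
#' @slot input character vector of candidate probes fed to filter 1
#' @slot removed data.frame mapping each removed probe to the filter that
#'   removed it
#' @export
setClass("PersistenceReport",
         representation(filters = "character", survivors = "list",
                        input = "character", removed = "data.frame"))

setValidity("PersistenceReport", function(object) {
    if (length(object@survivors) != length(object@filters))
        return("one survivor set per filter required")
    prev <- object@input
    for (s in object@survivors) {
        if (!all(s %in% prev)) return("survivor sets must be nested")
        prev <- s
    }
    TRUE
})

#' @describeIn PersistenceReport survivor counts after each filter
#' @param object a PersistenceReport
#' @export
survivorCounts <- function(object) {
    stats::setNames(lengths(object@survivors), object@filters)
}

#' @describeIn PersistenceReport survivors after the last filter
#' @export
persistentHits <- function(object) {
    object@survivors[[length(object@survivors)]]
}

#' @describeIn PersistenceReport survivor set after a given filter (by
#'   index or name)
#' @param filter filter index or name
#' @export
survivors <- function(object, filter) {
    if (is.character(filter)) filter <- match(filter, object@filters)
    object@survivors[[filter]]
}

setMethod("show", "PersistenceReport", function(object) {
    cat("PersistenceReport:", length(object@input), "candidate probes\n")
    counts <- survivorCounts(object)
    cat("  cascade:", length(object@input), "->",
        paste(counts, collapse = " -> "), "\n")
    for (i in seq_along(object@filters))
        cat(sprintf("  %d. %-22s %d survive\n", i, object@filters[i], counts[i]))
    invisible(NULL)
})
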