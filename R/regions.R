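# running mean with partial windows at the edges
.runMean <- function(x, window = 3) {
    if (window <= 1 || length(x) < 2) return(x)
    half <- (window - 1) %/% 2
    n <- length(x)
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - half, 1)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect differentially methylated regions by bump hunting
#'
#' Per chromosome, probe-level model coefficients are smoothed with a
#' running mean over neighbouring probes; maximal runs of same-sign
#' smoothed coefficients exceeding \code{coefThresh}, with gaps between
#' adjacent member probes of at most \code{maxgap} base pairs, form
#' candidate regions; runs of fewer than \code{minProbes} members are
#' dropped. Each region is scored by its area (sum of |smoothed
#' coefficient|). Probes are sorted by position internally, so the
#' result does not depend on input order; scaling all coefficients by a
#' positive constant (with the threshold scaled accordingly) leaves the
#' segmentation unchanged.
#'
#' @param coef named numeric vector of per-probe coefficients (M scale).
#' @param annotation data.frame with \code{probe_id}, \code{chrom} and
#'   \code{position} for (at least) the probes in \code{coef}.
#' @param maxgap maximum gap between adjacent member probes (bp).
#' @param minProbes minimum probes per region.
#' @param coefThresh smoothed-coefficient magnitude threshold; defaults
#'   to the 75th percentile of |smoothed coefficients|.
#' @param window running-mean window (probes).
#' @return data.frame of regions: chrom, start, end (1-based,
#'   inclusive), n_probes, probe ids (comma-separated), mean smoothed
#'   coefficient, direction and area. The threshold used is attached as
#'   attribute \code{coefThresh}.
#' @export
findDMRs <- function(coef, annotation, maxgap = 300, minProbes = 3,
                     coefThresh = NULL, window = 3) {
    ann <- annotation[match(names(coef), annotation$probe_id), ]
    hasPos <- !is.na(ann$chrom) & !is.na(ann$position)
    if (any(!hasPos)) {
        warning(sum(!hasPos), " probe(s) without genomic position excluded")
        coef <- coef[hasPos]; ann <- ann[hasPos, ]
    }
    ok <- !is.na(coef)
    coef <- coef[ok]; ann <- ann[ok, ]
    ord <- order(ann$chrom, ann$position)
    coef <- coef[ord]; ann <- ann[ord, ]

    sm <- numeric(length(coef))
    for (ch in unique(ann$chrom)) {
        ix <- which(ann$chrom == ch)
        sm[ix] <- .runMean(coef[ix], window)
    }
    if (is.null(coefThresh))
        coefThresh <- stats::quantile(abs(sm), 0.75, names = FALSE)

    cand <- abs(sm) > coefThresh
    sgn <- sign(sm)
    gapBreak <- c(TRUE, ann$chrom[-1] != ann$chrom[-length(sm)] |
                        diff(ann$position) > maxgap)
    newRun <- !cand | gapBreak | c(TRUE, sgn[-1] != sgn[-length(sm)])
    runId <- cumsum(newRun)
    runId[!cand] <- NA
    keepRuns <- names(which(table(runId) >= minProbes))
    regions <- lapply(keepRuns, function(r) {
        ix <- which(!is.na(runId) & runId == as.integer(r))
        data.frame(chrom = ann$chrom[ix[1]],
                   start = min(ann$position[ix]),
                   end = max(ann$position[ix]),
                   n_probes = length(ix),
                   probes = paste(ann$probe_id[ix], collapse = ","),
                   mean_coef = mean(sm[ix]),
                   direction = ifelse(mean(sm[ix]) > 0, "hyper", "hypo"),
                   area = sum(abs(sm[ix])),
                   stringsAsFactors = FALSE)
    })
    out <- if (length(regions)) do.call(rbind, regions) else
        data.frame(chrom = character(0), start = integer(0),
                   end = integer(0), n_probes = integer(0),
                   probes = character(0), mean_coef = numeric(0),
                   direction = character(0), area = numeric(0))
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "coefThresh") <- coefThresh
    out
}

#' Permutation q values for detected regions
#'
#' Status labels are permuted (within tissue) \code{nIter} times, the
#' per-probe models refit and the region scan repeated at the observed
#' coefficient threshold; each observed region's empirical p is the
#' fraction of permutations whose maximum region area reaches its area
#' (a max-statistic, family-wise null), with the add-one correction.
#' BH adjustment across regions gives q.
#'
#' @param regions data.frame from \code{\link{findDMRs}} (its
#'   \code{coefThresh} attribute is reused).
#' @param object the \linkS4class{MethylationSet} the regions came from.
#' @param contrast case group of the scanned coefficient.
#' @param reference reference group.
#' @param covariates additive covariates of the per-probe models.
#' @param maxgap,minProbes,window scan parameters (must match the
#'   original call).
#' @param nIter number of permutations (must be positive).
#' @param seed seed for the permutation stream.
#' @return \code{regions} with \code{perm_p} and \code{q} columns.
#' @export
dmrQvalues <- function(regions, object, contrast = "SB",
                       reference = "CON",
                       covariates = c("sex", "ga_weeks"),
                       maxgap = 300, minProbes = 3, window = 3,
                       nIter = 1000, seed = 1) {
    if (nIter < 1) stop("nIter must be positive")
    thr <- attr(regions, "coefThresh")
    if (is.null(thr)) stop("regions lack the coefThresh attribute")
    sheet <- sampleSheet(object)
    use <- sheet$status %in% c(reference, contrast)
    sub <- object[, use]
    sheet <- sampleSheet(sub)
    M <- mValues(sub)
    ann <- probeAnnotation(sub)
    covars <- if (length(covariates))
        sheet[, covariates, drop = FALSE] else NULL
    coefOf <- function(status) {
        fit <- .dmCore(M, factor(status, levels = c(reference, contrast)),
                       covars, moderated = FALSE, minPerGroup = 2,
                       call = FALSE)
        stats::setNames(fit@results$coef, fit@results$probe_id)
    }
    set.seed(seed)
    maxArea <- numeric(nIter)
    tis <- sheet$tissue
    for (i in seq_len(nIter)) {
        perm <- sheet$status
        for (ti in unique(tis)) {
            ix <- which(tis == ti)
            perm[ix] <- sheet$status[ix][sample.int(length(ix))]
        }
        r <- findDMRs(coefOf(perm), ann, maxgap = maxgap,
                      minProbes = minProbes, coefThresh = thr,
                      window = window)
        maxArea[i] <- if (nrow(r)) max(r$area) else 0
    }
    regions$perm_p <- vapply(regions$area, function(a)
        (1 + sum(maxArea >= a - 1e-12)) / (nIter + 1), 0)
    regions$q <- bhFDR(regions$perm_p)
    regions
}

#' Write regions as a BED file
#'
#' Converts the 1-based inclusive region coordinates to BED's 0-based
#' half-open convention; the area statistic goes in the score column.
#'
#' @param regions data.frame from \code{\link{findDMRs}}.
#' @param path output path.
#' @export
writeRegionsBED <- function(regions, path) {
    bed <- data.frame(regions$chrom, regions$start - 1L, regions$end,
                      paste0("DMR", seq_len(nrow(regions))),
                      regions$area, ifelse(regions$direction == "hyper",
                                           "+", "-"))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
}

#' Gene-score-resampling enrichment
#'
#' Gene scores are the best (largest) -log10 p over each gene's probes.
#' For every gene set within the size bounds, the observed statistic is
#' the median member score; the null is the same statistic on
#' \code{nIter} random draws of equally many genes from the background,
#' giving an empirical p with the add-one correction (so p is bounded
#' below by 1/(nIter+1)). BH adjustment across tested sets gives the
#' FDR.
#'
#' @param probeP named vector of per-probe p values.
#' @param probeGenes named character vector mapping probe id to gene
#'   (NA for unannotated probes), e.g. from
#'   \code{\link{annotateProbeGene}}.
#' @param geneSets named list of gene vectors (e.g.
#'   \code{\link{readGeneSets}}).
#' @param minSize,maxSize gene-set size bounds (after intersection with
#'   the background).
#' @param nIter resampling iterations.
#' @param seed seed for the resampling stream.
#' @return data.frame per tested set: size, observed median score,
#'   empirical p and BH q; skipped sets are listed in the
#'   \code{skipped} attribute with a reason.
#' @export
geneScoreResampling <- function(probeP, probeGenes, geneSets,
                                minSize = 10, maxSize = 200,
                                nIter = 10000, seed = 1) {
    common <- intersect(names(probeP), names(probeGenes))
    g <- probeGenes[common]
    p <- probeP[common]
    ok <- !is.na(g) & !is.na(p)
    score <- -log10(pmax(p[ok], 1e-300))
    geneScore <- tapply(score, g[ok], max)   # best score per gene
    bg <- names(geneScore)
    set.seed(seed)
    rows <- list(); skipped <- list()
    sizes <- vapply(geneSets, function(s) length(intersect(s, bg)), 0L)
    nullBySize <- list()
    for (nm in names(geneSets)) {
        s <- sizes[[nm]]
        if (s < minSize || s > maxSize) {
            skipped[[nm]] <- sprintf("size %d outside [%d, %d]",
                                     s, minSize, maxSize)
            next
        }
        obs <- stats::median(geneScore[intersect(geneSets[[nm]], bg)])
        key <- as.character(s)
        if (is.null(nullBySize[[key]]))
            nullBySize[[key]] <- vapply(seq_len(nIter), function(i)
                stats::median(geneScore[sample.int(length(geneScore), s)]),
                0)
        null <- nullBySize[[key]]
        rows[[nm]] <- data.frame(
            set = nm, size = s, observed = obs,
            p = (1 + sum(null >= obs - 1e-12)) / (nIter + 1),
            stringsAsFactors = FALSE)
    }
    out <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
        else data.frame(set = character(0), size = integer(0),
                        observed = numeric(0), p = numeric(0))
    out$q <- bhFDR(out$p)
    attr(out, "skipped") <- unlist(skipped)
    out
}

#' Over-representation analysis of a hit gene list
#'
#' Hypergeometric upper-tail test of each gene set against the hit list
#' within the background ("quick list" style), BH-adjusted.
#'
#' @param hits character vector of hit genes.
#' @param geneSets named list of gene vectors.
#' @param background character vector of all eligible genes.
#' @return data.frame per set: set size in background, overlap with the
#'   hits, p and BH q.
#' @export
ora <- function(hits, geneSets, background) {
    background <- unique(background)
    hits <- unique(intersect(hits, background))
    N <- length(background); n <- length(hits)
    rows <- lapply(names(geneSets), function(nm) {
        set <- intersect(geneSets[[nm]], background)
        m <- length(set)
        k <- length(intersect(set, hits))
        p <- if (n == 0 || m == 0) 1 else
            stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
        data.frame(set = nm, size = m, overlap = k, p = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    out$q <- bhFDR(out$p)
    out
}

#' Genomic-feature enrichment of a probe hit set
#'
#' For each feature (high-density CpG island, non-island, shore/shelf,
#' enhancer), a two-sided 2x2 Fisher exact test of hit membership
#' against feature membership within the background probe set; the
#' direction comes from the odds ratio.
#'
#' @param hitProbes character vector of hit probe ids.
#' @param annotation probe annotation data.frame covering the
#'   background.
#' @param background character vector of background probe ids (e.g. all
#'   clean probes); hits must be a subset.
#' @param features features to test; island categories refer to the
#'   \code{island_relation} column, \code{enhancer} to its flag.
#' @param alternative sidedness passed to the Fisher test;
#'   \code{"two.sided"} (default), \code{"greater"} (enrichment only) or
#'   \code{"less"}.
#' @return data.frame per feature: counts, odds ratio, direction and p.
#' @export
featureEnrichment <- function(hitProbes, annotation, background,
                              features = c("high_density_island",
                                           "non_island",
                                           "shore_shelf_other",
                                           "enhancer"),
                              alternative = "two.sided") {
    ann <- annotation[match(background, annotation$probe_id), ]
    if (anyNA(ann$probe_id)) stop("background probes missing from annotation")
    inHit <- background %in% hitProbes
    rows <- lapply(features, function(ft) {
        inFt <- if (ft == "enhancer") {
            if (!"enhancer" %in% colnames(ann))
                stop("feature 'enhancer' absent from annotation")
            ann$enhancer
        } else if (ft %in% ISLAND_LEVELS) {
            ann$island_relation == ft
        } else stop("unknown feature '", ft, "'")
        if (!any(inFt)) stop("feature '", ft, "' absent from annotation")
        tab <- table(factor(inHit, c(TRUE, FALSE)),
                     factor(inFt, c(TRUE, FALSE)))
        ft_test <- stats::fisher.test(tab, alternative = alternative)
        data.frame(feature = ft,
                   hits_in = tab[1, 1], hits_out = tab[1, 2],
                   bg_in = sum(inFt), bg_total = length(background),
                   odds_ratio = unname(ft_test$estimate),
                   direction = ifelse(ft_test$estimate > 1,
                                      "enriched", "depleted"),
                   p = ft_test$p.value, stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
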