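#' Array-average methylation per sample
#'
#' The mean (covariate-adjusted) beta over all clean probes, missing
#' values stripped.
#'
#' @param beta matrix of (adjusted) beta values, probes x samples.
#' @return named numeric vector, one value per sample.
#' @export
arrayAverage <- function(beta) {
    colMeans(beta, na.rm = TRUE)
}

#' Percentage of outlier probes per sample
#'
#' Computed within each tissue: a probe-sample cell is an outlier when
#' it lies more than \code{k} median absolute deviations from the probe
#' median across the tissue's samples; the count is normalised by the
#' number of probes with data in that sample. Probes whose MAD is zero
#' are skipped (no cell can be an outlier there) and counted in the
#' attribute \code{zeroMad}.
#'
#' @param beta matrix of beta values, probes x samples.
#' @param tissue tissue label per sample (a single tissue may be given).
#' @param k MAD multiplier (default 3).
#' @param constant MAD scale constant; 1.4826 (the normal-consistency
#'   default) unless raw MAD is requested with \code{constant = 1}.
#' @return named numeric vector of percentages in \[0, 100\]; samples in
#'   tissues with fewer than 3 samples get \code{NA} with a warning.
#' @export
outlierProbePct <- function(beta, tissue, k = 3, constant = 1.4826) {
    tissue <- rep_len(as.character(tissue), ncol(beta))
    out <- rep(NA_real_, ncol(beta))
    names(out) <- colnames(beta)
    zeroMad <- 0L
    for (ti in unique(tissue)) {
        cols <- which(tissue == ti)
        if (length(cols) < 3) {
            warning("tissue '", ti, "' has fewer than 3 samples; ",
                    "outlier percentage reported as missing")
            next
        }
        b <- beta[, cols, drop = FALSE]
        med <- apply(b, 1, stats::median, na.rm = TRUE)
        madv <- apply(b, 1, stats::mad, constant = constant, na.rm = TRUE)
        usable <- !is.na(madv) & madv > 0
        zeroMad <- zeroMad + sum(!usable, na.rm = TRUE)
        dev <- abs(b - med)
        isOut <- dev > k * madv
        isOut[!usable, ] <- FALSE
        out[cols] <- 100 * colSums(isOut, na.rm = TRUE) /
            colSums(!is.na(b))
    }
    attr(out, "zeroMad") <- zeroMad
    out
}

.ustat <- function(x, y) {
    # Mann-Whitney U for x (midranks)
    r <- rank(c(x, y))
    sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Permutation (or exhaustive) Mann-Whitney test
#'
#' Two-sided test of the Mann-Whitney U statistic (midranks). The null
#' distribution is built by permuting the group labels; a permutation is
#' "as or more extreme" when its |U - n1 n2 / 2| reaches the observed
#' value. The permutation p value uses the add-one correction
#' (1 + hits) / (nPerm + 1), so it is never exactly zero. With
#' \code{exact = TRUE} all label assignments are enumerated instead and
#' the exact tail proportion is returned.
#'
#' @param x,y numeric samples.
#' @param nPerm number of permutations (default 1000).
#' @param seed optional seed for the permutation stream.
#' @param exact enumerate all \code{choose(n1+n2, n1)} splits instead of
#'   sampling (feasible for small n).
#' @return list with \code{p}, the observed \code{U} and the mode used.
#' @export
permMannWhitney <- function(x, y, nPerm = 1000, seed = NULL, exact = FALSE) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    n1 <- length(x); n2 <- length(y)
    if (!n1 || !n2) stop("both groups need data")
    pool <- c(x, y)
    mu <- n1 * n2 / 2
    obs <- abs(.ustat(x, y) - mu)
    if (exact) {
        splits <- utils::combn(n1 + n2, n1)
        stat <- apply(splits, 2, function(ix)
            abs(.ustat(pool[ix], pool[-ix]) - mu))
        p <- mean(stat >= obs - 1e-12)
    } else {
        if (nPerm < 1) stop("nPerm must be positive")
        if (!is.null(seed)) set.seed(seed)
        hits <- 0L
        for (i in seq_len(nPerm)) {
            ix <- sample.int(n1 + n2, n1)
            if (abs(.ustat(pool[ix], pool[-ix]) - mu) >= obs - 1e-12)
                hits <- hits + 1L
        }
        p <- (1 + hits) / (nPerm + 1)
    }
    list(p = p, U = .ustat(x, y), exact = exact)
}

#' Fisher's exact test for a 2 x k table
#'
#' Exact two-sided p value summing all tables with point probability at
#' most that of the observed table (the network algorithm of
#' \code{\link[stats]{fisher.test}}).
#'
#' @param tab 2 x k integer matrix.
#' @return the p value.
#' @export
fisherExact2xk <- function(tab) {
    stats::fisher.test(as.matrix(tab))$p.value
}

#' Clinical characteristics table with group tests
#'
#' Builds a per-group summary of continuous variables (median and
#' range) and categorical variables (counts and percentages), with
#' Mann-Whitney (continuous) or Fisher's exact (categorical) p values
#' for each case group against the reference.
#'
#' @param sheet data.frame of per-sample (or per-individual) variables
#'   including \code{status}.
#' @param continuous,categorical column names to summarise.
#' @param reference reference status group.
#' @return list with \code{summary} (data.frame of formatted cells) and
#'   \code{p} (variables x contrasts matrix).
#' @export
groupClinicalStats <- function(sheet, continuous = "ga_weeks",
                               categorical = "sex", reference = "CON") {
    groups <- unique(sheet$status)
    cases <- setdiff(groups, reference)
    vars <- c(continuous, categorical)
    p <- matrix(NA_real_, length(vars), length(cases),
                dimnames = list(vars, paste0(cases, "_vs_", reference)))
    rows <- list()
    for (v in continuous) {
        x <- sheet[[v]]
        cells <- vapply(groups, function(g) {
            xi <- x[sheet$status == g]
            sprintf("%.1f (%.1f-%.1f)", stats::median(xi, na.rm = TRUE),
                    min(xi, na.rm = TRUE), max(xi, na.rm = TRUE))
        }, "")
        rows[[v]] <- cells
        for (g in cases)
            p[v, paste0(g, "_vs_", reference)] <- suppressWarnings(
                stats::wilcox.test(x[sheet$status == g],
                                   x[sheet$status == reference])$p.value)
    }
    for (v in categorical) {
        x <- sheet[[v]]
        lv <- sort(unique(x[!is.na(x)]))
        cells <- vapply(groups, function(g) {
            xi <- x[sheet$status == g]
            paste(vapply(lv, function(l)
                sprintf("%s=%d (%.0f%%)", l, sum(xi == l, na.rm = TRUE),
                        100 * mean(xi == l, na.rm = TRUE)), ""),
                collapse = ", ")
        }, "")
        rows[[v]] <- cells
        for (g in cases) {
            tab <- vapply(c(g, reference), function(gg)
                vapply(lv, function(l)
                    sum(x[sheet$status == gg] == l, na.rm = TRUE), 0L),
                integer(length(lv)))
            p[v, paste0(g, "_vs_", reference)] <-
                if (length(lv) < 2) 1 else fisherExact2xk(t(tab))
        }
    }
    summary <- do.call(rbind, rows)
    colnames(summary) <- groups
    list(summary = as.data.frame(summary), p = p)
}

#' Repetitive-element methylation summary from pyrosequencing
#'
#' Averages percent methylation across the CpG positions of each
#' element (e.g. four LINE1 promoter CpGs, three Alu CpGs) per sample,
#' flags samples failing the assay QC rule (between-CpG SD above
#' \code{maxSD} percent, or a peak height below \code{minPeak} when a
#' peak-height column is supplied), and reports the per-group median and
#' SD with permutation Mann-Whitney p values against the reference.
#'
#' @param pyro data.frame of percent-methylation values, samples in
#'   rows.
#' @param elements named list mapping element name to its CpG column
#'   names.
#' @param status group label per row of \code{pyro}.
#' @param reference reference group.
#' @param maxSD between-CpG SD threshold (percent).
#' @param peakHeight optional numeric vector of minimum peak heights.
#' @param minPeak peak-height threshold.
#' @param nPerm,seed permutation test control.
#' @return list with \code{perSample} (means and repeat flags) and
#'   \code{groups} (median, SD, n and permutation p per element and
#'   group).
#' @export
repetitiveSummary <- function(pyro, elements, status, reference = "CON",
                              maxSD = 10, peakHeight = NULL, minPeak = 75,
                              nPerm = 1000, seed = NULL) {
    perSample <- data.frame(row.names = rownames(pyro))
    flags <- rep(FALSE, nrow(pyro))
    for (el in names(elements)) {
        m <- as.matrix(pyro[, elements[[el]], drop = FALSE])
        perSample[[el]] <- rowMeans(m, na.rm = TRUE)
        perSample[[paste0(el, "_sd")]] <- apply(m, 1, stats::sd, na.rm = TRUE)
        flags <- flags | perSample[[paste0(el, "_sd")]] > maxSD
    }
    if (!is.null(peakHeight)) flags <- flags | peakHeight < minPeak
    perSample$repeat_flagged <- flags
    groups <- unique(status)
    res <- list()
    for (el in names(elements)) {
        v <- perSample[[el]]
        for (g in groups) {
            vi <- v[status == g]
            pval <- if (g == reference) NA_real_ else
                permMannWhitney(vi, v[status == reference],
                                nPerm = nPerm, seed = seed)$p
            res[[paste(el, g, sep = ".")]] <- data.frame(
                element = el, group = g, n = sum(!is.na(vi)),
                median = stats::median(vi, na.rm = TRUE),
                sd = stats::sd(vi, na.rm = TRUE), perm_p = pval,
                stringsAsFactors = FALSE)
        }
    }
    list(perSample = perSample, groups = do.call(rbind, c(res,
         list(make.row.names = FALSE))))
}

#' Hierarchical clustering of samples
#'
#' Euclidean distances on shared non-missing probes with
#' average-linkage agglomeration; ties are broken deterministically by
#' sample order (the behaviour of \code{\link[stats]{hclust}}).
#'
#' @param beta matrix of (adjusted) beta values, probes x samples.
#' @param k optional number of flat clusters to cut.
#' @return list with the \code{hclust} object, optional flat
#'   \code{clusters}, and a \code{newick} string of the dendrogram.
#' @export
hclustSamples <- function(beta, k = NULL) {
    d <- stats::dist(t(beta))
    if (anyNA(d)) stop("some sample pairs share no observed probes")
    hc <- stats::hclust(d, method = "average")
    out <- list(hclust = hc)
    if (!is.null(k)) out$clusters <- stats::cutree(hc, k = k)
    phy <- ape::as.phylo(hc)
    out$newick <- ape::write.tree(phy)
    out
}

#' Cross-platform validation correlation
#'
#' Spearman (by default) correlation of pyrosequencing percent
#' methylation against array beta values for one probe.
#'
#' @param pyroPct numeric vector of percent methylation.
#' @param arrayBeta numeric vector of array beta values, same samples.
#' @param method correlation method.
#' @return list with \code{r} and \code{p}.
#' @export
platformCorrelation <- function(pyroPct, arrayBeta, method = "spearman") {
    ct <- suppressWarnings(
        stats::cor.test(pyroPct, arrayBeta, method = method))
    list(r = unname(ct$estimate), p = ct$p.value)
}

#' Bonferroni correction
#'
#' @param p vector of p values.
#' @param m number of comparisons; defaults to \code{length(p)}.
#' @return adjusted p values, capped at 1.
#' @export
bonferroni <- function(p, m = length(p)) {
    pmin(1, p * m)
}
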