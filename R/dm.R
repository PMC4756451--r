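#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH adjustment with monotonicity enforcement, order-preserving
#' in the original indexing. Missing p values are left missing and do
#' not count toward the number of tests.
#'
#' @param p numeric vector of p values (NA allowed).
#' @return vector of q values of the same length.
#' @export
bhFDR <- function(p) {
    q <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    q[ok] <- stats::p.adjust(p[ok], method = "BH")
    q
}

# Core per-probe differential-methylation machinery shared by the
# full, candidate-subset, matched-subgroup and cascade analyses.
#
# M: probes x samples; status: factor, reference level first;
# covars: data.frame of additive covariates or NULL.
.dmCore <- function(M, status, covars = NULL, moderated = TRUE,
                    minPerGroup = 3, fdr = 0.05, delta = 0.05,
                    call = TRUE) {
    status <- droplevels(as.factor(status))
    if (nlevels(status) < 2) stop("need at least two status groups")
    keep <- rep(TRUE, ncol(M))
    if (!is.null(covars)) {
        covars <- as.data.frame(covars)
        for (cc in colnames(covars))
            if (is.character(covars[[cc]]))
                covars[[cc]] <- factor(covars[[cc]])
        keep <- stats::complete.cases(covars)
    }
    if (!all(keep)) {
        M <- M[, keep, drop = FALSE]
        status <- droplevels(status[keep])
        covars <- covars[keep, , drop = FALSE]
    }
    df <- data.frame(status = status)
    if (!is.null(covars)) df <- cbind(df, covars)
    X <- stats::model.matrix(~ ., df)
    fit <- .rowOLS(M, X)

    ## covariate-adjusted beta: remove covariate effects evaluated
    ## relative to their means; probes without a fit stay unadjusted
    statusCols <- c("(Intercept)", paste0("status", levels(status)[-1]))
    covCols <- setdiff(colnames(X), statusCols)
    adjM <- M
    if (length(covCols)) {
        cf <- fit$coefficients[, covCols, drop = FALSE]
        cf[is.na(cf)] <- 0
        Xc <- scale(X[, covCols, drop = FALSE], center = TRUE, scale = FALSE)
        adjM <- M - cf %*% t(Xc)
    }
    adjBeta <- mToBeta(adjM)
    gm <- groupDeltaBeta(adjBeta, status, reference = levels(status)[1])

    counts <- .rowCountsByLevel(M, status)
    ok0 <- !is.na(fit$sigma2) & fit$df > 0
    if (moderated) {
        sq <- limma::squeezeVar(fit$sigma2[ok0], fit$df[ok0])
        s2post <- dfprior <- rep(NA_real_, nrow(M))
        s2post[ok0] <- sq$var.post
        dfprior[ok0] <- sq$df.prior
        dfTotal <- fit$df + pmin(dfprior, 1e6)
    } else {
        s2post <- fit$sigma2
        dfTotal <- fit$df
    }

    ref <- levels(status)[1]
    out <- lapply(levels(status)[-1], function(ct) {
        cn <- paste0("status", ct)
        ok <- ok0 & counts[, ref] >= minPerGroup & counts[, ct] >= minPerGroup
        coef <- ifelse(ok, fit$coefficients[, cn], NA_real_)
        tstat <- coef / (fit$stdev.unscaled[, match(cn, colnames(X))] *
                         sqrt(s2post))
        p <- 2 * stats::pt(-abs(tstat), dfTotal)
        data.frame(probe_id = rownames(M), contrast = ct,
                   coef = coef, t = tstat, df = dfTotal,
                   p = p, q = bhFDR(p),
                   mean_ref = gm$means[, ref],
                   mean_case = gm$means[, ct],
                   delta_beta = gm$delta[, ct],
                   dm = NA, stringsAsFactors = FALSE, row.names = NULL)
    })
    res <- new("DMResult", results = do.call(rbind, out),
               params = list(reference = ref, covariates = colnames(covars),
                             moderated = moderated,
                             minPerGroup = minPerGroup,
                             nSamples = ncol(M),
                             nExcludedCovarNA = sum(!keep)))
    if (call) res <- callDM(res, fdr = fdr, delta = delta) else res
}

#' Fit per-CpG linear models of methylation on NTD status
#'
#' Ordinary least squares of M values on status plus additive
#' covariates, per probe on its non-missing values; contrasts of each
#' case group against the reference are extracted. By default residual
#' variances are moderated limma-style (shrunk toward a fitted
#' inverse-chi-square prior, with t evaluated on augmented degrees of
#' freedom); \code{moderated = FALSE} gives plain OLS t statistics.
#' Probes with fewer than \code{minPerGroup} observations in either
#' compared group are reported as missing for that contrast.
#'
#' @param object a \linkS4class{MethylationSet}.
#' @param covariates sample-sheet columns used as additive covariates.
#' @param reference status reference level.
#' @param moderated empirical-Bayes variance moderation switch.
#' @param minPerGroup minimum observations per compared group.
#' @param clip beta clipping bound for the M transform.
#' @return a \linkS4class{DMResult} with statistics, BH q values,
#'   covariate-adjusted group means and deltabeta, but no DM calls yet
#'   (see \code{\link{callDM}}).
#' @export
fitProbeModels <- function(object, covariates = c("sex", "ga_weeks"),
                           reference = "CON", moderated = TRUE,
                           minPerGroup = 3, clip = 0.001) {
    sheet <- sampleSheet(object)
    status <- stats::relevel(factor(sheet$status), ref = reference)
    covars <- if (length(covariates))
        sheet[, covariates, drop = FALSE] else NULL
    .dmCore(mValues(object, clip = clip), status, covars,
            moderated = moderated, minPerGroup = minPerGroup, call = FALSE)
}

#' Covariate-adjusted beta values
#'
#' Removes fitted covariate contributions (evaluated relative to the
#' covariate means, so the status effect and grand level are retained)
#' from the M values and back-transforms to beta. Missing cells stay
#' missing.
#'
#' @inheritParams fitProbeModels
#' @return matrix of adjusted beta values.
#' @export
adjustedBeta <- function(object, covariates = c("sex", "ga_weeks"),
                         reference = "CON", clip = 0.001) {
    sheet <- sampleSheet(object)
    status <- stats::relevel(factor(sheet$status), ref = reference)
    M <- mValues(object, clip = clip)
    covars <- sheet[, covariates, drop = FALSE]
    for (cc in colnames(covars))
        if (is.character(covars[[cc]])) covars[[cc]] <- factor(covars[[cc]])
    keep <- stats::complete.cases(covars)
    X <- stats::model.matrix(~ ., cbind(data.frame(status = status[keep]),
                                        covars[keep, , drop = FALSE]))
    fit <- .rowOLS(M[, keep, drop = FALSE], X)
    covCols <- setdiff(colnames(X),
                       c("(Intercept)", paste0("status",
                                               levels(status)[-1])))
    adjM <- M
    if (length(covCols)) {
        cf <- fit$coefficients[, covCols, drop = FALSE]
        cf[is.na(cf)] <- 0
        Xc <- scale(X[, covCols, drop = FALSE], center = TRUE, scale = FALSE)
        adjM[, keep] <- M[, keep, drop = FALSE] - cf %*% t(Xc)
    }
    mToBeta(adjM)
}

#' Group mean (adjusted) beta and deltabeta
#'
#' Per probe, the mean beta within each status group (missing values
#' stripped) and the difference of each non-reference group mean from
#' the reference mean.
#'
#' @param beta matrix of (adjusted) beta values, probes x samples.
#' @param status vector or factor of group labels per sample.
#' @param reference reference group.
#' @return list with \code{means} (probes x groups) and \code{delta}
#'   (probes x non-reference groups, case minus reference).
#' @export
groupDeltaBeta <- function(beta, status, reference = "CON") {
    status <- stats::relevel(droplevels(as.factor(status)), ref = reference)
    means <- sapply(levels(status), function(g) {
        m <- rowMeans(beta[, status == g, drop = FALSE], na.rm = TRUE)
        m[is.nan(m)] <- NA
        m
    })
    if (!is.matrix(means)) means <- matrix(means, nrow = 1,
                                           dimnames = list(NULL, levels(status)))
    delta <- means[, -1, drop = FALSE] - means[, 1]
    list(means = means, delta = delta)
}

#' Call differentially methylated sites with the dual criterion
#'
#' A probe is DM for a contrast when its BH q value is below
#' \code{fdr} and the magnitude of its covariate-adjusted group
#' difference reaches \code{delta} (both directions by default).
#'
#' @param object a \linkS4class{DMResult}.
#' @param fdr FDR threshold (default 0.05).
#' @param delta minimum |deltabeta| (default 0.05).
#' @param twoSided if FALSE only positive deltabeta (hypermethylation in
#'   the case group) qualifies.
#' @return the \linkS4class{DMResult} with the \code{dm} flags set.
#' @export
callDM <- function(object, fdr = 0.05, delta = 0.05, twoSided = TRUE) {
    res <- object@results
    mag <- if (twoSided) abs(res$delta_beta) else res$delta_beta
    res$dm <- !is.na(res$q) & !is.na(mag) & res$q < fdr & mag >= delta
    res$dm[is.na(res$q) | is.na(res$delta_beta)] <- NA
    object@results <- res
    object@params$fdr <- fdr
    object@params$delta <- delta
    object@params$twoSided <- twoSided
    object
}

#' Full differential-methylation analysis of one tissue
#'
#' Convenience wrapper: per-CpG linear models, BH q values per contrast,
#' covariate-adjusted group means and deltabeta, and dual-criterion DM
#' calls.
#'
#' @inheritParams fitProbeModels
#' @inheritParams callDM
#' @return a called \linkS4class{DMResult}.
#' @export
dmAnalysis <- function(object, covariates = c("sex", "ga_weeks"),
                       reference = "CON", moderated = TRUE,
                       minPerGroup = 3, fdr = 0.05, delta = 0.05,
                       clip = 0.001) {
    sheet <- sampleSheet(object)
    status <- stats::relevel(factor(sheet$status), ref = reference)
    covars <- if (length(covariates))
        sheet[, covariates, drop = FALSE] else NULL
    .dmCore(mValues(object, clip = clip), status, covars,
            moderated = moderated, minPerGroup = minPerGroup,
            fdr = fdr, delta = delta, call = TRUE)
}

#' Candidate-subset differential methylation
#'
#' The identical procedure restricted to a probe subset, with the FDR
#' computed within the subset only.
#'
#' @inheritParams dmAnalysis
#' @param probes probe ids (or row indices) of the candidate subset.
#' @return a called \linkS4class{DMResult} for the subset.
#' @export
candidateSubsetDM <- function(object, probes, ...) {
    if (!length(probes)) stop("empty candidate probe set")
    dmAnalysis(object[probes, ], ...)
}

#' Gestational-age-matched SB vs non-SB analysis
#'
#' Pools the AN and CON samples into a non-SB group, restricts to a
#' gestational-age window, and refits SB vs non-SB with sex and
#' gestational age as additive covariates.
#'
#' @param object a \linkS4class{MethylationSet}.
#' @param gaWindow inclusive gestational-age window in weeks.
#' @param covariates additive covariates.
#' @inheritParams dmAnalysis
#' @return a called \linkS4class{DMResult} with contrast \code{SB} vs
#'   reference \code{nonSB}.
#' @export
matchedSubgroupDM <- function(object, gaWindow = c(19, 24),
                              covariates = c("sex", "ga_weeks"),
                              moderated = TRUE, minPerGroup = 3,
                              fdr = 0.05, delta = 0.05, clip = 0.001) {
    sheet <- sampleSheet(object)
    inWin <- !is.na(sheet$ga_weeks) & sheet$ga_weeks >= gaWindow[1] &
        sheet$ga_weeks <= gaWindow[2]
    if (!any(inWin)) stop("no samples in gestational-age window")
    sub <- object[, inWin]
    sheet <- sampleSheet(sub)
    status <- factor(ifelse(sheet$status == "SB", "SB", "nonSB"),
                     levels = c("nonSB", "SB"))
    if (nlevels(droplevels(status)) < 2)
        stop("gestational-age window leaves fewer than two groups")
    covars <- if (length(covariates))
        sheet[, covariates, drop = FALSE] else NULL
    .dmCore(mValues(sub, clip = clip), status, covars,
            moderated = moderated, minPerGroup = minPerGroup,
            fdr = fdr, delta = delta, call = TRUE)
}

#' Plot-ready p-value histogram table
#'
#' @param object a \linkS4class{DMResult}.
#' @param breaks histogram breakpoints on \[0,1\].
#' @return data.frame of bin edges and counts per contrast.
#' @export
pvalueHistogramTable <- function(object, breaks = seq(0, 1, 0.05)) {
    res <- object@results
    do.call(rbind, lapply(unique(res$contrast), function(ct) {
        p <- res$p[res$contrast == ct & !is.na(res$p)]
        counts <- table(cut(p, breaks, include.lowest = TRUE))
        data.frame(contrast = ct, bin_lo = utils::head(breaks, -1),
                   bin_hi = breaks[-1], count = as.integer(counts),
                   stringsAsFactors = FALSE)
    }))
}

#' Plot-ready volcano table (deltabeta vs -log10 q)
#'
#' @param object a \linkS4class{DMResult}.
#' @return data.frame with one row per tested probe per contrast.
#' @export
volcanoTable <- function(object) {
    res <- object@results
    data.frame(probe_id = res$probe_id, contrast = res$contrast,
               delta_beta = res$delta_beta,
               neg_log10_q = -log10(res$q),
               p = res$p, dm = res$dm, stringsAsFactors = FALSE)
}
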