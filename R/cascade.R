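#' Post-hoc covariate-association filter
#'
#' For each hit probe, the status effect is removed (residuals of the
#' per-probe status model) and the residual methylation is tested
#' against each study covariate — regression F test, which covers both
#' categorical (ANOVA) and continuous covariates. A probe is dropped
#' when its smallest covariate p value, Bonferroni-corrected for the
#' number of covariates tested (\code{adjust = "none"} disables the
#' correction), falls below \code{alpha}.
#'
#' @param hits character vector of candidate probe ids.
#' @param object the internal \linkS4class{MethylationSet}.
#' @param covariates sample-sheet columns to test.
#' @param alpha per-probe significance threshold (default 0.01);
#'   0 disables removal.
#' @param adjust correction of the per-probe minimum p across
#'   covariates: \code{"bonferroni"} (default) or \code{"none"}.
#' @return surviving probe ids.
#' @export
covariatePosthocFilter <- function(hits, object,
                                   covariates = c("ga_weeks", "sex",
                                                  "plate", "chip", "row"),
                                   alpha = 0.01,
                                   adjust = c("bonferroni", "none")) {
    adjust <- match.arg(adjust)
    sheet <- sampleSheet(object)
    miss <- setdiff(covariates, colnames(sheet))
    if (length(miss))
        stop("covariates absent from sample sheet: ",
             paste(miss, collapse = ", "))
    if (!length(hits)) return(character(0))
    M <- mValues(object)[hits, , drop = FALSE]
    Xs <- stats::model.matrix(~ factor(sheet$status))
    fit0 <- .rowOLS(M, Xs)
    res <- M - tcrossprod(fit0$coefficients, Xs)
    minP <- rep(Inf, length(hits))
    for (v in covariates) {
        x <- sheet[[v]]
        keepV <- !is.na(x)
        x <- x[keepV]
        if (length(unique(x)) < 2) next   # constant covariate
        resV <- res[, keepV, drop = FALSE]
        Xv <- if (is.numeric(x)) stats::model.matrix(~ x)
              else stats::model.matrix(~ droplevels(factor(x)))
        if (ncol(Xv) < 2) next   # constant covariate: nothing to test
        fitv <- .rowOLS(resV, Xv)
        nObs <- rowSums(!is.na(resV))
        rss1 <- fitv$sigma2 * fitv$df
        mu <- rowMeans(resV, na.rm = TRUE)
        rss0 <- rowSums((resV - mu)^2, na.rm = TRUE)
        df1 <- fitv$df
        dfNum <- (nObs - 1) - df1
        f <- ((rss0 - rss1) / dfNum) / (rss1 / df1)
        p <- stats::pf(f, dfNum, df1, lower.tail = FALSE)
        minP <- pmin(minP, p, na.rm = TRUE)
    }
    if (adjust == "bonferroni") minP <- pmin(1, minP * length(covariates))
    hits[!(minP < alpha)]
}

#' Control-concordance filter against an external cohort
#'
#' Fits internal-control vs external-control models at the hit probes
#' and removes every probe differentially methylated between the two
#' control groups at the given FDR (computed within the tested hit
#' set).
#'
#' @param hits candidate probe ids.
#' @param object internal \linkS4class{MethylationSet} (its CON samples
#'   are used).
#' @param external \linkS4class{MethylationSet} of external control
#'   samples.
#' @param fdr FDR threshold for control-group DM.
#' @return surviving probe ids.
#' @export
controlConcordanceFilter <- function(hits, object, external, fdr = 0.05) {
    if (ncol(external) == 0) stop("external cohort is empty")
    if (!length(hits)) return(character(0))
    conIdx <- sampleSheet(object)$status == "CON"
    if (!any(conIdx)) stop("no internal CON samples")
    if (!all(hits %in% rownames(external)))
        stop("external cohort lacks some hit probes")
    w <- .rowWelch(mValues(object[hits, conIdx]),
                   mValues(external[hits, ]))
    q <- bhFDR(w$p)
    hits[!(q < fdr) | is.na(q)]
}

# Vectorised per-probe Welch two-sample comparison (NA-aware). The two
# cohorts get their own variances: with a small external group carrying
# its own variance structure, a pooled-variance t would be badly
# miscalibrated.
.rowWelch <- function(X, Y) {
    nX <- rowSums(!is.na(X)); nY <- rowSums(!is.na(Y))
    mX <- rowMeans(X, na.rm = TRUE); mY <- rowMeans(Y, na.rm = TRUE)
    vX <- rowSums((X - mX)^2, na.rm = TRUE) / pmax(nX - 1, 1)
    vY <- rowSums((Y - mY)^2, na.rm = TRUE) / pmax(nY - 1, 1)
    se2 <- vX / nX + vY / nY
    t <- (mY - mX) / sqrt(se2)
    df <- se2^2 / (vX^2 / (nX^2 * pmax(nX - 1, 1)) +
                   vY^2 / (nY^2 * pmax(nY - 1, 1)))
    bad <- nX < 2 | nY < 2 | se2 <= 0
    t[bad] <- NA; df[bad] <- NA
    list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
         diff = mY - mX)
}

#' External replication filter (dual DM criterion)
#'
#' Dual-criterion differential-methylation call of the internal case
#' group against the external controls, restricted to the surviving hit
#' set: probes must be DM at the FDR threshold with |deltabeta| at
#' least \code{delta} to survive.
#'
#' @inheritParams controlConcordanceFilter
#' @param case internal case group compared to the external controls.
#' @param delta minimum |deltabeta| (case mean beta minus external
#'   control mean beta).
#' @return surviving probe ids.
#' @export
externalDMFilter <- function(hits, object, external, case = "SB",
                             fdr = 0.05, delta = 0.05) {
    if (ncol(external) == 0) stop("external cohort is empty")
    if (!length(hits)) return(character(0))
    caseIdx <- sampleSheet(object)$status == case
    if (!any(caseIdx)) stop("no internal ", case, " samples")
    if (!all(hits %in% rownames(external)))
        stop("external cohort lacks some hit probes")
    w <- .rowWelch(mValues(external[hits, ]),
                   mValues(object[hits, caseIdx]))
    q <- bhFDR(w$p)
    db <- rowMeans(betaValues(object)[hits, caseIdx, drop = FALSE],
                   na.rm = TRUE) -
        rowMeans(betaValues(external)[hits, , drop = FALSE], na.rm = TRUE)
    hits[!is.na(q) & q < fdr & !is.na(db) & abs(db) >= delta]
}

#' Run the four-filter persistent-hit cascade
#'
#' Starting from the probes significant at the FDR threshold in the
#' internal case-control comparison, applies in order: (1) the
#' deltabeta magnitude criterion; (2) the post-hoc covariate filter;
#' (3) the control-concordance filter against the external cohort; and
#' (4) the external dual-criterion replication filter. Survivor sets
#' are nested by construction and every count is recorded.
#'
#' @param object internal \linkS4class{MethylationSet}.
#' @param external external-control \linkS4class{MethylationSet}
#'   sharing the probe universe.
#' @param dm optional precomputed \linkS4class{DMResult} for
#'   \code{object} (with q values); computed via
#'   \code{\link{dmAnalysis}} when absent.
#' @param contrast internal case group.
#' @param fdr,delta dual DM calling thresholds.
#' @param alpha post-hoc covariate threshold.
#' @param covariates covariates of the post-hoc filter.
#' @param dmCovariates additive covariates of the internal DM model
#'   (used only when \code{dm} is not supplied).
#' @param moderated variance moderation switch for the internal DM
#'   model (used only when \code{dm} is not supplied). The
#'   cross-cohort fits of filters 3 and 4 always use per-probe Welch
#'   statistics: the external cohort carries its own variance
#'   structure, so neither a pooled variance nor moderation across the
#'   combined cohorts is justified.
#' @return a \linkS4class{PersistenceReport}.
#' @export
runCascade <- function(object, external, dm = NULL, contrast = "SB",
                       fdr = 0.05, delta = 0.05, alpha = 0.01,
                       covariates = c("ga_weeks", "sex", "plate",
                                      "chip", "row"),
                       dmCovariates = c("sex", "ga_weeks"),
                       moderated = TRUE) {
    if (is.null(dm))
        dm <- dmAnalysis(object, covariates = dmCovariates,
                         moderated = moderated, fdr = fdr, delta = delta)
    res <- dmTable(dm)
    res <- res[res$contrast == contrast, ]
    input <- res$probe_id[!is.na(res$q) & res$q < fdr]
    s1 <- intersect(input, dmHits(callDM(dm, fdr = fdr, delta = delta),
                                  contrast))
    s2 <- covariatePosthocFilter(s1, object, covariates = covariates,
                                 alpha = alpha)
    s3 <- controlConcordanceFilter(s2, object, external, fdr = fdr)
    s4 <- externalDMFilter(s3, object, external, case = contrast,
                           fdr = fdr, delta = delta)
    filters <- c("delta_beta_criterion", "covariate_posthoc",
                 "control_concordance", "external_replication")
    surv <- list(s1, s2, s3, s4)
    removedAt <- c(
        stats::setNames(rep(filters[1], length(setdiff(input, s1))),
                        setdiff(input, s1)),
        stats::setNames(rep(filters[2], length(setdiff(s1, s2))),
                        setdiff(s1, s2)),
        stats::setNames(rep(filters[3], length(setdiff(s2, s3))),
                        setdiff(s2, s3)),
        stats::setNames(rep(filters[4], length(setdiff(s3, s4))),
                        setdiff(s3, s4)))
    new("PersistenceReport", filters = filters, survivors = surv,
        input = input,
        removed = data.frame(probe_id = names(removedAt),
                             filter = unname(removedAt),
                             stringsAsFactors = FALSE))
}

#' Supervised clustering of samples on a probe set
#'
#' Hierarchical clustering (Euclidean, average linkage) of the samples
#' restricted to the given probes, with the adjusted Rand index of the
#' two-cluster cut against NTD status.
#'
#' @param object a \linkS4class{MethylationSet}.
#' @param probes probe ids to cluster on (at least 2).
#' @param k number of flat clusters (default 2).
#' @return list with the \code{hclust} object, flat \code{clusters},
#'   \code{ari} and the \code{newick} dendrogram string.
#' @export
supervisedCluster <- function(object, probes, k = 2) {
    if (length(probes) < 2) stop("need at least 2 probes to cluster on")
    hc <- hclustSamples(betaValues(object)[probes, , drop = FALSE], k = k)
    hc$ari <- mclust::adjustedRandIndex(hc$clusters,
                                        sampleSheet(object)$status)
    hc
}
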