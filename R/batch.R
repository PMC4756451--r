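#' Empirical-Bayes location/scale batch adjustment of M values
#'
#' Removes per-batch location and scale differences from each probe with
#' parametric empirical-Bayes shrinkage: per-probe batch effects are
#' standardised against the pooled model fit, shrunk toward their
#' across-probe priors (normal for location, inverse-gamma for scale,
#' solved iteratively), and removed; the grand location and pooled scale
#' are restored. Covariates supplied via \code{mod} (a design matrix
#' without intercept) are preserved. Missing cells are excluded from all
#' estimates and stay missing.
#'
#' @param M numeric matrix (probes x samples) of M values, NA allowed.
#' @param batch vector of batch labels, one per sample.
#' @param mod optional covariate design matrix (samples x q, no
#'   intercept) whose effects are protected during adjustment.
#' @param tol,maxIter convergence control of the shrinkage iterations.
#' @return list with \code{adjusted} (matrix like \code{M}) and
#'   \code{model} (per-batch shrunken location/scale estimates and prior
#'   hyperparameters).
#' @export
ebBatchAdjust <- function(M, batch, mod = NULL, tol = 1e-6, maxIter = 200) {
    batch <- droplevels(as.factor(batch))
    L <- nlevels(batch)
    if (L < 2) {
        return(list(adjusted = M,
                    model = list(levels = levels(batch), gamma.star = NULL,
                                 delta.star = NULL, priors = NULL)))
    }
    nb <- .rowCountsByLevel(M, batch)           # probes x L
    if (any(nb < 2)) {
        bad <- which(rowSums(nb < 2) > 0)
        stop(length(bad), " probe(s) have a batch level with fewer than 2 ",
             "observed values; remove them first with dropUnderrepresented()")
    }
    B <- stats::model.matrix(~ 0 + batch)
    X <- if (is.null(mod)) B else cbind(B, mod)
    fit <- .rowOLS(M, X)
    if (anyNA(fit$coefficients))
        stop("batch design is rank deficient for some probes")
    gammaHatRaw <- fit$coefficients[, seq_len(L), drop = FALSE]
    nTot <- rowSums(!is.na(M))
    grand <- rowSums(gammaHatRaw * nb) / nTot
    covContrib <- if (is.null(mod)) 0 else
        fit$coefficients[, -seq_len(L), drop = FALSE] %*% t(mod)
    standMean <- grand + covContrib             # probes x samples (recycled)
    if (!is.matrix(standMean))
        standMean <- matrix(grand, nrow(M), ncol(M))
    resid <- M - tcrossprod(fit$coefficients, X)
    varPooled <- rowSums(resid^2, na.rm = TRUE) / nTot
    varPooled <- pmax(varPooled, 1e-12)
    Z <- (M - standMean) / sqrt(varPooled)

    gammaStar <- deltaStar <- gammaHat <- deltaHat <-
        matrix(NA_real_, nrow(M), L)
    priors <- vector("list", L)
    for (b in seq_len(L)) {
        cols <- which(batch == levels(batch)[b])
        Zb <- Z[, cols, drop = FALSE]
        g <- rowMeans(Zb, na.rm = TRUE)
        d <- apply(Zb, 1, stats::var, na.rm = TRUE)
        gammaHat[, b] <- g; deltaHat[, b] <- d
        gbar <- mean(g); t2 <- stats::var(g)
        m <- mean(d); s2 <- stats::var(d)
        aprior <- (2 * s2 + m^2) / s2
        bprior <- (m * s2 + m^3) / s2
        priors[[b]] <- list(gamma.bar = gbar, t2 = t2,
                            a.prior = aprior, b.prior = bprior)
        if (!is.finite(t2) || t2 <= 0 || !is.finite(s2) || s2 <= 0 ||
            !is.finite(aprior) || !is.finite(bprior)) {
            gammaStar[, b] <- g
            deltaStar[, b] <- pmax(d, 1e-12)
            next
        }
        nbb <- nb[, b]
        gOld <- g; dOld <- d
        for (it in seq_len(maxIter)) {
            gNew <- (nbb * t2 * g + dOld * gbar) / (nbb * t2 + dOld)
            sum2 <- rowSums((Zb - gNew)^2, na.rm = TRUE)
            dNew <- (0.5 * sum2 + bprior) / (nbb / 2 + aprior - 1)
            change <- max(abs(gNew - gOld) / (abs(gOld) + 1e-12),
                          abs(dNew - dOld) / (dOld + 1e-12))
            gOld <- gNew; dOld <- dNew
            if (change < tol) break
        }
        gammaStar[, b] <- gOld
        deltaStar[, b] <- pmax(dOld, 1e-12)
    }
    out <- M
    for (b in seq_len(L)) {
        cols <- which(batch == levels(batch)[b])
        out[, cols] <- (Z[, cols, drop = FALSE] - gammaStar[, b]) /
            sqrt(deltaStar[, b]) * sqrt(varPooled) +
            standMean[, cols, drop = FALSE]
    }
    dimnames(out) <- dimnames(M)
    list(adjusted = out,
         model = list(levels = levels(batch),
                      gamma.hat = gammaHat, delta.hat = deltaHat,
                      gamma.star = gammaStar, delta.star = deltaStar,
                      priors = priors, grand.mean = grand,
                      var.pooled = varPooled))
}

#' Sequential batch correction across several technical variables
#'
#' Applies \code{\link{ebBatchAdjust}} once per batch variable, in the
#' given order (plate, then chip row, then chip id by default); the
#' order matters and is recorded, together with each round's model, in
#' \code{metadata(mset)$batchReport}. Biological covariates are
#' preserved in every round.
#'
#' @param object a \linkS4class{MethylationSet}.
#' @param variables sample-sheet columns to correct, in order.
#' @param preserve sample-sheet columns protected as covariates.
#' @param clip beta clipping bound for the M transform.
#' @return the adjusted \linkS4class{MethylationSet}.
#' @export
sequentialAdjust <- function(object, variables = c("plate", "row", "chip"),
                             preserve = c("status", "sex", "ga_weeks"),
                             clip = 0.001) {
    sheet <- sampleSheet(object)
    miss <- setdiff(variables, colnames(sheet))
    if (length(miss))
        stop("batch variables absent from sample sheet: ",
             paste(miss, collapse = ", "))
    mod <- NULL
    if (length(preserve)) {
        df <- sheet[, preserve, drop = FALSE]
        for (cc in colnames(df))
            if (is.character(df[[cc]])) df[[cc]] <- factor(df[[cc]])
        mod <- stats::model.matrix(~ ., df)[, -1, drop = FALSE]
    }
    M <- mValues(object, clip = clip)
    report <- list(order = variables, rounds = list())
    for (v in variables) {
        adj <- ebBatchAdjust(M, sheet[[v]], mod = mod)
        M <- adj$adjusted
        report$rounds[[v]] <- adj$model
    }
    betaValues(object) <- mToBeta(M)
    metadata(object)$batchReport <- report
    object
}

#' Remove probes under-represented in a batch level
#'
#' Drops every probe for which some level of one of the batch variables
#' has fewer than two observed (non-missing) values — the condition
#' under which per-batch scale cannot be estimated.
#'
#' @param object a \linkS4class{MethylationSet}.
#' @param variables sample-sheet batch columns to scan.
#' @return list with the reduced \code{mset}, \code{nRemoved} and the
#'   removed probe ids.
#' @export
dropUnderrepresented <- function(object,
                                 variables = c("plate", "row", "chip")) {
    sheet <- sampleSheet(object)
    b <- betaValues(object)
    bad <- rep(FALSE, nrow(b))
    for (v in variables) {
        nb <- .rowCountsByLevel(b, sheet[[v]])
        bad <- bad | rowSums(nb < 2) > 0
    }
    list(mset = object[!bad, ], nRemoved = sum(bad),
         removed = rownames(b)[bad])
}

#' Associate principal components with batch and phenotype variables
#'
#' Runs a PCA of the samples (probes mean-imputed where missing) and
#' scores the top \code{k} components against each supplied variable:
#' one-way ANOVA F test for categorical variables, Pearson correlation
#' test for continuous ones. Large, significant associations of leading
#' components with a technical variable indicate a batch effect.
#'
#' @param object a \linkS4class{MethylationSet} or an M-value matrix.
#' @param variables data.frame of per-sample variables; defaults to the
#'   batch and phenotype columns of the sample sheet.
#' @param k number of components to score.
#' @return list with \code{p} (k x variables matrix of p values) and
#'   \code{varExplained} (fraction of variance per component).
#' @export
pcAssociation <- function(object,
                          variables = NULL,
                          k = 10) {
    if (is(object, "MethylationSet")) {
        if (is.null(variables))
            variables <- sampleSheet(object)[, c("plate", "chip", "row",
                                                 "status", "sex", "ga_weeks")]
        M <- mValues(object)
    } else {
        M <- object
        if (is.null(variables)) stop("variables required for matrix input")
    }
    pm <- rowMeans(M, na.rm = TRUE)
    idx <- which(is.na(M), arr.ind = TRUE)
    if (nrow(idx)) M[idx] <- pm[idx[, 1]]
    M <- M[apply(M, 1, stats::sd) > 0, , drop = FALSE]
    pc <- stats::prcomp(t(M), center = TRUE, scale. = FALSE)
    k <- min(k, ncol(pc$x))
    scores <- pc$x[, seq_len(k), drop = FALSE]
    p <- matrix(NA_real_, k, ncol(variables),
                dimnames = list(colnames(scores), colnames(variables)))
    for (v in colnames(variables)) {
        x <- variables[[v]]
        for (i in seq_len(k)) {
            p[i, v] <- if (is.numeric(x))
                stats::cor.test(scores[, i], x)$p.value
            else {
                f <- droplevels(factor(x))
                if (nlevels(f) < 2) NA_real_
                else stats::anova(stats::lm(scores[, i] ~ f))$`Pr(>F)`[1]
            }
        }
    }
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    list(p = p, varExplained = ve[seq_len(k)])
}
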