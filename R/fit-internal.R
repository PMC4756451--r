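# Vectorised per-probe ordinary least squares with missing-value support.
#
# Rows of Y (probes) sharing a missingness pattern are fit together with
# one cross-product solve; complete rows (the common case) are a single
# matrix operation. Rows whose reduced design is rank deficient or has
# no residual degrees of freedom are returned as NA.
#
# Y: probes x samples; X: samples x p design matrix.
# Returns coefficients (probes x p), sigma2, df, stdev.unscaled
# (sqrt of the diagonal of (X'X)^-1, probes x p).
.rowOLS <- function(Y, X) {
    n <- ncol(Y); p <- ncol(X)
    nr <- nrow(Y)
    coef <- matrix(NA_real_, nr, p, dimnames = list(rownames(Y), colnames(X)))
    unscaled <- matrix(NA_real_, nr, p)
    sigma2 <- df <- rep(NA_real_, nr)
    miss <- is.na(Y)
    hasNA <- rowSums(miss) > 0L
    fitGroup <- function(rows, keep) {
        Xs <- X[keep, , drop = FALSE]
        qrX <- qr(Xs)
        if (length(keep) <= p || qrX$rank < p) return()
        XtXi <- chol2inv(qr.R(qrX))
        B <- Y[rows, keep, drop = FALSE] %*% Xs %*% XtXi
        res <- Y[rows, keep, drop = FALSE] - B %*% t(Xs)
        rdf <- length(keep) - p
        coef[rows, ] <<- B
        sigma2[rows] <<- rowSums(res^2) / rdf
        df[rows] <<- rdf
        unscaled[rows, ] <<- matrix(sqrt(diag(XtXi)), length(rows), p,
                                    byrow = TRUE)
    }
    if (any(!hasNA)) fitGroup(which(!hasNA), seq_len(n))
    if (any(hasNA)) {
        pats <- vapply(which(hasNA), function(i)
            paste(which(miss[i, ]), collapse = ","), "")
        for (pt in unique(pats)) {
            rows <- which(hasNA)[pats == pt]
            keep <- setdiff(seq_len(n), as.integer(strsplit(pt, ",")[[1]]))
            fitGroup(rows, keep)
        }
    }
    list(coefficients = coef, sigma2 = sigma2, df = df,
         stdev.unscaled = unscaled)
}

# Non-missing sample counts per probe within each level of a factor.
.rowCountsByLevel <- function(Y, f) {
    f <- as.factor(f)
    out <- vapply(levels(f), function(l)
        rowSums(!is.na(Y[, f == l, drop = FALSE])), numeric(nrow(Y)))
    if (!is.matrix(out))
        out <- matrix(out, nrow = nrow(Y),
                      dimnames = list(rownames(Y), levels(f)))
    out
}
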