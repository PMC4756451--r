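#' Convert beta values to M values
#'
#' M = log2(beta / (1 - beta)). Beta values are clipped into
#' \code{[clip, 1 - clip]} first so that fully (un)methylated probes do
#' not map to infinity; the default clip of 0.001 bounds M at about
#' +/- 9.97.
#'
#' @param beta numeric vector or matrix of beta values in \[0, 1\]
#'   (NA allowed).
#' @param clip clipping bound in (0, 0.5); use 0 to disable.
#' @return object of the same shape on the M scale.
#' @seealso \code{\link{mToBeta}}
#' @export
betaToM <- function(beta, clip = 0.001) {
    rng <- suppressWarnings(range(beta, na.rm = TRUE))
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
        stop("beta values outside [0, 1]")
    b <- pmin(pmax(beta, clip), 1 - clip)
    out <- log2(b / (1 - b))
    if (is.matrix(beta)) dimnames(out) <- dimnames(beta)
    out
}

#' Convert M values back to beta values
#'
#' beta = 2^M / (2^M + 1); the inverse of \code{\link{betaToM}} inside
#' the clipping bounds.
#'
#' @param m numeric vector or matrix of M values (NA allowed).
#' @return object of the same shape on the beta scale.
#' @export
mToBeta <- function(m) {
    out <- 1 / (1 + 2^(-m))
    if (is.matrix(m)) dimnames(out) <- dimnames(m)
    out
}
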