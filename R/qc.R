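#' Sample identity check via SNP (rs) probe correlation
#'
#' Computes pairwise Pearson correlations between samples on the
#' genotyping (rs) probes, whose trimodal beta values act as a
#' fingerprint of the individual. Every sample whose individual
#' contributed more than one sample must find a sample of the same
#' individual as its nearest neighbour; anything else is flagged as a
#' potential identity mismatch.
#'
#' @param object a \linkS4class{MethylationSet} still containing rs
#'   probes.
#' @return data.frame with, per sample: nearest-neighbour sample, its
#'   correlation, whether a same-individual partner exists, whether the
#'   nearest neighbour matches, and the mismatch flag.
#' @export
checkSampleIdentity <- function(object) {
    ann <- probeAnnotation(object)
    rs <- ann$probe_class == "rs"
    if (!any(rs)) stop("no rs probes present; identity check impossible")
    b <- betaValues(object)[rs, , drop = FALSE]
    cc <- stats::cor(b, use = "pairwise.complete.obs")
    diag(cc) <- -Inf
    nn <- apply(cc, 1, which.max)
    sheet <- sampleSheet(object)
    ind <- sheet$individual_id
    hasPartner <- ind %in% ind[duplicated(ind)]
    matched <- ind[nn] == ind
    data.frame(
        sample_id = sheet$sample_id,
        individual_id = ind,
        nearest = sheet$sample_id[nn],
        nearest_individual = ind[nn],
        r = cc[cbind(seq_len(ncol(b)), nn)],
        has_partner = hasPartner,
        matched = matched,
        flagged = hasPartner & !matched,
        stringsAsFactors = FALSE, row.names = NULL)
}

#' Predict sample sex from sex-chromosome probes
#'
#' Samples are cut into two clusters (Euclidean distance, average
#' linkage) on chrX/chrY beta profiles; the cluster with the higher mean
#' chrY beta is labelled male (female Y probes carry only background
#' signal). Discordance with the recorded sex is flagged. A warning is
#' issued when the two clusters are not separated by Y signal, as
#' happens for single-sex inputs.
#'
#' @param object a \linkS4class{MethylationSet} containing chrX and chrY
#'   probes.
#' @param minYGap minimum between-cluster difference in mean chrY beta
#'   regarded as a real sex split.
#' @return data.frame with predicted sex, recorded sex and a discordance
#'   flag per sample.
#' @export
checkSex <- function(object, minYGap = 0.1) {
    ann <- probeAnnotation(object)
    xy <- ann$chrom %in% c("chrX", "chrY")
    isY <- ann$chrom == "chrY"
    if (!any(isY)) stop("no chrY probes present; sex check impossible")
    b <- betaValues(object)[xy, , drop = FALSE]
    # impute per-probe means so distances use all probes
    pm <- rowMeans(b, na.rm = TRUE)
    miss <- which(is.na(b), arr.ind = TRUE)
    if (nrow(miss)) b[miss] <- pm[miss[, 1]]
    cl <- stats::cutree(stats::hclust(stats::dist(t(b)), "average"), k = 2)
    yMean <- colMeans(betaValues(object)[isY, , drop = FALSE], na.rm = TRUE)
    mu <- tapply(yMean, cl, mean)
    if (length(mu) < 2 || abs(diff(mu)) < minYGap) {
        warning("sex clusters not separated by chrY signal; ",
                "input may be single-sex")
        maleCluster <- integer(0)
    } else maleCluster <- as.integer(names(mu)[which.max(mu)])
    predicted <- ifelse(cl %in% maleCluster, "M", "F")
    sheet <- sampleSheet(object)
    data.frame(
        sample_id = sheet$sample_id,
        predicted_sex = predicted,
        recorded_sex = sheet$sex,
        discordant = !is.na(sheet$sex) & predicted != sheet$sex,
        stringsAsFactors = FALSE, row.names = NULL)
}

# Robust z with a scale floor: count metrics are Poisson-like, so when
# the across-sample MAD collapses (near-constant counts) the deviation
# is scaled by sqrt(median + 1) instead of flagging every fluctuation.
.robustZ <- function(x, countScale = FALSE) {
    med <- stats::median(x)
    m <- stats::mad(x)
    if (countScale) m <- max(m, sqrt(med + 1))
    dev <- abs(x - med)
    ifelse(dev == 0, 0, dev / max(m, .Machine$double.eps))
}

#' Per-sample quality metrics and outlier flags
#'
#' Three metrics per sample: the number of probes with detection p above
#' \code{detp}, the number with fewer than \code{minBeads} bead
#' replicates, and the mean detection p over passing cells (a
#' background signal-quality proxy available at the beta level;
#' outright failures are already counted by the first metric). A sample
#' is an outlier if any metric lies more than \code{nmad} median
#' absolute deviations from the across-sample median.
#'
#' @param object a \linkS4class{MethylationSet}.
#' @param detp,minBeads reliability thresholds.
#' @param nmad robust-z cutoff (default 3).
#' @return data.frame of metrics with an \code{outlier} flag.
#' @export
sampleQuality <- function(object, detp = 0.01, minBeads = 3, nmad = 3) {
    dp <- detectionP(object)
    bc <- beadCounts(object)
    dpPass <- dp; dpPass[dpPass > detp] <- NA
    met <- data.frame(
        sample_id = sampleSheet(object)$sample_id,
        n_detection_failures = colSums(dp > detp, na.rm = TRUE),
        n_low_bead = colSums(bc < minBeads, na.rm = TRUE),
        mean_detp = colMeans(dpPass, na.rm = TRUE),
        mean_beta = colMeans(betaValues(object), na.rm = TRUE),
        stringsAsFactors = FALSE, row.names = NULL)
    z <- cbind(.robustZ(met$n_detection_failures, countScale = TRUE),
               .robustZ(met$n_low_bead, countScale = TRUE),
               .robustZ(met$mean_detp))
    met$outlier <- apply(z, 1, max) > nmad
    met
}

#' Remove systemically poor and untrustworthy probe classes
#'
#' Removes, in this order: (1) systemically poor probes (detection p >
#' \code{detp} in more than \code{frac} of samples, or fewer than
#' \code{minBeads} beads in more than \code{frac} of samples); (2)
#' sex-chromosome probes; (3) polymorphic probes; (4) probes that
#' cross-hybridize to the sex chromosomes. Each probe is counted in the
#' first category that applies, so the category counts are disjoint and
#' sum to the total removed.
#'
#' @param object a \linkS4class{MethylationSet}.
#' @param frac fraction-of-samples threshold (default 0.20).
#' @param detp,minBeads reliability thresholds.
#' @return list with the filtered \code{mset}, per-category \code{counts}
#'   and the removed probe ids per category.
#' @export
filterProbes <- function(object, frac = 0.20, detp = 0.01, minBeads = 3) {
    stopifnot(frac > 0, frac < 1)
    ann <- probeAnnotation(object)
    dp <- detectionP(object)
    bc <- beadCounts(object)
    poor <- rowMeans(dp > detp, na.rm = TRUE) > frac |
        rowMeans(bc < minBeads, na.rm = TRUE) > frac
    sexchr <- ann$chrom %in% c("chrX", "chrY")
    cats <- list(
        poor_quality = poor,
        sex_chromosome = sexchr & !poor,
        polymorphic = ann$polymorphic & !poor & !sexchr,
        cross_hybridizing = ann$cross_hybridizing & !poor & !sexchr &
            !ann$polymorphic)
    removed <- lapply(cats, function(m) ann$probe_id[m])
    drop <- Reduce(`|`, cats)
    list(mset = object[!drop, ],
         counts = vapply(cats, sum, 0L),
         removed = removed)
}

#' Mask unreliable probe-sample pairs as missing
#'
#' Beta values with detection p above \code{detp} or bead count below
#' \code{minBeads} are replaced by \code{NA}; all other values are left
#' untouched. Downstream means strip missing values.
#'
#' @inheritParams filterProbes
#' @return the \linkS4class{MethylationSet} with masked beta values.
#' @export
maskBadValues <- function(object, detp = 0.01, minBeads = 3) {
    b <- betaValues(object)
    b[detectionP(object) > detp | beadCounts(object) < minBeads] <- NA
    betaValues(object) <- b
    object
}

#' Collapse technical replicate pairs
#'
#' Samples sharing an individual id and tissue are treated as technical
#' replicates; the first by sample-sheet order is kept. The Pearson
#' correlation of each pair across probes is reported, a quality metric
#' that can be tracked at every pipeline stage.
#'
#' @param object a \linkS4class{MethylationSet}.
#' @return list with the deduplicated \code{mset} and a \code{report}
#'   data.frame (kept, dropped, r).
#' @export
dedupeReplicates <- function(object) {
    sheet <- sampleSheet(object)
    key <- paste(sheet$individual_id, sheet$tissue)
    dup <- duplicated(key)
    if (!any(dup))
        return(list(mset = object,
                    report = data.frame(kept = character(0),
                                        dropped = character(0),
                                        r = numeric(0))))
    b <- betaValues(object)
    rep <- lapply(which(dup), function(i) {
        j <- which(key == key[i])[1]
        data.frame(kept = sheet$sample_id[j], dropped = sheet$sample_id[i],
                   r = stats::cor(b[, i], b[, j],
                                  use = "pairwise.complete.obs"),
                   stringsAsFactors = FALSE)
    })
    list(mset = object[, !dup], report = do.call(rbind, rep))
}

#' Remove the SNP (rs) genotyping probes
#'
#' @param object a \linkS4class{MethylationSet}.
#' @return the object without rs-class probes.
#' @export
dropRsProbes <- function(object) {
    object[probeAnnotation(object)$probe_class != "rs", ]
}

#' Run the full sample and probe quality-control stage
#'
#' Applies, in order: identity and sex checks (reported, not enforced),
#' sample-quality outlier removal, probe filtering, masking of
#' unreliable probe-sample pairs, technical-replicate collapsing and
#' removal of the rs probes.
#'
#' @inheritParams filterProbes
#' @param nmad robust-z cutoff for sample outliers.
#' @param dropOutliers whether flagged samples are removed.
#' @return list with the clean \code{mset} and a \code{report} list
#'   (identity, sex, sample quality, per-category probe counts,
#'   replicate correlations, rs-probe count).
#' @export
runQC <- function(object, frac = 0.20, detp = 0.01, minBeads = 3,
                  nmad = 3, dropOutliers = TRUE) {
    report <- list()
    report$identity <- tryCatch(checkSampleIdentity(object),
                                error = function(e) conditionMessage(e))
    report$sex <- tryCatch(suppressWarnings(checkSex(object)),
                           error = function(e) conditionMessage(e))
    report$sample_quality <- sampleQuality(object, detp, minBeads, nmad)
    if (dropOutliers && any(report$sample_quality$outlier))
        object <- object[, !report$sample_quality$outlier]
    fp <- filterProbes(object, frac, detp, minBeads)
    report$probe_counts <- fp$counts
    object <- maskBadValues(fp$mset, detp, minBeads)
    dd <- dedupeReplicates(object)
    report$replicates <- dd$report
    object <- dd$mset
    report$n_rs_removed <- sum(probeAnnotation(object)$probe_class == "rs")
    object <- dropRsProbes(object)
    list(mset = object, report = report)
}
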