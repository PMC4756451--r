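#' Simulation configuration for synthetic 450k datasets
#'
#' Defaults reproduce the study conditions of the cohort the pipeline is
#' designed for: 19 control (CON), 22 spina bifida (SB) and 15
#' anencephaly (AN) individuals, per-group male fractions 7/19, 16/22
#' and 5/15, gestational ages uniform on 14.5-23.9, 19.4-23.7 and
#' 16.7-23.3 weeks respectively, 65 SNP (rs) genotyping probes, three
#' processing plates, twelve-sample chips with six row positions, and
#' two technical replicate pairs.
#'
#' @slot nProbes number of probes.
#' @slot nPerGroup named integer vector of individuals per status group.
#' @slot tissues tissues sampled from every individual.
#' @slot maleFraction named numeric, male fraction per status group.
#' @slot gaRange named list of \code{c(lo, hi)} gestational-age ranges
#'   (weeks) per group.
#' @slot dmTruth list of planted effects, each
#'   \code{list(probes=, contrast=, delta=)} with \code{delta} the target
#'   group difference on the beta scale (applied as the equivalent
#'   additive shift on the M scale).
#' @slot sexProbes,sexEffect autosomal probes with an additive M-scale
#'   shift in males.
#' @slot gaProbes,gaSlope autosomal probes with a linear M-scale
#'   gestational-age slope (per week, centred at 20 weeks).
#' @slot nPlates,nRows,chipSize batch layout; chips are nested in plates.
#' @slot batchShiftM named numeric \code{c(plate=, row=, chip=)}: M-scale
#'   location shift magnitude of the extreme levels of each variable
#'   (levels are spaced evenly in \code{[-shift, +shift]}).
#' @slot pctChrX,pctChrY fractions of probes placed on chrX / chrY.
#' @slot nRsProbes number of trimodal SNP probes (identical within an
#'   individual).
#' @slot failureRates named numeric \code{c(detection=, beads=)}:
#'   per-cell probabilities of a detection failure (p > 0.01) and of a
#'   low bead count (< 3).
#' @slot nReplicatePairs,replicateNoiseM technical replicate pairs and
#'   their M-scale technical noise.
#' @slot noiseSdM,priorDf probe noise scale on M and the chi-square
#'   degrees of freedom governing probe-to-probe variance spread.
#' @slot mixtureWeights weights of the low/intermediate/high baseline
#'   beta mixture.
#' @slot tissueEffectFrac,tissueEffectSd fraction of autosomal probes
#'   with tissue-specific offsets and their M-scale SD (multi-tissue
#'   configurations only).
#' @slot nOutlierSamples,outlierFailureRate trailing samples planted as
#'   quality outliers and their elevated detection-failure rate.
#' @slot seed integer seed; all draws come from one stream in documented
#'   order.
#' @export
setClass("SimulationConfig", representation(
    nProbes = "integer", nPerGroup = "integer", tissues = "character",
    maleFraction = "numeric", gaRange = "list", dmTruth = "list",
    sexProbes = "integer", sexEffect = "numeric",
    gaProbes = "integer", gaSlope = "numeric",
    nPlates = "integer", nRows = "integer", chipSize = "integer",
    batchShiftM = "numeric", pctChrX = "numeric", pctChrY = "numeric",
    nRsProbes = "integer", failureRates = "numeric",
    nReplicatePairs = "integer", replicateNoiseM = "numeric",
    noiseSdM = "numeric", priorDf = "numeric", mixtureWeights = "numeric",
    tissueEffectFrac = "numeric", tissueEffectSd = "numeric",
    nOutlierSamples = "integer", outlierFailureRate = "numeric",
    seed = "integer"))

.autosomalCount <- function(config) {
    config@nProbes - config@nRsProbes -
        round(config@pctChrX * config@nProbes) -
        round(config@pctChrY * config@nProbes)
}

setValidity("SimulationConfig", function(object) {
    msg <- character(0)
    if (object@nProbes < 1) msg <- c(msg, "nProbes must be positive")
    if (any(object@nPerGroup < 0)) msg <- c(msg, "group sizes must be >= 0")
    if (!all(STATUS_LEVELS %in% names(object@nPerGroup)))
        msg <- c(msg, "nPerGroup needs CON, SB and AN entries")
    pr <- c(object@failureRates, object@maleFraction,
            object@pctChrX, object@pctChrY, object@outlierFailureRate)
    if (any(pr < 0 | pr > 1)) msg <- c(msg, "probabilities must be in [0,1]")
    nAuto <- .autosomalCount(object)
    eff <- c(unlist(lapply(object@dmTruth, `[[`, "probes")),
             object@sexProbes, object@gaProbes)
    if (length(eff) && (max(eff) > nAuto || min(eff) < 1))
        msg <- c(msg, paste0("effect probes must be autosomal cg indices",
                             " (1..", nAuto, "), disjoint from sex-chromosome",
                             " and rs probes"))
    for (ct in vapply(object@dmTruth, `[[`, "", "contrast"))
        if (!ct %in% c("SB", "AN"))
            msg <- c(msg, "dmTruth contrasts must be 'SB' or 'AN'")
    if (object@nRsProbes < 0 || object@nReplicatePairs < 0)
        msg <- c(msg, "counts must be >= 0")
    if (object@noiseSdM <= 0) msg <- c(msg, "noiseSdM must be positive")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimulationConfig constructor with study-condition defaults
#' @param nProbes,nPerGroup,tissues,maleFraction,gaRange,dmTruth see slots
#' @param sexProbes,sexEffect,gaProbes,gaSlope see slots
#' @param nPlates,nRows,chipSize,batchShiftM,pctChrX,pctChrY see slots
#' @param nRsProbes,failureRates,nReplicatePairs,replicateNoiseM see slots
#' @param noiseSdM,priorDf,mixtureWeights see slots
#' @param tissueEffectFrac,tissueEffectSd see slots
#' @param nOutlierSamples,outlierFailureRate see slots
#' @param seed see slots
#' @export
SimulationConfig <- function(nProbes = 10000,
                             nPerGroup = c(CON = 19, SB = 22, AN = 15),
                             tissues = "kidney",
                             maleFraction = c(CON = 7/19, SB = 16/22, AN = 5/15),
                             gaRange = list(CON = c(14.5, 23.9),
                                            SB = c(19.4, 23.7),
                                            AN = c(16.7, 23.3)),
                             dmTruth = list(),
                             sexProbes = integer(0), sexEffect = 0.5,
                             gaProbes = integer(0), gaSlope = 0.05,
                             nPlates = 3, nRows = 6, chipSize = 12,
                             batchShiftM = c(plate = 0.2, row = 0.1, chip = 0.1),
                             pctChrX = 0.02, pctChrY = 0.005,
                             nRsProbes = 65,
                             failureRates = c(detection = 0.001, beads = 0.001),
                             nReplicatePairs = 2, replicateNoiseM = 0.1,
                             noiseSdM = 0.45, priorDf = 10,
                             mixtureWeights = c(low = 0.4, mid = 0.2, high = 0.4),
                             tissueEffectFrac = 0.3, tissueEffectSd = 1.5,
                             nOutlierSamples = 0, outlierFailureRate = 0.3,
                             seed = 1) {
    new("SimulationConfig",
        nProbes = as.integer(nProbes),
        nPerGroup = stats::setNames(as.integer(nPerGroup), names(nPerGroup)),
        tissues = tissues, maleFraction = maleFraction, gaRange = gaRange,
        dmTruth = lapply(dmTruth, function(x) {
            x$probes <- as.integer(x$probes); x
        }),
        sexProbes = as.integer(sexProbes), sexEffect = sexEffect,
        gaProbes = as.integer(gaProbes), gaSlope = gaSlope,
        nPlates = as.integer(nPlates), nRows = as.integer(nRows),
        chipSize = as.integer(chipSize), batchShiftM = batchShiftM,
        pctChrX = pctChrX, pctChrY = pctChrY,
        nRsProbes = as.integer(nRsProbes), failureRates = failureRates,
        nReplicatePairs = as.integer(nReplicatePairs),
        replicateNoiseM = replicateNoiseM,
        noiseSdM = noiseSdM, priorDf = priorDf,
        mixtureWeights = mixtureWeights,
        tissueEffectFrac = tissueEffectFrac, tissueEffectSd = tissueEffectSd,
        nOutlierSamples = as.integer(nOutlierSamples),
        outlierFailureRate = outlierFailureRate,
        seed = as.integer(seed))
}

.clipBeta <- function(b, clip = 0.001) pmin(pmax(b, clip), 1 - clip)

.mixtureBeta <- function(n, weights) {
    comp <- sample(c("low", "mid", "high"), n, replace = TRUE,
                   prob = weights[c("low", "mid", "high")])
    b <- numeric(n)
    b[comp == "low"]  <- stats::rbeta(sum(comp == "low"),  2, 25)
    b[comp == "mid"]  <- stats::rbeta(sum(comp == "mid"),  5, 5)
    b[comp == "high"] <- stats::rbeta(sum(comp == "high"), 25, 2)
    .clipBeta(b)
}

# evenly spaced, centred level shifts in [-mag, +mag]
.levelShift <- function(L, mag) {
    if (L <= 1) return(rep(0, max(L, 1)))
    mag * seq(-1, 1, length.out = L)
}

# M-scale shift that moves baseline beta b0 by target delta (clipped)
.deltaToMShift <- function(b0, delta) {
    target <- .clipBeta(b0 + delta)
    log2(target / (1 - target)) - log2(b0 / (1 - b0))
}

.makeAnnotation <- function(config) {
    nP <- config@nProbes
    nX <- round(config@pctChrX * nP)
    nY <- round(config@pctChrY * nP)
    nRs <- config@nRsProbes
    nAuto <- nP - nX - nY - nRs
    chrom <- c(rep(paste0("chr", 1:22),
                   diff(floor(seq(0, nAuto, length.out = 23)))),
               rep("chrX", nX), rep("chrY", nY),
               rep(paste0("chr", 1:22), length.out = nRs))
    ids <- c(sprintf("cg%06d", seq_len(nAuto + nX + nY)),
             if (nRs) sprintf("rs%05d", seq_len(nRs)))
    cls <- c(rep("cg", nAuto + nX + nY), rep("rs", nRs))
    # positions: island-like clusters (short gaps) separated by long gaps
    position <- integer(nP)
    geneOfProbe <- character(nP)
    geneCounter <- 0L
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        inCluster <- stats::runif(length(idx)) < 0.7
        gaps <- ifelse(inCluster,
                       round(stats::runif(length(idx), 30, 280)),
                       round(stats::runif(length(idx), 1000, 50000)))
        position[idx] <- 1e5 + cumsum(gaps)
        # one gene per cluster, some clusters intergenic
        newCluster <- c(TRUE, !inCluster[-1])
        geneId <- cumsum(newCluster) + geneCounter
        geneCounter <- max(geneId)
        named <- stats::runif(length(idx)) < 0.85
        geneOfProbe[idx] <- ifelse(named, sprintf("GENE%05d", geneId), "")
    }
    gene_field <- geneOfProbe
    closest <- geneOfProbe
    multi <- which(nzchar(geneOfProbe) & stats::runif(nP) < 0.10)
    if (length(multi)) {
        other <- sprintf("GENE%05d", geneCounter + seq_along(multi))
        gene_field[multi] <- paste(geneOfProbe[multi], other, sep = ";")
        swap <- stats::runif(length(multi)) < 0.5
        closest[multi] <- ifelse(swap, other, geneOfProbe[multi])
    }
    island <- sample(ISLAND_LEVELS, nP, replace = TRUE,
                     prob = c(0.30, 0.45, 0.25))
    ann <- data.frame(
        probe_id = ids, chrom = chrom, position = position,
        gene_field = gene_field, closest_tss_gene = closest,
        island_relation = island,
        enhancer = stats::runif(nP) < 0.10,
        polymorphic = stats::runif(nP) < 0.045,
        cross_hybridizing = stats::runif(nP) < 0.024,
        probe_class = cls, stringsAsFactors = FALSE)
    ann$gene_field[cls == "rs"] <- ""
    ann$closest_tss_gene[cls == "rs"] <- ""
    ann$polymorphic[cls == "rs"] <- FALSE
    ann$cross_hybridizing[cls == "rs"] <- FALSE
    ann
}

#' Generate a synthetic 450k dataset with known ground truth
#'
#' Baseline beta values are drawn from a three-component mixture (modes
#' near 0.05 and 0.95 plus an intermediate component); all planted
#' effects (group, sex, gestational age, batch) are additive on the M
#' scale and back-transformed, so beta stays in \[0,1\] by construction.
#' SNP (rs) probes are trimodal near 0/0.5/1 and identical for samples
#' sharing an individual id. Detection-p and bead-count matrices carry
#' the planted sporadic failures. The output is deterministic given the
#' seed: all draws come from a single stream in a fixed order (probe
#' baseline, probe variances, annotation, tissue offsets, individual
#' covariates, batch layout, rs genotypes, noise, sex-chromosome
#' adjustments, failures, replicates); planted effect shifts are
#' deterministic, so configs differing only in \code{dmTruth} share all
#' other draws.
#'
#' @param config a \code{\link{SimulationConfig}}.
#' @return list with \code{mset} (a \linkS4class{MethylationSet}) and
#'   \code{truth} (list of data.frames \code{probes} and \code{samples};
#'   effects at non-planted probes are exactly zero).
#' @export
generateDataset <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    set.seed(config@seed)
    nP <- config@nProbes
    nX <- round(config@pctChrX * nP)
    nY <- round(config@pctChrY * nP)
    nRs <- config@nRsProbes
    nAuto <- nP - nX - nY - nRs
    idxX <- if (nX) nAuto + seq_len(nX) else integer(0)
    idxY <- if (nY) nAuto + nX + seq_len(nY) else integer(0)
    idxRs <- if (nRs) nAuto + nX + nY + seq_len(nRs) else integer(0)

    ## 1-2. probe baseline and variances
    b0 <- .mixtureBeta(nP, config@mixtureWeights)
    M0 <- log2(b0 / (1 - b0))
    sdP <- config@noiseSdM * sqrt(config@priorDf /
                                  stats::rchisq(nP, config@priorDf))

    ## 3. annotation
    ann <- .makeAnnotation(config)

    ## 4. tissue offsets
    nTis <- length(config@tissues)
    tisEff <- NULL
    if (nTis > 1) {
        tisEff <- matrix(0, nP, nTis)
        affected <- sample(nAuto, round(config@tissueEffectFrac * nAuto))
        for (t in 2:nTis)
            tisEff[affected, t] <- stats::rnorm(length(affected), 0,
                                                config@tissueEffectSd)
    }

    ## 5. individuals: status, sex, gestational age
    groups <- rep(STATUS_LEVELS, config@nPerGroup[STATUS_LEVELS])
    nInd <- length(groups)
    indId <- sprintf("I%03d", seq_len(nInd))
    sex <- unlist(lapply(STATUS_LEVELS, function(g) {
        n <- config@nPerGroup[[g]]
        nM <- round(n * config@maleFraction[[g]])
        sample(c(rep("M", nM), rep("F", n - nM)))
    }))
    ga <- unlist(lapply(STATUS_LEVELS, function(g) {
        r <- config@gaRange[[g]]
        round(stats::runif(config@nPerGroup[[g]], r[1], r[2]), 1)
    }))

    ## samples: one per individual per tissue
    sampleInd <- rep(seq_len(nInd), times = nTis)
    sampleTis <- rep(config@tissues, each = nInd)
    nS <- length(sampleInd)
    sid <- paste(indId[sampleInd], sampleTis, sep = "_")

    ## 6. batch layout: chips nested in plates, samples shuffled to chips
    nChips <- ceiling(nS / config@chipSize)
    chipOfSample <- rep(seq_len(nChips), each = config@chipSize)[seq_len(nS)]
    if (sum(chipOfSample == nChips) == 1)  # avoid a singleton chip
        chipOfSample[chipOfSample == nChips] <- nChips - 1L
    ord <- sample(nS)
    chip <- integer(nS); posOnChip <- integer(nS)
    chip[ord] <- chipOfSample
    posOnChip[ord] <- stats::ave(chipOfSample, chipOfSample,
                                 FUN = seq_along)
    plateOfChip <- rep_len(seq_len(config@nPlates), max(chip))
    plate <- plateOfChip[chip]
    rowPos <- ((posOnChip - 1L) %% config@nRows) + 1L

    sheet <- data.frame(
        sample_id = sid, individual_id = indId[sampleInd],
        tissue = sampleTis, status = groups[sampleInd],
        sex = sex[sampleInd], ga_weeks = ga[sampleInd],
        plate = paste0("P", plate), chip = sprintf("C%02d", chip),
        row = paste0("R", rowPos), stringsAsFactors = FALSE)

    ## deterministic effect shifts on M
    eff <- matrix(0, nP, nS)
    deltaSB <- deltaAN <- numeric(nP)
    for (tr in config@dmTruth) {
        pr <- tr$probes
        shift <- .deltaToMShift(b0[pr], tr$delta)
        cols <- which(sheet$status == tr$contrast)
        eff[pr, cols] <- eff[pr, cols] + shift
        if (tr$contrast == "SB") deltaSB[pr] <- deltaSB[pr] + tr$delta
        else deltaAN[pr] <- deltaAN[pr] + tr$delta
    }
    sexEff <- numeric(nP); sexEff[config@sexProbes] <- config@sexEffect
    if (length(config@sexProbes)) {
        males <- which(sheet$sex == "M")
        eff[config@sexProbes, males] <- eff[config@sexProbes, males] +
            config@sexEffect
    }
    gaEff <- numeric(nP); gaEff[config@gaProbes] <- config@gaSlope
    if (length(config@gaProbes))
        eff[config@gaProbes, ] <- eff[config@gaProbes, ] +
            outer(rep(config@gaSlope, length(config@gaProbes)),
                  sheet$ga_weeks - 20)
    batchVals <- list(plate = plate, row = rowPos, chip = chip)
    batchShifted <- FALSE
    for (v in names(batchVals)) {
        mag <- config@batchShiftM[[v]]
        if (is.na(mag) || mag == 0) next
        batchShifted <- TRUE
        lv <- batchVals[[v]]
        eff <- eff + matrix(.levelShift(max(lv), mag)[lv], nP, nS,
                            byrow = TRUE)
    }
    if (!is.null(tisEff))
        eff <- eff + tisEff[, match(sampleTis, config@tissues)]

    ## 7. rs genotypes, identical within individual
    rsBeta <- NULL
    if (nRs) {
        geno <- matrix(sample(c(0.03, 0.5, 0.97), nRs * nInd, replace = TRUE,
                              prob = c(0.25, 0.5, 0.25)), nRs, nInd)
        geno <- .clipBeta(geno + stats::rnorm(nRs * nInd, 0, 0.02))
        rsBeta <- geno[, sampleInd, drop = FALSE]
    }

    ## 8. noise and assembly
    noise <- matrix(stats::rnorm(nP * nS, 0, sdP), nP, nS)
    beta <- mToBeta(M0 + eff + noise)

    ## 9. sex-chromosome structure (modelled by sex only)
    females <- which(sheet$sex == "F")
    if (length(idxX) && length(females))
        beta[idxX, females] <- 0.5 + (beta[idxX, females] - 0.5) * 0.3
    if (length(idxY) && length(females))
        beta[idxY, females] <- matrix(
            stats::rbeta(length(idxY) * length(females), 2, 18),
            length(idxY), length(females))
    if (nRs) beta[idxRs, ] <- rsBeta

    ## 10. planted detection / bead failures
    detP <- matrix(stats::runif(nP * nS, 0, 0.005), nP, nS)
    beads <- matrix(3L + stats::rpois(nP * nS, 9), nP, nS)
    failD <- matrix(stats::runif(nP * nS) < config@failureRates[["detection"]],
                    nP, nS)
    if (config@nOutlierSamples > 0) {
        bad <- nS - seq_len(config@nOutlierSamples) + 1L
        failD[, bad] <- failD[, bad] |
            matrix(stats::runif(nP * length(bad)) < config@outlierFailureRate,
                   nP, length(bad))
    }
    detP[failD] <- stats::runif(sum(failD), 0.011, 0.8)
    failB <- matrix(stats::runif(nP * nS) < config@failureRates[["beads"]],
                    nP, nS)
    beads[failB] <- sample(1:2, sum(failB), replace = TRUE)

    ## 11. technical replicates of the first pairs' first-tissue samples
    repOf <- rep(NA_character_, nS)
    if (config@nReplicatePairs > 0) {
        src <- seq_len(min(config@nReplicatePairs, nInd))
        for (s in src) {
            rb <- mToBeta(betaToM(beta[, s, drop = FALSE]) +
                          stats::rnorm(nP, 0, config@replicateNoiseM))
            if (nRs) rb[idxRs, 1] <- beta[idxRs, s]
            beta <- cbind(beta, rb)
            dpRep <- stats::runif(nP, 0, 0.005)
            fd <- stats::runif(nP) < config@failureRates[["detection"]]
            dpRep[fd] <- stats::runif(sum(fd), 0.011, 0.8)
            detP <- cbind(detP, dpRep)
            bdRep <- 3L + stats::rpois(nP, 9)
            fb <- stats::runif(nP) < config@failureRates[["beads"]]
            bdRep[fb] <- sample(1:2, sum(fb), replace = TRUE)
            beads <- cbind(beads, bdRep)
            sheet <- rbind(sheet, sheet[s, ])
            n <- nrow(sheet)
            sheet$sample_id[n] <- paste0(sheet$sample_id[s], "_rep")
            repOf <- c(repOf, sheet$sample_id[s])
        }
    }
    rownames(sheet) <- NULL

    truthProbes <- data.frame(
        probe_id = ann$probe_id, chrom = ann$chrom,
        position = ann$position, probe_class = ann$probe_class,
        baseline_beta = b0,
        delta_sb = deltaSB, delta_an = deltaAN,
        sex_effect_m = sexEff, ga_slope = gaEff,
        batch_sensitive = batchShifted & ann$probe_class != "rs",
        stringsAsFactors = FALSE)
    truthSamples <- cbind(sheet, replicate_of = repOf,
                          planted_outlier = c(
                              rep(FALSE, nS - config@nOutlierSamples),
                              rep(TRUE, config@nOutlierSamples),
                              rep(FALSE, nrow(sheet) - nS))[seq_len(nrow(sheet))],
                          stringsAsFactors = FALSE)

    mset <- MethylationSet(beta, sheet, ann, detectionP = detP,
                           beadCount = beads)
    list(mset = mset, truth = list(probes = truthProbes,
                                   samples = truthSamples))
}

#' Export / import the ground-truth tables
#'
#' The probe-level truth is written to \code{file} and the sample-level
#' truth (covariates, batch labels, replicate partners) to
#' \code{samplesFile}; both round-trip losslessly through
#' \code{readTruth}.
#'
#' @param truth truth list from \code{\link{generateDataset}}.
#' @param file TSV path for the probe-level table.
#' @param samplesFile TSV path for the sample-level table; defaults to
#'   \code{file} with a \code{_samples} suffix.
#' @return \code{exportTruth}: the paths, invisibly. \code{readTruth}:
#'   the truth list.
#' @export
exportTruth <- function(truth, file, samplesFile = NULL) {
    if (is.null(samplesFile))
        samplesFile <- if (grepl("\\.tsv$", file))
            sub("\\.tsv$", "_samples.tsv", file)
        else paste0(file, "_samples")
    utils::write.table(truth$probes, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    utils::write.table(truth$samples, samplesFile, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(c(file, samplesFile))
}

#' @rdname exportTruth
#' @export
readTruth <- function(file, samplesFile = NULL) {
    if (is.null(samplesFile))
        samplesFile <- if (grepl("\\.tsv$", file))
            sub("\\.tsv$", "_samples.tsv", file)
        else paste0(file, "_samples")
    probes <- utils::read.table(file, header = TRUE, sep = "\t",
                                na.strings = "NA", stringsAsFactors = FALSE)
    samples <- utils::read.table(samplesFile, header = TRUE, sep = "\t",
                                 na.strings = "NA", stringsAsFactors = FALSE)
    probes$probe_class <- as.character(probes$probe_class)
    list(probes = probes, samples = samples)
}

#' Simulate internal and external cohorts with four planted hit classes
#'
#' Builds a two-cohort kidney scenario for exercising the persistent-hit
#' cascade: an internal CON/SB cohort and a small external control
#' cohort sharing the probe set. Four disjoint probe classes are
#' planted, each differentially methylated internally but removable by a
#' specific cascade filter: \code{true_effect} (consistent SB shift vs
#' both control groups, survives everything), \code{batch_driven}
#' (probes whose apparent status effect is induced by a plate shift,
#' through a moderate plate-status confounding of the sample layout;
#' removed by the covariate post-hoc filter), \code{cohort_shift}
#' (external controls shifted vs internal controls, removed by the
#' control-concordance filter) and \code{internal_only} (a modest
#' internal shift whose external contrast falls below the deltabeta
#' criterion, removed by the external DM filter). The internal_only
#' class is modelled as unstable in the external cohort — its external
#' values sit midway between the internal groups with strongly elevated
#' variance, the realistic mechanism by which an internal hit fails to
#' replicate. Cohort sizes default to the kidney study conditions
#' (16 CON, 20 SB, 5 external controls); the external cohort carries
#' somewhat larger technical noise, as expected for data processed
#' elsewhere.
#'
#' @param nProbes total probes; the class blocks occupy the first
#'   \code{4 * nPerClass} with mid-range baselines so planted deltas are
#'   realisable.
#' @param nPerClass probes per planted class.
#' @param nCON,nSB,nExternal cohort sizes.
#' @param delta planted SB-vs-CON group difference (beta scale).
#' @param plateEffectM M-scale plate shift for the batch_driven class.
#' @param plateBias sampling weights over the three plates for CON
#'   samples (reversed for SB): the plate-status confounding that turns
#'   the plate shift into an apparent status effect.
#' @param cohortShift beta-scale shift of external controls for the
#'   cohort_shift class.
#' @param internalDelta,externalGap beta-scale internal shift of the
#'   internal_only class and the external-contrast remainder (kept below
#'   the 0.05 calling threshold; the default puts the external mean
#'   midway between the internal groups).
#' @param unstableExtSdM M-scale noise of the internal_only class in
#'   the external cohort (its cross-cohort instability).
#' @param noiseSdM,extNoiseSdM,priorDf internal / external noise scale
#'   on M and the probe-variance spread, as in
#'   \code{\link{SimulationConfig}}.
#' @param seed integer seed.
#' @return list with \code{internal} and \code{external}
#'   \linkS4class{MethylationSet}s and \code{truth} (probe_id, class).
#' @export
simulateCascadeScenario <- function(nProbes = 4000, nPerClass = 100,
                                    nCON = 16, nSB = 20, nExternal = 5,
                                    delta = 0.25, plateEffectM = 2,
                                    plateBias = c(0.7, 0.2, 0.1),
                                    cohortShift = 0.3,
                                    internalDelta = 0.08,
                                    externalGap = 0.04,
                                    unstableExtSdM = 1.2,
                                    noiseSdM = 0.35, extNoiseSdM = 0.45,
                                    priorDf = 10, seed = 1) {
    set.seed(seed)
    nBlock <- 4L * nPerClass
    stopifnot(nProbes > nBlock)
    b0 <- c(stats::runif(nBlock, 0.35, 0.55),
            .mixtureBeta(nProbes - nBlock, c(low = .4, mid = .2, high = .4)))
    M0 <- log2(b0 / (1 - b0))
    sdP <- noiseSdM * sqrt(priorDf / stats::rchisq(nProbes, priorDf))
    sdPExt <- sdP * extNoiseSdM / noiseSdM
    classes <- rep(c("true_effect", "batch_driven", "cohort_shift",
                     "internal_only", "none"),
                   c(rep(nPerClass, 4), nProbes - nBlock))
    idx <- split(seq_len(nProbes), classes)

    nInt <- nCON + nSB
    status <- c(rep("CON", nCON), rep("SB", nSB))
    sex <- sample(rep(c("M", "F"), length.out = nInt))
    ga <- round(stats::runif(nInt, 15, 24), 1)
    plate <- c(sample(1:3, nCON, replace = TRUE, prob = plateBias),
               sample(1:3, nSB, replace = TRUE, prob = rev(plateBias)))
    sheet <- data.frame(
        sample_id = sprintf("K%03d", seq_len(nInt)),
        individual_id = sprintf("KI%03d", seq_len(nInt)),
        tissue = "kidney", status = status, sex = sex, ga_weeks = ga,
        plate = paste0("P", plate),
        chip = sprintf("C%02d", sample(rep_len(1:5, nInt))),
        row = paste0("R", sample(rep_len(1:6, nInt))),
        stringsAsFactors = FALSE)

    eff <- matrix(0, nProbes, nInt)
    sb <- which(status == "SB")
    for (cl in c("true_effect", "cohort_shift"))
        eff[idx[[cl]], sb] <- .deltaToMShift(b0[idx[[cl]]], delta)
    eff[idx$internal_only, sb] <- .deltaToMShift(b0[idx$internal_only],
                                                 internalDelta)
    eff[idx$batch_driven, ] <- eff[idx$batch_driven, ] +
        matrix(.levelShift(3, plateEffectM)[plate], nPerClass, nInt,
               byrow = TRUE)
    betaInt <- mToBeta(M0 + eff +
                       matrix(stats::rnorm(nProbes * nInt, 0, sdP),
                              nProbes, nInt))

    extSheet <- data.frame(
        sample_id = sprintf("EXT%02d", seq_len(nExternal)),
        individual_id = sprintf("EI%02d", seq_len(nExternal)),
        tissue = "kidney", status = "CON",
        sex = sample(c("M", "F"), nExternal, replace = TRUE),
        ga_weeks = round(stats::runif(nExternal, 15, 24), 1),
        plate = "EXT", chip = "EXT", row = "EXT",
        stringsAsFactors = FALSE)
    effE <- matrix(0, nProbes, nExternal)
    effE[idx$cohort_shift, ] <- .deltaToMShift(b0[idx$cohort_shift],
                                               -cohortShift)
    effE[idx$internal_only, ] <- .deltaToMShift(
        b0[idx$internal_only], internalDelta - externalGap)
    sdExtMat <- matrix(sdPExt, nProbes, nExternal)
    sdExtMat[idx$internal_only, ] <- unstableExtSdM
    betaExt <- mToBeta(M0 + effE +
                       matrix(stats::rnorm(nProbes * nExternal, 0, sdExtMat),
                              nProbes, nExternal))

    ann <- data.frame(
        probe_id = sprintf("cg%06d", seq_len(nProbes)),
        chrom = rep(paste0("chr", 1:22), length.out = nProbes),
        position = 1e5 + 500L * seq_len(nProbes),
        gene_field = "", closest_tss_gene = "",
        island_relation = "non_island", enhancer = FALSE,
        polymorphic = FALSE, cross_hybridizing = FALSE,
        probe_class = "cg", stringsAsFactors = FALSE)

    list(internal = MethylationSet(betaInt, sheet, ann),
         external = MethylationSet(betaExt, extSheet, ann),
         truth = data.frame(probe_id = ann$probe_id, class = classes,
                            stringsAsFactors = FALSE))
}
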