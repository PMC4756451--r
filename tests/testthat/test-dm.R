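test_that("the toy three-sample fit matches hand OLS", {
    beta <- matrix(mToBeta(c(1, 2, 3)), 1, 3)
    ms <- toyMset(beta, c("CON", "CON", "SB"), annotation = toyAnnotation(1))
    fit <- fitProbeModels(ms, covariates = character(0), moderated = FALSE,
                          minPerGroup = 1, clip = 0)
    tb <- dmTable(fit)
    expect_equal(tb$coef, 1.5)
    expect_equal(tb$t, 1.5 / sqrt(0.75), tolerance = 1e-8)
    expect_equal(tb$df, 1)
})

test_that("moderated statistics match the limma oracle on complete data", {
    d <- generateDataset(cleanConfig(17, nProbes = 400))
    M <- mValues(d$mset)
    sheet <- sampleSheet(d$mset)
    fit <- fitProbeModels(d$mset, moderated = TRUE)
    tb <- dmTable(fit)
    tb <- tb[tb$contrast == "SB", ]
    design <- stats::model.matrix(~ factor(status, c("CON", "SB")) +
                                      factor(sex) + ga_weeks, sheet)
    lf <- limma::eBayes(limma::lmFit(M, design))
    expect_equal(tb$t, lf$t[, 2], tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(tb$p, lf$p.value[, 2], tolerance = 1e-6, ignore_attr = TRUE)
    # unmoderated equals plain OLS t
    f0 <- dmTable(fitProbeModels(d$mset, moderated = FALSE))
    ord <- limma::lmFit(M, design)
    tOls <- ord$coefficients[, 2] / (ord$stdev.unscaled[, 2] * ord$sigma)
    expect_equal(f0$t[f0$contrast == "SB"], tOls, tolerance = 1e-6,
                 ignore_attr = TRUE)
})

test_that("BH adjustment matches hand-computed examples and handles NA", {
    expect_equal(bhFDR(c(0.01, 0.02, 0.03)), rep(0.03, 3))
    expect_equal(bhFDR(c(0.005, 0.04, 0.03, 0.8)),
                 c(0.02, 0.0533333333, 0.0533333333, 0.8),
                 tolerance = 1e-9)
    expect_equal(bhFDR(rep(1, 5)), rep(1, 5))
    p <- c(0.01, NA, 0.5)
    q <- bhFDR(p)
    expect_true(is.na(q[2]))
    expect_equal(q[c(1, 3)], bhFDR(p[c(1, 3)]))
})

test_that("BH equals the brute-force step-up on random vectors", {
    set.seed(33)
    for (i in 1:50) {
        p <- runif(sample(2:200, 1))
        expect_equal(bhFDR(p), bruteBH(p), tolerance = 1e-12)
    }
})

test_that("covariate adjustment removes a planted gestational-age slope", {
    base <- generateDataset(cleanConfig(18, nProbes = 1000))
    room <- which(base$truth$probes$baseline_beta > 0.3 &
                  base$truth$probes$baseline_beta < 0.7)[1:50]
    cfg <- cleanConfig(18, nProbes = 1000)
    cfg@gaProbes <- as.integer(room); cfg@gaSlope <- 0.3
    d <- generateDataset(cfg)
    sheet <- sampleSheet(d$mset)
    raw <- betaValues(d$mset)
    adj <- adjustedBeta(d$mset)
    corRaw <- apply(raw[room, ], 1, function(x) cor(x, sheet$ga_weeks))
    corAdj <- apply(adj[room, ], 1, function(x) cor(x, sheet$ga_weeks))
    expect_gt(mean(abs(corRaw)), 0.5)
    expect_lt(mean(abs(corAdj)), 0.15)
    # no covariates -> adjusted equals the (clipped) raw beta
    none <- adjustedBeta(d$mset, covariates = character(0))
    expect_equal(none, mToBeta(mValues(d$mset)), tolerance = 1e-12)
})

test_that("group means strip missing values exactly as a brute-force mean", {
    beta <- matrix(runif(40), 10, 4)
    beta[2, 1] <- NA; beta[5, 3:4] <- NA
    status <- c("CON", "CON", "SB", "SB")
    gd <- groupDeltaBeta(beta, status)
    expect_equal(unname(gd$means[2, "CON"]), beta[2, 2])
    expect_true(is.na(gd$means[5, "SB"]))
    expect_true(is.na(gd$delta[5, "SB"]))
    expect_equal(unname(gd$delta[1, "SB"]),
                 mean(beta[1, 3:4]) - mean(beta[1, 1:2]))
    # toy values
    gd2 <- groupDeltaBeta(matrix(c(0.2, 0.2, 0.3, 0.3), 1), status)
    expect_equal(unname(gd2$delta[1, "SB"]), 0.1)
})

test_that("dual-criterion calling requires both thresholds", {
    res <- data.frame(probe_id = c("a", "b", "c"), contrast = "SB",
                      coef = 1, t = 1, df = 10,
                      p = c(0.001, 0.001, 0.5),
                      q = c(0.04, 0.04, 0.9),
                      mean_ref = 0.2, mean_case = 0.3,
                      delta_beta = c(0.06, 0.03, 0.2), dm = NA)
    dm <- callDM(new("DMResult", results = res, params = list()))
    expect_equal(dmHits(dm), "a")
    # negative deltas count by default, not with twoSided = FALSE
    res$delta_beta <- c(-0.06, 0.03, 0.2)
    dm2 <- callDM(new("DMResult", results = res, params = list()))
    expect_equal(dmHits(dm2), "a")
    dm3 <- callDM(new("DMResult", results = res, params = list()),
                  twoSided = FALSE)
    expect_length(dmHits(dm3), 0)
})

test_that("status p values are uniform when only covariate effects exist", {
    cfg <- cleanConfig(19, nProbes = 3000)
    cfg@sexProbes <- 1:500; cfg@sexEffect <- 1
    d <- generateDataset(cfg)
    dm <- dmAnalysis(d$mset, moderated = FALSE)
    tb <- dmTable(dm); p <- tb$p[tb$contrast == "SB"]
    expect_lt(abs(mean(p < 0.05) - 0.05), 0.015)
    expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("candidate-subset analysis recomputes FDR within the subset", {
    d <- generateDataset(cleanConfig(20, nProbes = 500))
    full <- dmAnalysis(d$mset)
    sub <- candidateSubsetDM(d$mset, rownames(d$mset))
    expect_equal(dmTable(sub)$q, dmTable(full)$q)
    ids <- rownames(d$mset)[1:100]
    # plain OLS so per-probe p does not depend on the moderation set
    fullOls <- dmAnalysis(d$mset, moderated = FALSE)
    subset100 <- candidateSubsetDM(d$mset, ids, moderated = FALSE)
    tbF <- dmTable(fullOls); tbS <- dmTable(subset100)
    sb <- tbS$contrast == "SB"
    expect_equal(tbS$p[sb], tbF$p[tbF$contrast == "SB"][1:100])
    expect_equal(tbS$q[sb], bhFDR(tbS$p[sb]))
    expect_error(candidateSubsetDM(d$mset, character(0)), "empty")
})

test_that("the GA-matched subgroup analysis pools AN and CON into non-SB", {
    cfg <- cleanConfig(21, nProbes = 800,
                       nPerGroup = c(CON = 12, SB = 14, AN = 10))
    base <- generateDataset(cfg)
    room <- which(base$truth$probes$baseline_beta > 0.3 &
                  base$truth$probes$baseline_beta < 0.6)[1:60]
    d <- generateDataset(cleanConfig(21, nProbes = 800,
        nPerGroup = c(CON = 12, SB = 14, AN = 10),
        dmTruth = list(list(probes = room, contrast = "SB", delta = 0.2))))
    res <- matchedSubgroupDM(d$mset, gaWindow = c(0, 100))
    tb <- dmTable(res)
    expect_equal(unique(tb$contrast), "SB")
    expect_equal(res@params$reference, "nonSB")
    expect_equal(res@params$nSamples, ncol(d$mset))
    hits <- dmHits(res, "SB")
    expect_gt(mean(rownames(d$mset)[room] %in% hits), 0.8)
    # restricting the window drops samples
    win <- matchedSubgroupDM(d$mset, gaWindow = c(19, 24))
    expect_lt(win@params$nSamples, ncol(d$mset))
    expect_error(matchedSubgroupDM(d$mset, gaWindow = c(90, 99)), "window")
})

test_that("plot tables reflect the p-value distribution and probe count", {
    base <- generateDataset(cleanConfig(22, nProbes = 1000))
    room <- which(base$truth$probes$baseline_beta > 0.2 &
                  base$truth$probes$baseline_beta < 0.7)[1:100]
    d <- generateDataset(cleanConfig(22, nProbes = 1000,
        dmTruth = list(list(probes = room, contrast = "SB", delta = 0.2))))
    dm <- dmAnalysis(d$mset)
    h <- pvalueHistogramTable(dm)
    hSB <- h[h$contrast == "SB", ]
    expect_gt(hSB$count[1], max(hSB$count[-1]))   # left-peaking
    expect_equal(sum(hSB$count), 1000)
    v <- volcanoTable(dm)
    expect_equal(nrow(v), 1000)                   # one contrast (SB)
    expect_true(all(c("delta_beta", "neg_log10_q") %in% colnames(v)))
    # null data: near-uniform histogram
    d0 <- generateDataset(cleanConfig(23, nProbes = 1000))
    h0 <- pvalueHistogramTable(dmAnalysis(d0$mset, moderated = FALSE))
    h0SB <- h0[h0$contrast == "SB", ]
    expect_lt(max(h0SB$count), 2 * min(h0SB$count) + 20)
})
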