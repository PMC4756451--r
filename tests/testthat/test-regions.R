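test_that("the gap rule segments the canonical four-probe toy", {
    ann <- toyAnnotation(4, position = c(100L, 200L, 450L, 900L))
    co <- stats::setNames(rep(1, 4), ann$probe_id)
    r <- findDMRs(co, ann, maxgap = 300, minProbes = 3, coefThresh = 0.5,
                  window = 1)
    expect_equal(nrow(r), 1)
    expect_equal(r$start, 100)
    expect_equal(r$end, 450)
    expect_equal(r$n_probes, 3)
    expect_equal(r$probes, "p001,p002,p003")
    # all-zero coefficients: no regions
    r0 <- findDMRs(stats::setNames(rep(0, 4), ann$probe_id), ann,
                   coefThresh = 0.5, window = 1)
    expect_equal(nrow(r0), 0)
})

test_that("segmentation is invariant to input order and positive scaling", {
    set.seed(13)
    ann <- toyAnnotation(60, position = sort(sample(1e5, 60)))
    co <- stats::setNames(rnorm(60), ann$probe_id)
    r1 <- findDMRs(co, ann, coefThresh = 0.4)
    shuffle <- sample(60)
    r2 <- findDMRs(co[shuffle], ann[shuffle, ], coefThresh = 0.4)
    expect_equal(r1, r2, ignore_attr = TRUE)
    r3 <- findDMRs(co * 7, ann, coefThresh = 0.4 * 7)
    expect_equal(r3$probes, r1$probes)
    expect_equal(r3$area, r1$area * 7)
    # members share sign and respect the gap bound
    for (i in seq_len(nrow(r1))) {
        ids <- strsplit(r1$probes[i], ",")[[1]]
        pos <- ann$position[match(ids, ann$probe_id)]
        expect_true(all(diff(sort(pos)) <= 300))
    }
})

test_that("a planted block is recovered with correct boundaries and low q", {
    set.seed(14)
    n <- 400
    pos <- cumsum(c(1000, sample(c(50, 100, 150, 5000), n - 1, replace = TRUE,
                                 prob = c(.3, .3, .2, .2))))
    ann <- toyAnnotation(n, position = as.integer(pos))
    # choose 5 adjacent probes with small gaps
    gaps <- diff(pos)
    start <- which(vapply(seq_len(n - 4), function(i)
        all(gaps[i:(i + 3)] <= 300), TRUE))[1]
    block <- start:(start + 4)
    nS <- 24
    status <- rep(c("CON", "SB"), each = nS / 2)
    M <- matrix(rnorm(n * nS, 0, 0.4), n, nS)
    M[block, status == "SB"] <- M[block, status == "SB"] + 1.2
    ms <- MethylationSet(mToBeta(M), toySheet(status), ann)
    fit <- fitProbeModels(ms, covariates = character(0), moderated = FALSE)
    co <- stats::setNames(dmTable(fit)$coef, dmTable(fit)$probe_id)
    r <- findDMRs(co, ann, coefThresh = 0.5)
    hit <- r[r$n_probes >= 3 & r$start <= pos[block[1]] &
             r$end >= pos[block[5]], ]
    expect_equal(nrow(hit), 1)
    expect_true(all(ann$probe_id[block] %in%
                    strsplit(hit$probes, ",")[[1]]))
    rq <- dmrQvalues(r, ms, covariates = character(0), nIter = 200,
                     seed = 4)
    expect_lt(rq$q[which(rq$area == hit$area)], 0.05)
    expect_error(dmrQvalues(r, ms, nIter = 0), "positive")
})

test_that("null data produce no excess of small region q values", {
    set.seed(15)
    n <- 300
    ann <- toyAnnotation(n, position = as.integer(cumsum(
        c(500, sample(c(100, 200, 2000), n - 1, replace = TRUE)))))
    status <- rep(c("CON", "SB"), each = 10)
    ms <- MethylationSet(mToBeta(matrix(rnorm(n * 20, 0, 0.4), n, 20)),
                         toySheet(status), ann)
    fit <- fitProbeModels(ms, covariates = character(0), moderated = FALSE)
    co <- stats::setNames(dmTable(fit)$coef, dmTable(fit)$probe_id)
    r <- findDMRs(co, ann)
    if (nrow(r)) {
        rq <- dmrQvalues(r, ms, covariates = character(0), nIter = 100,
                         seed = 5)
        expect_gt(min(rq$perm_p), 1 / 101 - 1e-12)
        expect_gt(median(rq$perm_p), 0.1)
    }
    succeed()
})

test_that("BED export converts to 0-based half-open coordinates", {
    ann <- toyAnnotation(4, position = c(100L, 200L, 450L, 900L))
    r <- findDMRs(stats::setNames(rep(1, 4), ann$probe_id), ann,
                  coefThresh = 0.5, window = 1)
    f <- tempfile(fileext = ".bed")
    writeRegionsBED(r, f)
    bed <- utils::read.table(f, sep = "\t")
    expect_equal(bed$V2, 99)
    expect_equal(bed$V3, 450)
})

test_that("gene score resampling ranks a top-gene set at the resolution floor", {
    set.seed(16)
    genes <- sprintf("G%03d", 1:100)
    probes <- sprintf("p%03d", 1:300)
    probeGenes <- stats::setNames(rep(genes, each = 3), probes)
    p <- stats::setNames(runif(300, 0.2, 1), probes)
    top <- genes[1:12]
    p[probeGenes %in% top] <- runif(36, 1e-8, 1e-6)
    sets <- list(hot = top, cold = genes[51:70],
                 tiny = genes[1:3], huge = genes)
    gsr <- geneScoreResampling(p, probeGenes, sets, minSize = 10,
                               maxSize = 50, nIter = 500, seed = 2)
    expect_equal(gsr$p[gsr$set == "hot"], 1 / 501)
    expect_gt(gsr$p[gsr$set == "cold"], 0.05)
    expect_false(any(c("tiny", "huge") %in% gsr$set))
    expect_match(attr(gsr, "skipped")[["tiny"]], "outside")
    # monotone: stronger observed statistic, smaller p
    ord <- order(gsr$observed, decreasing = TRUE)
    expect_equal(order(gsr$p[ord]), seq_along(ord))
})

test_that("over-representation matches the hand hypergeometric", {
    bg <- sprintf("G%02d", 1:20)
    sets <- list(inset = bg[1:10], other = bg[11:15])
    res <- ora(bg[1:5], sets, bg)
    expect_equal(res$p[res$set == "inset"],
                 choose(10, 5) / choose(20, 5), tolerance = 1e-9)
    expect_equal(res$overlap[res$set == "inset"], 5)
    # empty hit list: all p = 1
    res0 <- ora(character(0), sets, bg)
    expect_true(all(res0$p == 1))
    # hits identical to one set give it the smallest p
    res1 <- ora(bg[11:15], sets, bg)
    expect_equal(res1$set[which.min(res1$p)], "other")
})

test_that("feature enrichment reproduces the one-sided hypergeometric toy", {
    ann <- toyAnnotation(20)
    ann$enhancer[1:10] <- TRUE
    hits <- ann$probe_id[1:5]              # all enhancer
    fe <- featureEnrichment(hits, ann, ann$probe_id,
                            features = "enhancer", alternative = "greater")
    expect_equal(fe$p, choose(10, 5) / choose(20, 5), tolerance = 1e-9)
    expect_equal(fe$direction, "enriched")
    # feature absent from annotation
    annNone <- ann; annNone$enhancer <- FALSE
    expect_error(featureEnrichment(hits, annNone, ann$probe_id,
                                   features = "enhancer"), "absent")
    expect_error(featureEnrichment(hits, ann, ann$probe_id,
                                   features = "promoter"), "unknown feature")
    # island categories run against the island_relation column
    ann$island_relation[1:8] <- "high_density_island"
    fe2 <- featureEnrichment(ann$probe_id[9:14], ann, ann$probe_id,
                             features = c("high_density_island",
                                          "non_island"))
    expect_equal(fe2$direction[fe2$feature == "high_density_island"],
                 "depleted")
})
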