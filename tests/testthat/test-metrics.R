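test_that("array average is the missing-stripped column mean", {
    b <- matrix(0.5, 10, 3)
    expect_equal(unname(arrayAverage(b)), rep(0.5, 3))
    b[1, 2] <- NA; b[2, 2] <- 0.9
    expect_equal(unname(arrayAverage(b))[2],
                 mean(c(rep(0.5, 8), 0.9)))
    set.seed(1)
    r <- matrix(runif(60), 20, 3)
    expect_equal(unname(arrayAverage(r)), apply(r, 2, mean))
})

test_that("outlier-probe percentage matches the hand-computed toy", {
    vals <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 2.0)
    b <- matrix(vals, 1, 7)
    # raw MAD = 0.2, median 0.4: only |2.0 - 0.4| = 1.6 > 0.6
    pct <- outlierProbePct(b, "kidney", k = 3, constant = 1)
    expect_equal(unname(pct), c(rep(0, 6), 100), ignore_attr = TRUE)
    # same call with the consistency constant flags the same cell here
    pct2 <- outlierProbePct(b, "kidney", k = 3)
    expect_equal(unname(pct2), c(rep(0, 6), 100), ignore_attr = TRUE)
    # identical samples: zero everywhere
    expect_equal(unname(outlierProbePct(matrix(0.3, 5, 4), "kidney")),
                 rep(0, 4), ignore_attr = TRUE)
    # translation invariance per probe
    b2 <- rbind(b, b + 0.1)
    p2 <- outlierProbePct(b2, "kidney", constant = 1)
    expect_equal(unname(p2), c(rep(0, 6), 100), ignore_attr = TRUE)
})

test_that("a spiked sample's outlier percentage rises by the planted fraction", {
    set.seed(7)
    b <- matrix(rnorm(500 * 12, 0.5, 0.01), 500, 12)
    b[1:50, 1] <- b[1:50, 1] + 0.3          # 10% of probes spiked
    pct <- outlierProbePct(b, "kidney")
    expect_gt(pct[1], mean(pct[-1]) + 8)
    expect_lt(abs(pct[1] - 10), 3)
    # small tissue: warning and missing metric
    expect_warning(p3 <- outlierProbePct(b[, 1:2], "kidney"), "fewer than 3")
    expect_true(all(is.na(p3)))
})

test_that("permutation Mann-Whitney matches exhaustive enumeration", {
    expect_equal(permMannWhitney(c(1, 2), c(3, 4), exact = TRUE)$p, 1/3)
    expect_equal(permMannWhitney(c(1, 2, 3), c(1, 2, 3), exact = TRUE)$p, 1)
    set.seed(5)
    for (i in 1:5) {
        x <- rnorm(4); y <- rnorm(4) + i / 4
        ex <- permMannWhitney(x, y, exact = TRUE)$p
        expect_equal(ex, exactMWOracle(x, y), tolerance = 1e-12)
        pm <- permMannWhitney(x, y, nPerm = 4000, seed = 1)$p
        expect_lt(abs(pm - ex), 0.03)
    }
    expect_error(permMannWhitney(numeric(0), 1:3), "both groups")
})

test_that("permutation test holds its nominal size under the null", {
    set.seed(12)
    rej <- mean(replicate(200, {
        permMannWhitney(rnorm(10), rnorm(10), nPerm = 199)$p <= 0.05
    }))
    expect_gt(rej, 0.01); expect_lt(rej, 0.09)
})

test_that("Fisher 2xk matches enumeration and the printed clinical table", {
    expect_equal(fisherExact2xk(matrix(c(0, 5, 5, 0), 2)), 2/252,
                 tolerance = 1e-9)
    expect_equal(fisherExact2xk(matrix(c(5, 5, 5, 5), 2)), 1)
    # CON 7M/12F vs SB 16M/6F
    expect_equal(round(fisherExact2xk(matrix(c(7, 12, 16, 6), 2,
                                             byrow = TRUE)), 2), 0.03)
    # 2x3 table vs brute-force enumeration over tables with fixed margins
    tab <- matrix(c(5, 2, 1, 2, 4, 5), 2, byrow = TRUE)
    enumP <- local({
        rs <- rowSums(tab); cs <- colSums(tab)
        prob <- function(m) exp(sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) -
                                lgamma(sum(rs) + 1) - sum(lgamma(m + 1)))
        pObs <- prob(tab); tot <- 0
        for (a in 0:min(rs[1], cs[1])) for (b in 0:min(rs[1] - a, cs[2])) {
            cc <- rs[1] - a - b
            if (cc < 0 || cc > cs[3]) next
            m <- rbind(c(a, b, cc), cs - c(a, b, cc))
            if (any(m < 0)) next
            if (prob(m) <= pObs + 1e-10) tot <- tot + prob(m)
        }
        tot
    })
    expect_equal(fisherExact2xk(tab), enumP, tolerance = 1e-7)
})

test_that("the clinical summary reproduces group tests", {
    sheet <- rbind(toySheet(rep("CON", 19), sex = c(rep("M", 7), rep("F", 12)),
                            ga = rnorm(19, 19, 1)),
                   toySheet(rep("SB", 22), sex = c(rep("M", 16), rep("F", 6)),
                            ga = rnorm(22, 22, 1)))
    sheet$sample_id <- sprintf("S%03d", seq_len(nrow(sheet)))
    cs <- groupClinicalStats(sheet)
    expect_equal(round(cs$p["sex", "SB_vs_CON"], 2), 0.03)
    expect_lt(cs$p["ga_weeks", "SB_vs_CON"], 0.01)
    # identical groups: p = 1
    s2 <- sheet; s2$status <- rep(c("CON", "SB"), length.out = nrow(s2))
    s2$sex <- "M"; s2$ga_weeks <- 20
    cs2 <- groupClinicalStats(s2)
    expect_equal(unname(cs2$p["sex", ]), 1)
})

test_that("repetitive-element summaries average CpGs and apply the QC rule", {
    pyro <- data.frame(L1 = c(80, 80), L2 = c(80, 95), L3 = c(80, 70),
                       L4 = c(80, 75))
    rs <- repetitiveSummary(pyro, list(LINE1 = c("L1", "L2", "L3", "L4")),
                            status = c("CON", "SB"), nPerm = 50, seed = 1)
    expect_equal(rs$perSample$LINE1[1], 80)
    expect_false(rs$perSample$repeat_flagged[1])
    expect_true(rs$perSample$repeat_flagged[2])   # SD > 10 across CpGs
    # group medians match brute force
    set.seed(2)
    pyro2 <- as.data.frame(matrix(runif(30 * 3, 70, 90), 30, 3))
    status <- rep(c("CON", "SB", "AN"), each = 10)
    rs2 <- repetitiveSummary(pyro2, list(Alu = names(pyro2)), status,
                             nPerm = 100, seed = 3)
    g <- rs2$groups
    expect_equal(g$median[g$group == "SB"],
                 median(rowMeans(pyro2)[status == "SB"]))
    # peak-height rule
    rs3 <- repetitiveSummary(pyro, list(LINE1 = c("L1", "L2")),
                             status = c("CON", "SB"),
                             peakHeight = c(80, 60), nPerm = 10)
    expect_true(rs3$perSample$repeat_flagged[2])
})

test_that("sample clustering is deterministic with sane dendrogram structure", {
    set.seed(9)
    b <- cbind(matrix(runif(200, 0, 0.3), 100, 2),
               matrix(runif(200, 0.7, 1), 100, 2))
    b <- cbind(b, b[, 4])     # duplicate of sample 4
    colnames(b) <- paste0("S", 1:5)
    hc <- hclustSamples(b, k = 2)
    expect_equal(unname(hc$clusters), c(1, 1, 2, 2, 2))
    # duplicates merge first at height zero
    expect_equal(hc$hclust$height[1], 0)
    expect_true(all(diff(hc$hclust$height) >= -1e-12))
    expect_match(hc$newick, "^\\(")
})

test_that("platform correlation and Bonferroni behave on exact relations", {
    b <- seq(0.1, 0.9, length.out = 9)
    expect_equal(platformCorrelation(100 * b, b)$r, 1)
    expect_equal(platformCorrelation(rev(100 * b), b)$r, -1)
    expect_equal(bonferroni(0.01, m = 5), 0.05)
    expect_equal(bonferroni(c(0.4, 0.01), m = 5), c(1, 0.05))
})
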