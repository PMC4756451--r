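test_that("a single batch level leaves the matrix unchanged", {
    M <- matrix(rnorm(100), 20, 5)
    out <- ebBatchAdjust(M, rep("A", 5))
    expect_equal(out$adjusted, M)
})

test_that("a noise-free constant batch shift is removed exactly", {
    base <- seq(-3, 3, length.out = 40)
    M <- matrix(rep(base, 8), 40, 8)
    batch <- rep(c("A", "B"), each = 4)
    M[, batch == "B"] <- M[, batch == "B"] + 1.5
    adj <- ebBatchAdjust(M, batch)$adjusted
    gap <- rowMeans(adj[, 1:4]) - rowMeans(adj[, 5:8])
    expect_lt(max(abs(gap)), 1e-6)
})

test_that("adjustment matches the sva ComBat oracle on complete data", {
    skip_if_not_installed("sva")
    set.seed(21)
    M <- matrix(rnorm(300 * 12), 300, 12)
    batch <- rep(c("A", "B", "C"), each = 4)
    M <- M + rep(c(0, 1, -0.5), each = 4)[col(M)] * rnorm(300)[row(M)] * 0.1 +
        rep(c(0, 0.8, -0.8), each = 4)[col(M)]
    ref <- suppressMessages(sva::ComBat(M, batch = batch))
    mine <- ebBatchAdjust(M, batch)$adjusted
    expect_lt(max(abs(mine - ref)), 1e-4)
})

test_that("a planted treatment effect orthogonal to batch is preserved", {
    set.seed(3)
    n <- 16
    group <- rep(c(0, 1), 8)                    # orthogonal to batch
    batch <- rep(c("A", "B"), each = 8)
    M <- matrix(rnorm(200 * n, sd = 0.3), 200, n)
    M[1:50, group == 1] <- M[1:50, group == 1] + 1
    M[, batch == "B"] <- M[, batch == "B"] + 2
    mod <- cbind(group = group)
    adj <- ebBatchAdjust(M, batch, mod = mod)$adjusted
    effBefore <- rowMeans(M[1:50, group == 1]) - rowMeans(M[1:50, group == 0])
    effAfter <- rowMeans(adj[1:50, group == 1]) -
        rowMeans(adj[1:50, group == 0])
    expect_lt(max(abs(effAfter - effBefore)), 0.1)
    # batch gap removed
    expect_lt(max(abs(rowMeans(adj[, batch == "A"]) -
                      rowMeans(adj[, batch == "B"]))), 0.5)
})

test_that("missing cells are excluded from estimates and stay missing", {
    set.seed(4)
    M <- matrix(rnorm(100 * 10), 100, 10)
    batch <- rep(c("A", "B"), each = 5)
    M[1, 2] <- NA; M[50, 8] <- NA
    adj <- ebBatchAdjust(M, batch)$adjusted
    expect_true(is.na(adj[1, 2]) && is.na(adj[50, 8]))
    expect_equal(sum(is.na(adj)), 2)
    # under-represented probe-batch cells error with guidance
    M[2, 1:4] <- NA
    expect_error(ebBatchAdjust(M, batch), "dropUnderrepresented")
})

test_that("adjustment is idempotent in distribution", {
    set.seed(6)
    M <- matrix(rnorm(300 * 10), 300, 10)
    batch <- rep(c("A", "B"), each = 5)
    M[, batch == "B"] <- M[, batch == "B"] + 1
    once <- ebBatchAdjust(M, batch)
    twice <- ebBatchAdjust(once$adjusted, batch)
    # across-probe average batch shift estimated on re-run is ~ zero
    expect_lt(max(abs(colMeans(twice$model$gamma.hat))), 0.05)
    expect_lt(max(abs(colMeans(once$adjusted[, batch == "A"]) -
                      colMeans(twice$adjusted[, batch == "A"]))), 0.05)
})

test_that("sequential correction removes all three planted shifts in order", {
    d <- generateDataset(SimulationConfig(nProbes = 1500, seed = 31,
        batchShiftM = c(plate = 1.5, row = 0.8, chip = 0.8),
        pctChrX = 0, pctChrY = 0, nRsProbes = 0,
        failureRates = c(detection = 0, beads = 0), nReplicatePairs = 0))
    adj <- sequentialAdjust(d$mset)
    expect_equal(metadata(adj)$batchReport$order, c("plate", "row", "chip"))
    sheet <- sampleSheet(adj)
    Madj <- mValues(adj)
    Mraw <- mValues(d$mset)
    for (v in c("plate", "row", "chip")) {
        gm <- vapply(split(seq_len(ncol(Madj)), sheet[[v]]),
                     function(ix) mean(Madj[, ix]), 0)
        gmRaw <- vapply(split(seq_len(ncol(Mraw)), sheet[[v]]),
                        function(ix) mean(Mraw[, ix]), 0)
        expect_lt(max(gm) - min(gm), 0.15)
        expect_lt(max(gm) - min(gm), 0.2 * (max(gmRaw) - min(gmRaw)))
    }
    # order matters: permuting the order changes the output
    adj2 <- sequentialAdjust(d$mset, variables = c("chip", "row", "plate"))
    expect_false(isTRUE(all.equal(mValues(adj2), Madj)))
    # a single variable equals one direct call
    one <- sequentialAdjust(d$mset, variables = "plate")
    sheet0 <- sampleSheet(d$mset)
    df <- sheet0[, c("status", "sex", "ga_weeks")]
    df$status <- factor(df$status); df$sex <- factor(df$sex)
    mod <- stats::model.matrix(~ ., df)[, -1]
    direct <- ebBatchAdjust(mValues(d$mset), sheet0$plate, mod = mod)$adjusted
    expect_equal(betaValues(one), mToBeta(direct), tolerance = 1e-10)
})

test_that("under-represented probes are found exactly", {
    d <- generateDataset(cleanConfig(7, nProbes = 200))
    ms <- d$mset
    b <- betaValues(ms)
    sheet <- sampleSheet(ms)
    # plant a probe observed once on plate P1
    p1 <- sheet$plate == sheet$plate[1]
    b[5, which(p1)[-1]] <- NA
    betaValues(ms) <- b
    out <- dropUnderrepresented(ms, variables = "plate")
    expect_equal(out$nRemoved, 1)
    expect_equal(out$removed, rownames(ms)[5])
    # full design: nothing removed
    expect_equal(dropUnderrepresented(d$mset)$nRemoved, 0)
    # brute-force scan agrees
    brute <- sum(vapply(seq_len(nrow(b)), function(i)
        any(vapply(split(b[i, ], sheet$plate),
                   function(x) sum(!is.na(x)) < 2, TRUE)), TRUE))
    expect_equal(out$nRemoved, brute)
})

test_that("PC association finds a planted plate shift and its removal", {
    d <- generateDataset(SimulationConfig(nProbes = 1000, seed = 32,
        batchShiftM = c(plate = 2, row = 0, chip = 0),
        pctChrX = 0, pctChrY = 0, nRsProbes = 0,
        failureRates = c(detection = 0, beads = 0), nReplicatePairs = 0))
    pa <- pcAssociation(d$mset, k = 5)
    expect_lt(pa$p["PC1", "plate"], 1e-8)
    adj <- sequentialAdjust(d$mset, variables = "plate")
    pa2 <- pcAssociation(adj, k = 5)
    expect_gt(pa2$p["PC1", "plate"], 1e-4)
    expect_gt(pa2$p["PC1", "plate"], pa$p["PC1", "plate"])
})

test_that("adjustment with protected covariates matches the sva oracle", {
    skip_if_not_installed("sva")
    set.seed(9)
    M <- matrix(rnorm(400 * 20), 400, 20)
    batch <- rep(c("A", "B"), each = 10)
    grp <- rep(c(0, 1), 10)
    M[, batch == "B"] <- M[, batch == "B"] + 1
    M[1:50, grp == 1] <- M[1:50, grp == 1] + 0.8
    modS <- stats::model.matrix(~ factor(grp))
    ref <- suppressMessages(sva::ComBat(M, batch = batch, mod = modS))
    mine <- ebBatchAdjust(M, batch, mod = modS[, -1, drop = FALSE])$adjusted
    expect_lt(max(abs(mine - ref)), 1e-4)
})
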