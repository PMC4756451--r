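# Shared fixtures: all built in code, no stored data.

# A small clean two-group configuration: no batch shifts, no
# sex-chromosome or rs probes, no failures -- the exact-null condition
# under which OLS p values are exactly t-distributed.
cleanConfig <- function(seed, nProbes = 2000,
                        nPerGroup = c(CON = 20, SB = 20, AN = 0),
                        dmTruth = list(), ...) {
    SimulationConfig(nProbes = nProbes, nPerGroup = nPerGroup,
                     dmTruth = dmTruth,
                     batchShiftM = c(plate = 0, row = 0, chip = 0),
                     pctChrX = 0, pctChrY = 0, nRsProbes = 0,
                     failureRates = c(detection = 0, beads = 0),
                     nReplicatePairs = 0, seed = seed, ...)
}

# Minimal annotation for hand-built matrices.
toyAnnotation <- function(n, chrom = "chr1",
                          position = seq(100L, by = 100L, length.out = n),
                          probe_class = "cg", polymorphic = FALSE,
                          cross_hybridizing = FALSE, enhancer = FALSE,
                          island = "non_island", gene = "") {
    data.frame(probe_id = sprintf("p%03d", seq_len(n)), chrom = chrom,
               position = position, gene_field = gene,
               closest_tss_gene = gene, island_relation = island,
               enhancer = enhancer, polymorphic = polymorphic,
               cross_hybridizing = cross_hybridizing,
               probe_class = probe_class, stringsAsFactors = FALSE)
}

# Minimal sample sheet for hand-built matrices.
toySheet <- function(status, sex = rep(c("M", "F"), length.out = length(status)),
                     ga = seq(15, 23, length.out = length(status)),
                     tissue = "kidney", plate = "P1", chip = "C1",
                     row = "R1", individual = NULL) {
    n <- length(status)
    data.frame(sample_id = sprintf("S%03d", seq_len(n)),
               individual_id = if (is.null(individual))
                   sprintf("I%03d", seq_len(n)) else individual,
               tissue = tissue, status = status, sex = sex, ga_weeks = ga,
               plate = rep_len(plate, n), chip = rep_len(chip, n),
               row = rep_len(row, n), stringsAsFactors = FALSE)
}

toyMset <- function(beta, status, annotation = NULL, sheet = NULL, ...) {
    if (is.null(annotation)) annotation <- toyAnnotation(nrow(beta))
    if (is.null(sheet)) sheet <- toySheet(status, ...)
    MethylationSet(beta, sheet, annotation)
}

# Independent brute-force BH step-up (the oracle bhFDR is tested
# against): sort, apply p * n / rank, enforce monotonicity from the
# largest rank down, restore order.
bruteBH <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    if (n > 1) for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
    q <- pmin(q, 1)
    out <- numeric(n)
    out[o] <- q
    out
}

# Exhaustive two-sided Mann-Whitney p by label enumeration (oracle).
exactMWOracle <- function(x, y) {
    pool <- c(x, y); n1 <- length(x)
    mu <- n1 * length(y) / 2
    U <- function(a, b) sum(rank(c(a, b))[seq_along(a)]) -
        length(a) * (length(a) + 1) / 2
    obs <- abs(U(x, y) - mu)
    splits <- utils::combn(length(pool), n1)
    mean(apply(splits, 2, function(ix)
        abs(U(pool[ix], pool[-ix]) - mu)) >= obs - 1e-12)
}
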