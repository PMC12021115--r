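test_that("graph frequencies follow the Balding-Nichols drift model", {
    # zero drift: every population identical to the ancestral draw
    g0 <- admixtureGraph(nodes = c("anc", "a", "b"),
                         edges = data.frame(parent = "anc",
                                            child = c("a", "b"), f = 0),
                         nSites = 500, seed = 11)
    f0 <- simulateGraphFrequencies(g0)
    expect_identical(f0[, "a"], f0[, "anc"])
    expect_identical(f0[, "b"], f0[, "anc"])

    # two-population split, F = 0.1: E[(pA - pB)^2] = 2 F E[p(1-p)]
    # = 2 * 0.1 * 0.1825 = 0.0365 for ancestral U(0.05, 0.95)
    g <- admixtureGraph(nodes = c("anc", "a", "b"),
                        edges = data.frame(parent = "anc",
                                           child = c("a", "b"), f = 0.1),
                        nSites = 50000, seed = 12)
    f <- simulateGraphFrequencies(g)
    d2 <- (f[, "a"] - f[, "b"])^2
    mcSe <- sd(d2) / sqrt(length(d2))
    expect_lt(abs(mean(d2) - 0.0365), 3 * mcSe + 1e-4)

    # martingale: child mean tracks parent mean
    expect_lt(abs(mean(f[, "a"]) - mean(f[, "anc"])),
              3 * sd(f[, "a"] - f[, "anc"]) / sqrt(nrow(f)))

    # admixture with alpha = 1 copies parent A exactly
    ga <- admixtureGraph(
        nodes = c("anc", "a", "b", "c"),
        edges = data.frame(parent = "anc", child = c("a", "b"),
                           f = c(0.2, 0.05)),
        admixtures = data.frame(child = "c", parentA = "a",
                                parentB = "b", alpha = 1),
        nSites = 300, seed = 13)
    fa <- simulateGraphFrequencies(ga)
    expect_identical(fa[, "c"], fa[, "a"])
})

test_that("invalid graph specifications are rejected", {
    expect_error(admixtureGraph(
        nodes = c("anc", "a"),
        edges = data.frame(parent = "anc", child = "a", f = 1.0),
        nSites = 10, seed = 1), "F < 1")
    expect_error(admixtureGraph(
        nodes = c("a", "b"),
        edges = data.frame(parent = c("a", "b"), child = c("b", "a"),
                           f = 0.1),
        nSites = 10, seed = 1), "root")
})

test_that("genotype draws are binomial in the population frequency", {
    freqs <- cbind(p1 = c(1, 0.5, 0), p2 = c(0.2, 0.5, 0.8))
    freqs <- freqs[rep(1:3, each = 2), ]
    gd <- simulateGenotypes(freqs, c(p1 = 4, p2 = 4), seed = 21,
                            chromLen = 1e5)
    d <- dosage(gd)
    expect_true(all(d[1:2, sampleMeta(gd)$breed == "p1"] == 2L))
    expect_true(all(d[5:6, sampleMeta(gd)$breed == "p1"] == 0L))
    # phased consistency is enforced by the class validity; check anyway
    expect_identical(hapA(gd) + hapB(gd), d)

    # sample frequency concentrates: p = 0.5, 10,000 haplotypes
    f5 <- matrix(0.5, 50, 1, dimnames = list(NULL, "q"))
    gbig <- simulateGenotypes(f5, c(q = 5000), seed = 22,
                              chromLen = 1e5)
    pHat <- altFreq(gbig)
    expect_true(all(abs(pHat - 0.5) < 3 * sqrt(0.25 / 10000)))
})

test_that("sweep implantation creates the expected diversity loss", {
    fx <- sweepScanFixture(seed = 31, carrierFreq = 1.0)
    pony <- sampleMeta(fx$gd)$breed == "pony"
    wp <- windowedPi(fx$gd, pony, fx$windows)
    inS <- IRanges::overlapsAny(fx$windows, fx$truth, type = "within")
    piIn <- S4Vectors::mcols(wp)$theta_pi[inS]
    # carrier frequency 1: the target population is monomorphic inside
    expect_true(all(piIn == 0))

    fx9 <- sweepScanFixture(seed = 31, carrierFreq = 0.9)
    wp9 <- windowedPi(fx9$gd, pony, fx9$windows)
    piIn9 <- mean(S4Vectors::mcols(wp9)$theta_pi[inS])
    piOut9 <- mean(S4Vectors::mcols(wp9)$theta_pi[!inS])
    expect_lt(piIn9, piOut9)

    # non-target population untouched byte for byte
    noSweep <- sweepScanFixture(seed = 31, carrierFreq = 0.9)$gd
    horse <- sampleMeta(fx9$gd)$breed == "horse"
    expect_identical(dosage(fx9$gd)[, horse], dosage(noSweep)[, horse])
})

test_that("depth simulation separates the sexes as designed", {
    # female with zero residual: no Y reads at all
    f0 <- simulateDepthTable(depthProfile("female", yResidual = 0,
                                          seed = 41))
    expect_identical(f0$total_reads[f0$chrom == "chrY"], 0L)
    expect_identical(f0$covered_bp[f0$chrom == "chrY"], 0L)

    # male at 10x: Y/Chr1 per-bp ratio near one half
    m <- simulateDepthTable(depthProfile("male", meanDepth = 10,
                                         seed = 42))
    rate <- m$total_reads / m$chrom_len
    names(rate) <- m$chrom
    expect_gt(rate[["chrY"]] / rate[["chr1"]], 0.4)
    expect_lt(rate[["chrY"]] / rate[["chr1"]], 0.6)

    # linearity: doubling mean depth doubles expected counts
    a <- simulateDepthTable(depthProfile("male", meanDepth = 5,
                                         overdispersion = 0, seed = 43))
    b <- simulateDepthTable(depthProfile("male", meanDepth = 10,
                                         overdispersion = 0, seed = 44))
    ratio <- b$total_reads / a$total_reads
    expect_true(all(abs(ratio - 2) < 0.05))
})

test_that("every simulator stage is bit-reproducible under its seed", {
    f1 <- simulateGraphFrequencies(admixtureGraph(
        nodes = c("anc", "a"), edges = data.frame(parent = "anc",
                                                  child = "a", f = 0.1),
        nSites = 200, seed = 5))
    f2 <- simulateGraphFrequencies(admixtureGraph(
        nodes = c("anc", "a"), edges = data.frame(parent = "anc",
                                                  child = "a", f = 0.1),
        nSites = 200, seed = 5))
    expect_identical(f1, f2)
    fxA <- sweepScanFixture(seed = 7, nSites = 300)
    fxB <- sweepScanFixture(seed = 7, nSites = 300)
    expect_identical(dosage(fxA$gd), dosage(fxB$gd))
    expect_identical(simulateDepthTable(depthProfile("male", seed = 9)),
                     simulateDepthTable(depthProfile("male", seed = 9)))
})

test_that("a YAML config drives the simulator end to end", {
    skip_if_not_installed("yaml")
    cfg <- tempfile(fileext = ".yaml")
    writeLines(c(
        "nodes: [anc, pony, horse]",
        "edges:",
        "  - {parent: anc, child: pony, f: 0.1}",
        "  - {parent: anc, child: horse, f: 0.1}",
        "n_sites: 100",
        "seed: 99",
        "chrom_len: 200000",
        "n_per_pop: {pony: 3, horse: 3}"), cfg)
    gd <- simulateFromConfig(cfg)
    expect_s4_class(gd, "GenotypeData")
    expect_equal(dim(gd), c(100L, 6L))
})
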