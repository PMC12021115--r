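test_that("per-site Weir-Cockerham components behave at the anchors", {
    # no differentiation: p = 0.5 both sides, observed het = expected
    g <- c(rep(0L, 5), rep(1L, 10), rep(2L, 5))
    # one site, two populations of 20 with identical genotype vectors
    d <- matrix(c(g, g), nrow = 1)
    colnames(d) <- sprintf("s%02d", 1:40)
    gd <- toyGenotypes(d)
    r <- siteFst(gd, 1:20, 21:40)
    # the estimator corrects for sampling variance, so identical
    # samples land near, not exactly at, zero
    expect_lt(abs(r$a), 0.01)
    expect_lt(abs(r$fst), 0.05)

    # fixed difference: FST = 1
    d2 <- matrix(c(rep(2L, 20), rep(0L, 20)), nrow = 1)
    colnames(d2) <- colnames(d)
    r2 <- siteFst(toyGenotypes(d2), 1:20, 21:40)
    expect_lt(abs(r2$fst - 1), 1e-9)

    # label-swap symmetry
    set.seed(201)
    d3 <- matrix(rbinom(5 * 40, 2, runif(5, 0.2, 0.8)), 5, 40)
    colnames(d3) <- colnames(d)
    gd3 <- toyGenotypes(d3)
    expect_equal(siteFst(gd3, 1:20, 21:40)$fst,
                 siteFst(gd3, 21:40, 1:20)$fst)

    # scalar oracle transcription agrees site by site
    o <- t(vapply(1:5, function(i)
        oracleWcSite(d3[i, 1:20], d3[i, 21:40]), numeric(2)))
    r3 <- siteFst(gd3, 1:20, 21:40)
    expect_equal(r3$a, o[, "a"], tolerance = 1e-12)
    expect_equal(r3$d, o[, "d"], tolerance = 1e-12)
})

test_that("window FST uses ratio-of-sums weighting", {
    set.seed(202)
    d <- matrix(rbinom(3 * 30, 2, c(0.2, 0.5, 0.9)), 3, 30)
    colnames(d) <- sprintf("s%02d", 1:30)
    gd <- toyGenotypes(d, pos = c(100, 200, 300))
    win <- tileWindows(c(chr1 = 1000), size = 1000)
    comp <- siteFst(gd, 1:15, 16:30)
    wf <- windowedFst(gd, 1:15, 16:30, win)
    expect_equal(S4Vectors::mcols(wf)$fst,
                 sum(comp$a) / sum(comp$d))
    # ratio-of-sums differs from mean-of-ratios on this 3-site toy
    wm <- windowedFst(gd, 1:15, 16:30, win,
                      weighting = "mean_of_ratios")
    expect_equal(S4Vectors::mcols(wm)$fst,
                 mean(comp$fst, na.rm = TRUE))

    # single-SNP window equals the per-site value
    g1 <- toyGenotypes(d[1, , drop = FALSE], pos = 50)
    w1 <- windowedFst(g1, 1:15, 16:30, tileWindows(c(chr1 = 100), 100))
    expect_equal(S4Vectors::mcols(w1)$fst,
                 comp$a[1] / comp$d[1])
})

test_that("theta-pi equals the pairwise-difference oracle", {
    # one SNP, 4 chromosomes split 2/2: pi_site = 4/6, 10-kb window
    ha <- matrix(c(1L, 0L), 1, 2)
    hb <- matrix(c(1L, 0L), 1, 2)
    d <- ha + hb
    colnames(d) <- c("s1", "s2")
    gd <- makeGenotypeData(d,
        GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, width = 1)),
        data.frame(sample = c("s1", "s2")), hapA = ha, hapB = hb)
    w <- tileWindows(c(chr1 = 10000))
    wp <- windowedPi(gd, 1:2, w)
    expect_equal(S4Vectors::mcols(wp)$theta_pi, (4 / 6) / 10000)

    # monomorphic window is 0
    d0 <- matrix(2L, 3, 4, dimnames = list(NULL, paste0("s", 1:4)))
    w0 <- windowedPi(toyGenotypes(d0), 1:4, tileWindows(c(chr1 = 1000)))
    expect_equal(S4Vectors::mcols(w0)$theta_pi, 0)

    # brute-force oracle on 20 random phased windows
    set.seed(203)
    for (rep in 1:20) {
        nS <- sample(3:12, 1); nInd <- sample(2:6, 1)
        ha <- matrix(rbinom(nS * nInd, 1, 0.5), nS, nInd)
        hb <- matrix(rbinom(nS * nInd, 1, 0.5), nS, nInd)
        d <- ha + hb
        colnames(d) <- sprintf("s%d", 1:nInd)
        pos <- sort(sample(1:900, nS))
        gd <- makeGenotypeData(d,
            GenomicRanges::GRanges("chr1",
                IRanges::IRanges(pos, width = 1)),
            data.frame(sample = colnames(d)), hapA = ha, hapB = hb)
        wp <- windowedPi(gd, seq_len(nInd),
                         tileWindows(c(chr1 = 1000), 1000))
        haps <- t(cbind(ha, hb))  # chromosomes x sites
        hapsInterleaved <- rbind(t(ha), t(hb))
        expect_equal(S4Vectors::mcols(wp)$theta_pi,
                     oraclePi(hapsInterleaved, 1000))
    }
})

test_that("the diversity ratio flags swept windows by its limits", {
    set.seed(204)
    d <- matrix(rbinom(20 * 40, 2, 0.5), 20, 40)
    colnames(d) <- sprintf("s%02d", 1:40)
    gd <- toyGenotypes(d, pos = seq(50, 999, length.out = 20))
    w <- tileWindows(c(chr1 = 1000), 1000)
    pr <- piRatio(gd, 1:20, 21:40, w)
    wq <- windowedPi(gd, 1:20, w)
    wr <- windowedPi(gd, 21:40, w)
    expect_equal(S4Vectors::mcols(pr)$pi_ratio,
                 S4Vectors::mcols(wq)$theta_pi /
                     S4Vectors::mcols(wr)$theta_pi)
    # identical groups: ratio exactly 1
    pr1 <- piRatio(gd, 1:20, 1:20, w)
    expect_equal(S4Vectors::mcols(pr1)$pi_ratio, 1)
    # query monomorphic, ref diverse: ratio 0
    d2 <- d; d2[, 1:20] <- 0L
    pr0 <- piRatio(toyGenotypes(d2,
                                pos = seq(50, 999, length.out = 20)),
                   1:20, 21:40, w)
    expect_equal(S4Vectors::mcols(pr0)$pi_ratio, 0)
})

test_that("LD decay reports mean r2 by distance bin", {
    set.seed(205)
    base <- rbinom(20, 2, 0.5)
    d <- rbind(base, base, matrix(rbinom(20 * 4, 2, 0.5), 4, 20))
    rownames(d) <- NULL
    colnames(d) <- sprintf("s%02d", 1:20)
    gd <- toyGenotypes(d, pos = c(100, 150, 5000, 10000, 20000, 40000))
    dec <- ldDecay(gd, 1:20, maxDist = 10000, binWidth = 1000)
    expect_equal(dec$mean_r2[dec$bin_start == 0][1], 1) # duplicated pair
    expect_true(all(dec$bin_end <= 10000))
    expect_error(ldDecay(gd, 1:5), "fewer than")

    # no-LD baseline: E[r2] ~ 1/n for independent sites
    set.seed(206)
    n <- 50
    dI <- matrix(rbinom(40 * n, 2, 0.5), 40, n)
    colnames(dI) <- sprintf("s%02d", 1:n)
    gI <- toyGenotypes(dI, pos = seq(100, 39000, length.out = 40))
    decI <- ldDecay(gI, 1:n, maxDist = 40000, binWidth = 40000)
    r2s <- decI$mean_r2[1]
    # mean over ~780 pairs; binomial-ish spread well under 0.01
    expect_lt(abs(r2s - 1 / n), 0.01)
})

test_that("ROH scanning recovers constructed homozygous tracts", {
    # 80-SNP homozygous tract spanning ~592 kb, dense het flanks
    tractPos <- 1e6 + (0:79) * 7500
    leftPos <- seq(1e6 - 100000, 1e6 - 500, length.out = 100)
    rightPos <- seq(max(tractPos) + 500, max(tractPos) + 100000,
                    length.out = 100)
    pos <- c(leftPos, tractPos, rightPos)
    g <- c(rep(1L, 100), rep(2L, 80), rep(1L, 100))
    d <- matrix(g, ncol = 1, dimnames = list(NULL, "s1"))
    gd <- toyGenotypes(d, pos = round(pos))
    segs <- rohDetect(gd)
    expect_equal(nrow(segs), 1L)
    # boundaries fall inside the tract (the scanning rule trims at most
    # a SNP or two at the edges) and exclude every heterozygous flank SNP
    expect_gte(segs$start, min(tractPos))
    expect_lte(segs$end, max(tractPos))
    expect_gte(segs$n_snps, 76)
    expect_gte(segs$length_kb, 500)

    # a 150-kb internal gap splits the run; neither half reaches 500 kb
    tract2 <- c(tractPos[1:40], tractPos[41:80] + 150000)
    pos2 <- c(leftPos, tract2, rightPos + 160000)
    gd2 <- toyGenotypes(d, pos = round(pos2))
    segs2 <- rohDetect(gd2)
    expect_equal(nrow(segs2), 0L)

    # a fully heterozygous sample yields nothing
    dHet <- matrix(1L, 280, 1, dimnames = list(NULL, "s1"))
    expect_equal(nrow(rohDetect(toyGenotypes(dHet, pos = round(pos)))),
                 0L)

    # emitted segments re-satisfy all four thresholds
    expect_true(all(segs$length_kb >= 500 & segs$n_snps >= 50 &
                    segs$length_kb / segs$n_snps <= 50))

    # sample-order invariance
    d2 <- cbind(d, s2 = rep(c(1L, 2L), 140))
    gdA <- toyGenotypes(d2, pos = round(pos))
    gdB <- toyGenotypes(d2[, 2:1], pos = round(pos))
    sa <- rohDetect(gdA); sb <- rohDetect(gdB)
    expect_equal(sa[order(sa$sample), -1],
                 sb[order(sb$sample), -1], ignore_attr = TRUE)
})
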