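# Independent brute-force oracles used to pin down the fast
# implementations. Each is written from the definition, not from the
# package's code path.

# mean pairwise Hamming distance between chromosomes at each site,
# summed and divided by window length (haps: haplotypes x sites)
oraclePi <- function(haps, windowLen) {
    n <- nrow(haps)
    stopifnot(n >= 2)
    tot <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
        tot <- tot + sum(haps[i, ] != haps[j, ])
    tot / choose(n, 2) / windowLen
}

# EHH by explicit pair enumeration: fraction of haplotype pairs
# identical over the span from the core to each extension site
oracleEhh <- function(haps, core, direction) {
    n <- nrow(haps)
    sites <- if (direction == "right") core:ncol(haps) else core:1
    vapply(seq_along(sites), function(k) {
        span <- sites[seq_len(k)]
        same <- 0
        for (i in seq_len(n - 1)) for (j in (i + 1):n)
            if (all(haps[i, span] == haps[j, span])) same <- same + 1
        same / choose(n, 2)
    }, numeric(1))
}

# HWE exact p by absolute-probability enumeration: P(h heterozygotes |
# allele counts) = n! / (nAA! h! naa!) * 2^h * nA! na! / (2n)!
oracleHwe <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    nA <- 2 * nAA + nAa
    na <- 2 * naa + nAa
    if (nA == 0 || na == 0) return(1)
    hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
    pr <- vapply(hets, function(h) {
        a <- (nA - h) / 2
        b <- (na - h) / 2
        exp(lfactorial(n) - lfactorial(a) - lfactorial(h) -
            lfactorial(b) + h * log(2) + lfactorial(nA) +
            lfactorial(na) - lfactorial(2 * n))
    }, numeric(1))
    stopifnot(abs(sum(pr) - 1) < 1e-9)
    obs <- pr[match(nAa, hets)]
    sum(pr[pr <= obs * (1 + 1e-12)])
}

# Weir & Cockerham (1984) components for one bi-allelic site and two
# populations, transcribed scalar-by-scalar from the published
# estimator (r = 2)
oracleWcSite <- function(g1, g2) {
    n1 <- sum(!is.na(g1)); n2 <- sum(!is.na(g2))
    p1 <- sum(g1, na.rm = TRUE) / (2 * n1)
    p2 <- sum(g2, na.rm = TRUE) / (2 * n2)
    h1 <- mean(g1 == 1, na.rm = TRUE)
    h2 <- mean(g2 == 1, na.rm = TRUE)
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
        (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    c(a = a, d = a + b + cc)
}

# random phased cohort for property tests
randomPanel <- function(nHap, nSites, seed, posStep = 1000) {
    set.seed(seed)
    h <- matrix(sample(0:1, nHap * nSites, replace = TRUE),
                nHap, nSites)
    new("HaplotypePanel", haplotypes = h,
        positions = seq_len(nSites) * posStep, population = "p")
}

# small GenotypeData straight from matrices
toyGenotypes <- function(dosage, pos = NULL, chrom = "chr1",
                         breed = NULL, hapA = NULL, hapB = NULL) {
    m <- nrow(dosage)
    if (is.null(pos)) pos <- seq_len(m) * 100
    if (is.null(colnames(dosage)))
        colnames(dosage) <- sprintf("s%02d", seq_len(ncol(dosage)))
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1))
    samples <- data.frame(sample = colnames(dosage),
                          breed = breed %||% "b1")
    makeGenotypeData(dosage, gr, samples, hapA = hapA, hapB = hapB)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# non-overlapping uniform interval starts (0-based) by rejection
placeRandomIntervals <- function(n, w, L) {
    repeat {
        st <- sort(sample.int(L - w, n))
        if (all(diff(st) >= w)) return(st)
    }
}
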