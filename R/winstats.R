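#' Tile a genome into non-overlapping windows
#'
#' Windows start at coordinate 0 (0-based half-open internally, exposed
#' as 1-based GRanges) and tile each chromosome with fixed-width bins;
#' the final partial bin is kept.
#'
#' @param chromLens named numeric vector of chromosome lengths (bp).
#' @param size window width in bp (default 10 kb).
#' @return `GRanges` of windows.
#' @export
tileWindows <- function(chromLens, size = 10000) {
    grl <- lapply(names(chromLens), function(chr) {
        len <- chromLens[[chr]]
        s <- seq(0, len - 1, by = size)
        GRanges(chr, IRanges(start = s + 1, end = pmin(s + size, len)))
    })
    do.call(c, grl)
}

#' Weir-Cockerham per-site variance components (two populations)
#'
#' Computes the 1984 variance-components decomposition from observed
#' allele frequencies, sample sizes and heterozygote proportions:
#' `a` (among-population), `b` (among individuals within populations),
#' `c` (within individuals). The per-site estimator is `a / (a+b+c)`;
#' window estimates should use the ratio-of-sums form via
#' [windowedFst()]. Sites where either population has fewer than two
#' non-missing calls are skipped (NA components).
#'
#' @param x a [GenotypeData-class] object or dosage matrix.
#' @param pop1,pop2 sample selectors (ids, indices or logical masks)
#'   defining the two populations.
#' @return data.frame with per-site `a`, `d` (= a+b+c), `fst`.
#' @export
siteFst <- function(x, pop1, pop2) {
    d <- if (is(x, "GenotypeData")) dosage(x) else x
    g1 <- d[, pop1, drop = FALSE]
    g2 <- d[, pop2, drop = FALSE]
    n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
    p1 <- rowSums(g1, na.rm = TRUE) / (2 * n1)
    p2 <- rowSums(g2, na.rm = TRUE) / (2 * n2)
    h1 <- rowMeans(g1 == 1L, na.rm = TRUE)
    h2 <- rowMeans(g2 == 1L, na.rm = TRUE)
    r <- 2
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    bad <- n1 < 2 | n2 < 2
    a[bad] <- NA; b[bad] <- NA; cc[bad] <- NA
    dd <- a + b + cc
    data.frame(a = a, d = dd, fst = ifelse(dd > 0, a / dd, NA_real_))
}

.assignWindows <- function(chrom, pos, windows) {
    gr <- GRanges(chrom, IRanges(pos, width = 1L))
    GenomicRanges::findOverlaps(gr, windows,
                                select = "first")
}

#' Windowed Weir-Cockerham FST (ratio of sums)
#'
#' Window FST is `sum(a) / sum(a+b+c)` over the sites in each window;
#' the mean-of-ratios alternative is available via
#' `weighting = "mean_of_ratios"`. Windows with no usable site or a
#' non-positive denominator are NA and are excluded from downstream
#' quantile ranking.
#'
#' @param x a [GenotypeData-class] object.
#' @param pop1,pop2 sample selectors for the two populations.
#' @param windows `GRanges` of windows (e.g. from [tileWindows()]).
#' @param weighting "ratio_of_sums" (default) or "mean_of_ratios".
#' @return the `windows` GRanges with mcols `n_snps` and `fst`.
#' @export
windowedFst <- function(x, pop1, pop2, windows,
                        weighting = c("ratio_of_sums",
                                      "mean_of_ratios")) {
    weighting <- match.arg(weighting)
    comp <- siteFst(x, pop1, pop2)
    w <- .assignWindows(as.character(seqnames(x)), start(x), windows)
    ok <- !is.na(w) & !is.na(comp$d)
    nW <- length(windows)
    nsnp <- tabulate(w[ok], nbins = nW)
    if (weighting == "ratio_of_sums") {
        sa <- rep(0, nW); sd <- rep(0, nW)
        sa[seq_len(nW)] <- tapplySum(comp$a[ok], w[ok], nW)
        sd[seq_len(nW)] <- tapplySum(comp$d[ok], w[ok], nW)
        fst <- ifelse(nsnp > 0 & sd > 0, sa / sd, NA_real_)
    } else {
        s <- tapplySum(ifelse(is.na(comp$fst[ok]), 0, comp$fst[ok]),
                       w[ok], nW)
        nn <- tabulate(w[ok & !is.na(comp$fst)], nbins = nW)
        fst <- ifelse(nn > 0, s / nn, NA_real_)
    }
    out <- windows
    S4Vectors::mcols(out)$n_snps <- nsnp
    S4Vectors::mcols(out)$fst <- fst
    out
}

tapplySum <- function(v, g, nbins) {
    out <- rep(0, nbins)
    s <- tapply(v, g, sum)
    out[as.integer(names(s))] <- as.numeric(s)
    out
}

#' Windowed nucleotide diversity (theta-pi)
#'
#' Per-site pi is the expected pairwise difference
#' `c_ref * c_alt / choose(n_chrom, 2)` over the non-missing chromosomes
#' at the site; window theta-pi divides the summed site pi by the window
#' length in bp. Monomorphic windows give 0.
#'
#' @param x a [GenotypeData-class] object.
#' @param samples sample selector defining the group.
#' @param windows `GRanges` of windows.
#' @return the `windows` GRanges with mcols `n_snps` (polymorphic sites)
#'   and `theta_pi` (per-bp).
#' @export
windowedPi <- function(x, samples, windows) {
    d <- dosage(x)[, samples, drop = FALSE]
    nChrom <- 2 * rowSums(!is.na(d))
    cAlt <- rowSums(d, na.rm = TRUE)
    cRef <- nChrom - cAlt
    piSite <- ifelse(nChrom >= 2,
                     cRef * cAlt / choose(nChrom, 2), NA_real_)
    w <- .assignWindows(as.character(seqnames(x)), start(x), windows)
    ok <- !is.na(w) & !is.na(piSite)
    nW <- length(windows)
    s <- tapplySum(piSite[ok], w[ok], nW)
    poly <- ok & piSite > 0
    out <- windows
    S4Vectors::mcols(out)$n_snps <- tabulate(w[poly], nbins = nW)
    S4Vectors::mcols(out)$theta_pi <- s / width(windows)
    out
}

#' Windowed diversity ratio between two groups
#'
#' Computes theta-pi for each group on a shared window grid and their
#' ratio `pi_query / pi_ref` (conventionally pony over horse, so a sweep
#' in ponies drives the ratio toward 0). Windows where the reference
#' diversity is 0, or with fewer than `minSnps` segregating sites in
#' either group, are NA and excluded from ranking.
#'
#' @param x a [GenotypeData-class] object.
#' @param query,ref sample selectors for the two groups.
#' @param windows `GRanges` of windows.
#' @param minSnps minimum segregating sites per window (default 1).
#' @return the `windows` GRanges with mcols `pi_query`, `pi_ref`,
#'   `pi_ratio`, `n_snps` (total segregating in either group).
#' @export
piRatio <- function(x, query, ref, windows, minSnps = 1L) {
    wq <- windowedPi(x, query, windows)
    wr <- windowedPi(x, ref, windows)
    pq <- S4Vectors::mcols(wq)$theta_pi
    pr <- S4Vectors::mcols(wr)$theta_pi
    nq <- S4Vectors::mcols(wq)$n_snps
    nr <- S4Vectors::mcols(wr)$n_snps
    ratio <- ifelse(pr > 0 & pmax(nq, nr) >= minSnps, pq / pr, NA_real_)
    out <- windows
    S4Vectors::mcols(out)$pi_query <- pq
    S4Vectors::mcols(out)$pi_ref <- pr
    S4Vectors::mcols(out)$pi_ratio <- ratio
    S4Vectors::mcols(out)$n_snps <- pmax(nq, nr)
    out
}

#' Linkage-disequilibrium decay curve
#'
#' All site pairs within `maxDist` bp on the same chromosome contribute
#' their dosage-correlation r-squared to a distance bin; the curve is
#' the per-bin mean. Groups below `minSamples` individuals are rejected,
#' mirroring the >= 8-individuals-per-breed rule for breed-resolved
#' decay comparisons.
#'
#' @param x a [GenotypeData-class] object.
#' @param samples sample selector for the breed/group.
#' @param maxDist maximum pair distance in bp.
#' @param binWidth distance-bin width in bp.
#' @param minSamples minimum group size (default 8).
#' @return data.frame with `bin_start`, `bin_end`, `mean_r2`, `n_pairs`.
#' @export
ldDecay <- function(x, samples, maxDist = 100000, binWidth = 1000,
                    minSamples = 8L) {
    d <- dosage(x)[, samples, drop = FALSE]
    if (ncol(d) < minSamples)
        stop("group has fewer than ", minSamples, " samples")
    chrom <- as.character(seqnames(x)); pos <- start(x)
    nb <- ceiling(maxDist / binWidth)
    sums <- rep(0, nb); cnts <- rep(0L, nb)
    for (chr in unique(chrom)) {
        idx <- which(chrom == chr)
        if (length(idx) < 2L) next
        dd <- t(d[idx, , drop = FALSE])
        pp <- pos[idx]
        r2 <- .r2mat(dd)
        for (i in seq_len(length(idx) - 1L)) {
            js <- which(pp > pp[i] & pp - pp[i] <= maxDist)
            js <- js[js > i]
            if (!length(js)) next
            b <- pmin(nb, ceiling((pp[js] - pp[i]) / binWidth))
            v <- r2[i, js]
            keep <- !is.na(v)
            if (!any(keep)) next
            tb <- tapply(v[keep], b[keep], sum)
            sums[as.integer(names(tb))] <- sums[as.integer(names(tb))] +
                as.numeric(tb)
            tc <- table(b[keep])
            cnts[as.integer(names(tc))] <- cnts[as.integer(names(tc))] +
                as.integer(tc)
        }
    }
    used <- cnts > 0
    data.frame(bin_start = (which(used) - 1L) * binWidth,
               bin_end = which(used) * binWidth,
               mean_r2 = sums[used] / cnts[used],
               n_pairs = cnts[used])
}

#' Detect runs of homozygosity with a scanning-window algorithm
#'
#' PLINK `--homozyg`-style detection per sample: a sliding window of
#' `windowSnps` SNPs is a "hit" when it contains at most `maxHetInWindow`
#' heterozygous and at most `maxMissingInWindow` missing calls; a SNP is
#' in-ROH when the fraction of windows overlapping it that are hits is
#' at least `hitRate`. Maximal runs of consecutive in-ROH SNPs are split
#' at adjacent-SNP gaps above `maxGapKb` and reported when they span at
#' least `minLengthKb`, contain at least `minSnps` SNPs and have density
#' (kb per SNP) at most `maxKbPerSnp`.
#'
#' @param x a [GenotypeData-class] object (sites position-sorted).
#' @param samples sample selector (default: all samples).
#' @param windowSnps scanning window size in SNPs (default 50).
#' @param maxHetInWindow max heterozygous calls per hit window (default 1).
#' @param maxMissingInWindow max missing calls per hit window (default 5).
#' @param hitRate minimum hit fraction for a SNP (default 0.05).
#' @param minLengthKb minimum segment length in kb (default 500).
#' @param minSnps minimum SNPs per segment (default 50).
#' @param maxGapKb maximum between-variant gap in kb (default 100).
#' @param maxKbPerSnp maximum segment kb-per-SNP density (default 50).
#' @return data.frame of segments: `sample`, `chrom`, `start`, `end`
#'   (bp, 1-based inclusive), `n_snps`, `length_kb`.
#' @export
rohDetect <- function(x, samples = NULL, windowSnps = 50L,
                      maxHetInWindow = 1L, maxMissingInWindow = 5L,
                      hitRate = 0.05, minLengthKb = 500,
                      minSnps = 50L, maxGapKb = 100,
                      maxKbPerSnp = 50) {
    d <- dosage(x)
    if (!is.null(samples)) d <- d[, samples, drop = FALSE]
    chrom <- as.character(seqnames(x)); pos <- start(x)
    out <- list()
    for (s in colnames(d)) {
        g <- d[, s]
        for (chr in unique(chrom)) {
            idx <- which(chrom == chr)
            m <- length(idx)
            if (m < windowSnps) {
                warning("chromosome ", chr,
                        " shorter than one scanning window; skipped")
                next
            }
            gg <- g[idx]; pp <- pos[idx]
            het <- as.integer(!is.na(gg) & gg == 1L)
            mis <- as.integer(is.na(gg))
            cumh <- c(0L, cumsum(het)); cumm <- c(0L, cumsum(mis))
            nW <- m - windowSnps + 1L
            ws <- seq_len(nW)
            hit <- (cumh[ws + windowSnps] - cumh[ws]) <= maxHetInWindow &
                   (cumm[ws + windowSnps] - cumm[ws]) <= maxMissingInWindow
            # windows overlapping SNP i: starts max(1,i-W+1)..min(i,nW)
            cumhit <- c(0L, cumsum(as.integer(hit)))
            lo <- pmax(1L, seq_len(m) - windowSnps + 1L)
            hi <- pmin(seq_len(m), nW)
            nOv <- hi - lo + 1L
            nHit <- cumhit[hi + 1L] - cumhit[lo]
            inRoh <- nOv > 0L & nHit / nOv >= hitRate
            # additionally a het call itself can never sit inside an ROH
            inRoh <- inRoh & het == 0L
            if (!any(inRoh)) next
            r <- rle(inRoh)
            ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
            for (k in which(r$values)) {
                runIdx <- starts[k]:ends[k]
                # split at gaps > maxGapKb
                gaps <- diff(pp[runIdx])
                cut <- which(gaps > maxGapKb * 1000)
                bounds <- c(0L, cut, length(runIdx))
                for (b in seq_len(length(bounds) - 1L)) {
                    sub <- runIdx[(bounds[b] + 1L):bounds[b + 1L]]
                    lenKb <- (pp[sub[length(sub)]] - pp[sub[1L]] + 1) / 1000
                    nS <- length(sub)
                    if (lenKb >= minLengthKb && nS >= minSnps &&
                        lenKb / nS <= maxKbPerSnp) {
                        out[[length(out) + 1L]] <- data.frame(
                            sample = s, chrom = chr,
                            start = pp[sub[1L]],
                            end = pp[sub[length(sub)]],
                            n_snps = nS, length_kb = lenKb,
                            stringsAsFactors = FALSE)
                    }
                }
            }
        }
    }
    if (!length(out))
        return(data.frame(sample = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          n_snps = integer(), length_kb = numeric()))
    do.call(rbind, out)
}
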