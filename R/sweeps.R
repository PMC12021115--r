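#' Empirical-quantile tail threshold for a metric track
#'
#' The threshold is the empirical quantile over defined (non-NA) values
#' only; flagging is strict (`>` for the upper tail, `<` for the lower),
#' so ties sitting exactly at the threshold are not flagged.
#'
#' @param values per-window metric values (NA = undefined window).
#' @param q tail fraction (default 0.01 for a top-1% rule).
#' @param tail "upper" or "lower".
#' @return list with `threshold` and logical `flagged` (same length as
#'   `values`; NA windows are never flagged).
#' @export
quantileCut <- function(values, q = 0.01, tail = c("upper", "lower")) {
    tail <- match.arg(tail)
    ok <- !is.na(values)
    if (!any(ok)) stop("all windows undefined")
    if (q >= 1) {
        thr <- if (tail == "upper") min(values[ok]) else max(values[ok])
        return(list(threshold = thr, flagged = ok))
    }
    if (sum(ok) < 1 / q)
        warning("fewer than 1/q defined windows; the tail is coarse")
    thr <- if (tail == "upper")
        stats::quantile(values[ok], 1 - q, names = FALSE)
    else stats::quantile(values[ok], q, names = FALSE)
    flagged <- rep(FALSE, length(values))
    flagged[ok] <- if (tail == "upper") values[ok] > thr
                   else values[ok] < thr
    list(threshold = thr, flagged = flagged)
}

.mergeFlagged <- function(windows, flagged, mergeGap = 0) {
    if (!any(flagged)) return(GRanges())
    GenomicRanges::reduce(windows[flagged],
                          min.gapwidth = mergeGap + 1L)
}

#' Call multi-metric selective-sweep candidates
#'
#' Per metric, the top-tail windows (top 1% by default) are merged into
#' regions (adjacent or within `mergeGap` bp); a candidate region is
#' any interval covered by at least two of the three metric region
#' sets (FST upper tail, pi-ratio lower tail for a query-side sweep,
#' |mean XP-EHH| with the configured tail). The output is sorted and
#' non-overlapping, each region annotated with its supporting metrics.
#'
#' @param windows `GRanges` carrying the metric mcols.
#' @param fst,piRatio,xpehh per-window numeric tracks (any may be NULL
#'   to drop that metric); by default read from mcols `fst`, `pi_ratio`,
#'   `mean_xpehh` of `windows`.
#' @param q tail fraction per metric (default 0.01).
#' @param piRatioTail tail for the diversity ratio: "lower" flags
#'   query-side sweeps (default), "upper" reference-side.
#' @param xpehhTail tail for mean XP-EHH ("upper" = query-side, the
#'   pony-vs-horse convention).
#' @param mergeGap merge distance for flagged windows in bp (default 0:
#'   only adjacent windows merge).
#' @param minSupport minimum number of supporting metrics (default 2).
#' @return `GRanges` of candidate regions with mcols `supports`
#'   (comma-separated metric names) and `n_supports`.
#' @export
callCandidates <- function(windows, fst = NULL, piRatio = NULL,
                           xpehh = NULL, q = 0.01,
                           piRatioTail = c("lower", "upper"),
                           xpehhTail = c("upper", "lower"),
                           mergeGap = 0, minSupport = 2L) {
    piRatioTail <- match.arg(piRatioTail)
    xpehhTail <- match.arg(xpehhTail)
    mc <- S4Vectors::mcols(windows)
    if (is.null(fst) && "fst" %in% names(mc)) fst <- mc$fst
    if (is.null(piRatio) && "pi_ratio" %in% names(mc))
        piRatio <- mc$pi_ratio
    if (is.null(xpehh) && "mean_xpehh" %in% names(mc))
        xpehh <- mc$mean_xpehh
    sets <- list()
    if (!is.null(fst))
        sets$FST <- .mergeFlagged(windows,
            quantileCut(fst, q, "upper")$flagged, mergeGap)
    if (!is.null(piRatio))
        sets$PI_RATIO <- .mergeFlagged(windows,
            quantileCut(piRatio, q, piRatioTail)$flagged, mergeGap)
    if (!is.null(xpehh))
        sets$XPEHH <- .mergeFlagged(windows,
            quantileCut(xpehh, q, xpehhTail)$flagged, mergeGap)
    if (length(sets) < minSupport)
        stop("need at least ", minSupport, " metric tracks")
    all <- GenomicRanges::reduce(do.call(c, unname(sets)))
    if (!length(all)) return(GRanges())
    # split the union into atomic pieces and count metric support
    pieces <- GenomicRanges::disjoin(do.call(c, unname(sets)))
    support <- sapply(sets, function(s)
        IRanges::overlapsAny(pieces, s))
    if (is.null(dim(support)))
        support <- matrix(support, nrow = length(pieces),
                          dimnames = list(NULL, names(sets)))
    nSup <- rowSums(support)
    keep <- nSup >= minSupport
    if (!any(keep)) return(GRanges())
    cand <- GenomicRanges::reduce(pieces[keep])
    sup <- sapply(seq_along(cand), function(i) {
        hit <- vapply(sets, function(s)
            IRanges::overlapsAny(cand[i], s), logical(1))
        paste(names(sets)[hit], collapse = ",")
    })
    S4Vectors::mcols(cand)$supports <- sup
    S4Vectors::mcols(cand)$n_supports <- vapply(
        strsplit(sup, ","), length, integer(1))
    sort(cand)
}

#' Merge flagged SNP positions into intervals
#'
#' SNPs closer than `maxGap` bp are merged into one interval — the
#' region-building rule applied to significant XP-EHH cores before the
#' interval-overlap analysis (merge distance < 100 bp).
#'
#' @param chrom,pos vectors of SNP coordinates (1-based).
#' @param maxGap merge distance in bp; gaps strictly smaller merge
#'   (default 100).
#' @return `GRanges` of merged intervals.
#' @export
mergeNearbySnps <- function(chrom, pos, maxGap = 100) {
    gr <- GRanges(chrom, IRanges(pos, width = 1L))
    GenomicRanges::reduce(gr, min.gapwidth = maxGap - 1L)
}

#' Genotype-frequency gradient across ordered height groups
#'
#' For the SNPs of a candidate region, computes per-group frequencies of
#' the 0/1/2 genotype classes and of the ALT allele, and flags whether
#' the ALT-allele frequency is monotone (non-decreasing or
#' non-increasing) across the ordered groups — the pattern expected when
#' a height-associated sweep allele grades with withers height.
#'
#' @param x a [GenotypeData-class] object.
#' @param region `GRanges` (length 1) selecting the SNPs.
#' @param groups ordered factor/character of per-sample group labels
#'   (e.g. height classes, shortest to tallest); samples with NA group
#'   are dropped, empty groups excluded with a warning.
#' @return list: `freq` data.frame (group, n, f0, f1, f2, alt_freq),
#'   `monotone` logical (NA with fewer than 2 groups).
#' @export
genotypeGradient <- function(x, region, groups) {
    keep <- IRanges::overlapsAny(rowRanges(x), region)
    if (!any(keep)) stop("no SNPs in region")
    d <- dosage(x)[keep, , drop = FALSE]
    groups <- as.character(groups)
    ok <- !is.na(groups)
    d <- d[, ok, drop = FALSE]; groups <- groups[ok]
    lev <- unique(groups)
    n <- vapply(lev, function(g) sum(groups == g), integer(1))
    if (any(n == 0)) {
        warning("empty groups excluded")
        lev <- lev[n > 0]
    }
    tab <- t(vapply(lev, function(g) {
        gg <- d[, groups == g, drop = FALSE]
        tot <- sum(!is.na(gg))
        c(n = sum(groups == g),
          f0 = sum(gg == 0L, na.rm = TRUE) / tot,
          f1 = sum(gg == 1L, na.rm = TRUE) / tot,
          f2 = sum(gg == 2L, na.rm = TRUE) / tot,
          alt_freq = sum(gg, na.rm = TRUE) / (2 * tot))
    }, numeric(5)))
    freq <- data.frame(group = lev, tab, row.names = NULL)
    mono <- if (length(lev) < 2L) NA else {
        a <- freq$alt_freq
        all(diff(a) >= 0) || all(diff(a) <= 0)
    }
    list(freq = freq, monotone = mono)
}

.asGRangesIntervals <- function(x, genome = NULL) {
    if (is(x, "GRanges")) return(GenomicRanges::reduce(x))
    # data.frame chrom/start/end, 0-based half-open
    GenomicRanges::reduce(GRanges(x$chrom,
                                  IRanges(x$start + 1, x$end)))
}

#' Interval-overlap Fisher exact test
#'
#' Builds an interval-wise 2x2 contingency table in the style of
#' `bedtools fisher`: n11 = A-intervals overlapping at least one
#' B-interval, n12 = the remaining A-intervals, n21 = B-intervals
#' overlapping no A-interval, and n22 estimates the number of
#' comparably-sized genome slots left empty,
#' `max(0, round(L / (mean_len_A + mean_len_B)) - n11 - n12 - n21)`.
#' Both sets are internally merged first. The p-value is the two-sided
#' Fisher exact test on this table; the odds ratio applies a Haldane
#' 0.5 correction when a cell is zero. The n22 slot count is an
#' approximation and is reported alongside the raw counts.
#'
#' @param A,B interval sets: `GRanges` or data.frames with `chrom`,
#'   `start`, `end` (0-based half-open).
#' @param genomeLens named vector of chromosome lengths (bp).
#' @return list: `table` (2x2 matrix), `odds_ratio`, `p_value`.
#' @export
intervalFisher <- function(A, B, genomeLens) {
    A <- .asGRangesIntervals(A); B <- .asGRangesIntervals(B)
    if (!length(A) || !length(B)) stop("empty interval set")
    n11 <- sum(IRanges::overlapsAny(A, B))
    n12 <- length(A) - n11
    n21 <- sum(!IRanges::overlapsAny(B, A))
    L <- sum(genomeLens)
    slots <- round(L / (mean(width(A)) + mean(width(B))))
    n22 <- max(0, slots - n11 - n12 - n21)
    tab <- matrix(c(n11, n12, n21, n22), 2, 2, byrow = TRUE,
                  dimnames = list(c("A", "notA"), c("B", "notB")))
    ft <- stats::fisher.test(tab)
    orr <- if (any(tab == 0))
        ((n11 + 0.5) * (n22 + 0.5)) / ((n12 + 0.5) * (n21 + 0.5))
    else (n11 * n22) / (n12 * n21)
    list(table = tab, odds_ratio = orr, p_value = ft$p.value)
}

.placeIntervals <- function(widths, chromLen, maxTries = 1000L) {
    # place interval widths uniformly on [0, chromLen) without overlap
    for (try in seq_len(maxTries)) {
        starts <- floor(runif(length(widths), 0, chromLen - widths))
        o <- order(starts)
        s <- starts[o]; w <- widths[o]
        if (all(s[-1] >= (s + w)[-length(s)])) {
            res <- numeric(length(widths))
            res[o] <- s
            return(res)
        }
    }
    NULL
}

#' Permutation null for interval overlap
#'
#' Repeats the overlap odds-ratio computation with set A re-placed
#' uniformly at random `nShuffles` times; each interval keeps its
#' length and chromosome (a conservative null) and placed intervals do
#' not overlap each other. The empirical p-value is
#' `(1 + #(null OR >= observed OR)) / (nShuffles + 1)`, never a literal
#' zero. `freePlacement = TRUE` instead reassigns intervals to
#' chromosomes with probability proportional to length.
#'
#' @param A,B interval sets as in [intervalFisher()].
#' @param genomeLens named chromosome lengths (bp).
#' @param nShuffles number of permutations (default 10000).
#' @param seed integer RNG seed (mandatory; the null is reproducible).
#' @param freePlacement drop the per-chromosome constraint.
#' @return list: observed `table`/`odds_ratio`/`p_value` (Fisher), the
#'   `null` odds-ratio sample (length `nShuffles`), `empirical_p`,
#'   `seed`.
#' @export
shuffleOverlapNull <- function(A, B, genomeLens, nShuffles = 10000L,
                               seed, freePlacement = FALSE) {
    if (missing(seed)) stop("a seed is mandatory")
    A <- .asGRangesIntervals(A); B <- .asGRangesIntervals(B)
    obs <- intervalFisher(A, B, genomeLens)
    old <- .saveRNGState()
    on.exit(.restoreRNGState(old))
    set.seed(seed)
    chromA <- as.character(seqnames(A))
    wA <- width(A)
    for (chr in unique(chromA)) {
        if (sum(wA[chromA == chr]) >= genomeLens[[chr]])
            stop("intervals on ", chr, " exceed chromosome length")
    }
    # plain numeric interval arithmetic in the replicate loop; closed
    # 1-based coordinates throughout
    bChrom <- as.character(seqnames(B))
    bByChrom <- lapply(stats::setNames(nm = names(genomeLens)),
                       function(chr) {
        i <- which(bChrom == chr)
        s <- start(B)[i]; e <- end(B)[i]
        o <- order(s)
        list(start = s[o], end = e[o], cummaxEnd = cummax(e[o]),
             origIdx = i[o])
    })
    L <- sum(genomeLens)
    slots <- round(L / (mean(wA) + mean(width(B))))
    nullOR <- numeric(nShuffles)
    for (r in seq_len(nShuffles)) {
        chroms <- if (freePlacement)
            sample(names(genomeLens), length(wA), replace = TRUE,
                   prob = genomeLens)
        else chromA
        n11 <- 0L
        bHit <- logical(length(B))
        for (chr in unique(chroms)) {
            i <- chroms == chr
            st <- .placeIntervals(wA[i], genomeLens[[chr]])
            if (is.null(st))
                stop("interval placement failed on ", chr)
            aS <- st + 1; aE <- st + wA[i]
            bb <- bByChrom[[chr]]
            if (length(bb$start)) {
                j <- findInterval(aE, bb$start)
                n11 <- n11 + sum(j >= 1L & bb$cummaxEnd[pmax(j, 1L)] >= aS)
                # which B intervals on this chromosome are hit
                oA <- order(aS)
                aSo <- aS[oA]; aEo <- aE[oA]
                k <- findInterval(bb$end, aSo)
                hit <- k >= 1L & cummax(aEo)[pmax(k, 1L)] >= bb$start
                bHit[bb$origIdx] <- bHit[bb$origIdx] | hit
            }
        }
        n12 <- length(wA) - n11
        n21 <- length(B) - sum(bHit)
        n22 <- max(0, slots - n11 - n12 - n21)
        nullOR[r] <- ((n11 + 0.5) * (n22 + 0.5)) /
                     ((n12 + 0.5) * (n21 + 0.5))
    }
    tab <- obs$table
    obsOR <- ((tab[1, 1] + 0.5) * (tab[2, 2] + 0.5)) /
             ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
    list(table = obs$table, odds_ratio = obs$odds_ratio,
         p_value = obs$p_value, null = nullOR,
         empirical_p = (1 + sum(nullOR >= obsOR)) / (nShuffles + 1),
         seed = seed)
}

#' Run the full multi-metric sweep scan
#'
#' Convenience pipeline over one phased cohort: windowed FST, windowed
#' diversity ratio and window-averaged XP-EHH between a query and a
#' reference group (pony vs horse in the motivating design), followed
#' by multi-metric candidate calling.
#'
#' @param x a phased [GenotypeData-class] object.
#' @param query,ref sample selectors (logical masks or ids) for the two
#'   groups.
#' @param windows `GRanges` of windows (default: 10-kb tiling of
#'   `metadata(x)$chromLen`).
#' @param q tail fraction for each metric (default 0.01).
#' @param ... further arguments to [callCandidates()].
#' @return list: `windows` (with `fst`, `pi_ratio`, `mean_xpehh`,
#'   `n_snps` mcols), `track` (per-core XP-EHH), `candidates`
#'   (`GRanges`).
#' @export
sweepScan <- function(x, query, ref, windows = NULL, q = 0.01, ...) {
    if (is.null(windows)) {
        cl <- metadata(x)$chromLen
        if (is.null(cl)) stop("supply windows or set metadata chromLen")
        windows <- tileWindows(stats::setNames(
            cl, as.character(seqnames(x)[1])))
    }
    wf <- windowedFst(x, query, ref, windows)
    wp <- piRatio(x, query, ref, windows)
    pq <- haplotypePanel(x, query, population = "query")
    pr <- haplotypePanel(x, ref, population = "ref")
    tr <- xpehhScores(pq, pr)
    wx <- windowAverage(tr, windows)
    out <- windows
    S4Vectors::mcols(out)$n_snps <- S4Vectors::mcols(wf)$n_snps
    S4Vectors::mcols(out)$fst <- S4Vectors::mcols(wf)$fst
    S4Vectors::mcols(out)$pi_query <- S4Vectors::mcols(wp)$pi_query
    S4Vectors::mcols(out)$pi_ref <- S4Vectors::mcols(wp)$pi_ref
    S4Vectors::mcols(out)$pi_ratio <- S4Vectors::mcols(wp)$pi_ratio
    S4Vectors::mcols(out)$mean_xpehh <- S4Vectors::mcols(wx)$mean_xpehh
    list(windows = out, track = tr,
         candidates = callCandidates(out, q = q, ...))
}
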