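#' Extended haplotype homozygosity outward from a core site
#'
#' At extension site x, haplotypes are partitioned by identity over the
#' span [core..x]; EHH(x) is the probability that two random distinct
#' haplotypes fall in the same class: `sum(choose(n_g, 2)) / choose(n, 2)`.
#' At the core itself the partition is by core allele. The curve is
#' monotone non-increasing away from the core (each step refines the
#' partition).
#'
#' @param panel a [HaplotypePanel-class].
#' @param core core site index (1-based column of the panel).
#' @param direction "right" (increasing position) or "left".
#' @return data.frame with `index`, `pos`, `ehh`, ordered outward from
#'   the core (first row = the core site).
#' @export
ehhCurve <- function(panel, core, direction = c("right", "left")) {
    direction <- match.arg(direction)
    h <- haplotypes(panel)
    m <- ncol(h); n <- nrow(h)
    if (core < 1L || core > m) stop("core out of range")
    if (n < 2L) stop("need at least 2 haplotypes")
    sites <- if (direction == "right") core:m else core:1
    denom <- choose(n, 2)
    grp <- rep(1L, n)
    ehh <- numeric(length(sites))
    for (k in seq_along(sites)) {
        key <- grp * 2L + h[, sites[k]]
        grp <- match(key, unique(key))
        tab <- tabulate(grp)
        ehh[k] <- sum(choose(tab, 2)) / denom
    }
    data.frame(index = sites, pos = positions(panel)[sites], ehh = ehh)
}

#' Integrated EHH (iHH) at a core site
#'
#' Trapezoidal integral of the EHH curve over physical position, left
#' and right of the core, stopping when EHH drops below `cutoff`
#' (integrating down to the crossing), when the extension exceeds
#' `maxExtend` (integrating up to the boundary), or at an adjacent-site
#' gap larger than `maxGap` (integration truncated there). iHH is the
#' sum of the two one-sided integrals, in bp units.
#'
#' @param panel a [HaplotypePanel-class].
#' @param core core site index.
#' @param cutoff EHH stop threshold (default 0.05).
#' @param maxExtend maximum one-sided extension in bp (default 1 Mb).
#' @param maxGap maximum tolerated adjacent-site gap in bp (default 200 kb).
#' @return list with `ihh` (bp) and `truncated` (TRUE when either side
#'   ran off the panel before EHH reached the cutoff).
#' @export
ihh <- function(panel, core, cutoff = 0.05, maxExtend = 1e6,
                maxGap = 2e5) {
    h <- haplotypes(panel)
    pos <- positions(panel)
    ri <- .ehhWalkIntegrate(h, pos, core, +1L, cutoff, maxExtend,
                            maxGap)
    li <- .ehhWalkIntegrate(h, pos, core, -1L, cutoff, maxExtend,
                            maxGap)
    list(ihh = ri$ihh + li$ihh, truncated = ri$truncated || li$truncated)
}

# incremental one-sided EHH walk + trapezoid, stopping at the cutoff
# crossing, the maxExtend boundary, a gap > maxGap, EHH = 0, or the
# panel edge (only the last counts as truncation)
.ehhWalkIntegrate <- function(h, pos, core, dir, cutoff, maxExtend,
                              maxGap) {
    n <- nrow(h); m <- ncol(h)
    denom <- choose(n, 2)
    grp <- match(h[, core], unique(h[, core]))
    tab <- tabulate(grp)
    ehhPrev <- sum(tab * (tab - 1) / 2) / denom
    if (ehhPrev < cutoff) return(list(ihh = 0, truncated = FALSE))
    total <- 0
    k <- core
    repeat {
        k <- k + dir
        if (k < 1L || k > m)
            return(list(ihh = total, truncated = TRUE))
        step <- abs(pos[k] - pos[k - dir])
        if (step > maxGap)
            return(list(ihh = total, truncated = FALSE))
        key <- grp * 2L + h[, k]
        grp <- match(key, unique(key))
        tab <- tabulate(grp)
        e2 <- sum(tab * (tab - 1) / 2) / denom
        ext <- abs(pos[k] - pos[core])
        if (ext > maxExtend) {
            prevExt <- abs(pos[k - dir] - pos[core])
            fr <- (maxExtend - prevExt) / (ext - prevExt)
            eB <- ehhPrev + fr * (e2 - ehhPrev)
            total <- total + (maxExtend - prevExt) * (ehhPrev + eB) / 2
            return(list(ihh = total, truncated = FALSE))
        }
        if (e2 < cutoff) {
            fr <- if (ehhPrev > e2) (ehhPrev - cutoff) / (ehhPrev - e2)
                  else 1
            total <- total + step * fr * (ehhPrev + cutoff) / 2
            return(list(ihh = total, truncated = FALSE))
        }
        total <- total + step * (ehhPrev + e2) / 2
        ehhPrev <- e2
        if (e2 == 0) return(list(ihh = total, truncated = FALSE))
    }
}

#' Cross-population EHH (XP-EHH) scores
#'
#' For each eligible core site the raw statistic is
#' `ln(iHH_query / iHH_ref)`; the normalized statistic subtracts the
#' mean and divides by the SD of the raw scores over all scored cores
#' (genome-wide normalization, not frequency-binned). With ponies as
#' the query and horses as the reference, positive scores localize
#' selection on the pony side and negative scores on the horse side.
#' Cores are restricted to pooled MAF at least `minMaf`; cores where
#' either population's iHH is 0 are skipped with a reason.
#'
#' @param query,ref [HaplotypePanel-class] objects on a shared site set.
#' @param minMaf pooled minor-allele-frequency floor for core sites
#'   (default 0.05).
#' @param cutoff,maxExtend,maxGap passed to [ihh()].
#' @return data.frame with `pos`, `raw`, `norm` for scored cores;
#'   attribute `skipped` lists unscored cores and reasons.
#' @export
xpehhScores <- function(query, ref, minMaf = 0.05, cutoff = 0.05,
                        maxExtend = 1e6, maxGap = 2e5) {
    stopifnot(length(positions(query)) == length(positions(ref)),
              all(positions(query) == positions(ref)))
    hq <- haplotypes(query); hr <- haplotypes(ref)
    pooled <- (colSums(hq) + colSums(hr)) / (nrow(hq) + nrow(hr))
    maf <- pmin(pooled, 1 - pooled)
    cores <- which(maf >= minMaf)
    pos <- positions(query)
    raw <- rep(NA_real_, length(cores))
    skip <- character(length(cores))
    for (k in seq_along(cores)) {
        iq <- ihh(query, cores[k], cutoff, maxExtend, maxGap)
        ir <- ihh(ref, cores[k], cutoff, maxExtend, maxGap)
        if (iq$ihh <= 0 || ir$ihh <= 0) {
            skip[k] <- "zero iHH"
            next
        }
        raw[k] <- log(iq$ihh / ir$ihh)
    }
    ok <- !is.na(raw)
    rawOk <- raw[ok]
    sdv <- stats::sd(rawOk)
    norm <- if (isTRUE(sdv > 0)) (rawOk - mean(rawOk)) / sdv
            else rep(0, length(rawOk))
    out <- data.frame(pos = pos[cores[ok]], raw = rawOk, norm = norm)
    attr(out, "skipped") <- data.frame(pos = pos[cores[!ok]],
                                       reason = skip[!ok])
    out
}

#' Average an XP-EHH track over windows
#'
#' Mean normalized score of the cores falling in each window; windows
#' containing no core are NA.
#'
#' @param track data.frame from [xpehhScores()] (columns `pos`, `norm`).
#' @param windows `GRanges` of windows.
#' @param chrom chromosome the track belongs to (default: first seqname
#'   of `windows`).
#' @return the `windows` GRanges with mcols `n_cores` and `mean_xpehh`.
#' @export
windowAverage <- function(track, windows, chrom = NULL) {
    if (is.null(chrom))
        chrom <- as.character(seqnames(windows)[1])
    w <- .assignWindows(rep(chrom, nrow(track)), track$pos, windows)
    ok <- !is.na(w)
    nW <- length(windows)
    n <- tabulate(w[ok], nbins = nW)
    s <- tapplySum(track$norm[ok], w[ok], nW)
    out <- windows
    S4Vectors::mcols(out)$n_cores <- n
    S4Vectors::mcols(out)$mean_xpehh <- ifelse(n > 0, s / n, NA_real_)
    out
}
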