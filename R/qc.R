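#' Default GATK-style hard-filter thresholds
#'
#' A site fails when any clause of
#' `QD < 2 || MQ < 50 || FS > 60 || SOR > 3 || MQRankSum < -5 ||
#'  ReadPosRankSum < -5 || QUAL < 30`
#' triggers. All comparisons are strict.
#'
#' @return named list of thresholds.
#' @export
hardFilterDefaults <- function() {
    list(qd_min = 2.0, mq_min = 50.0, fs_max = 60.0, sor_max = 3.0,
         mqranksum_min = -5.0, readposranksum_min = -5.0,
         qual_min = 30.0)
}

#' Apply hard filters to variant annotations
#'
#' Evaluates the OR expression clause by clause. A site fails iff at
#' least one clause triggers; an absent (NA) annotation never triggers
#' its clause and is recorded as not evaluated. Non-numeric annotation
#' values are reported per site as evaluation errors without stopping
#' the run.
#'
#' @param variants a [GenotypeData-class] object, a `GRanges`, or a
#'   data.frame with columns QD, MQ, FS, SOR, MQRankSum, ReadPosRankSum,
#'   QUAL (any may be absent).
#' @param thresholds list as from [hardFilterDefaults()].
#' @return `DataFrame` with per-site `pass` (logical), `reasons`
#'   (comma-separated failed clauses), `not_evaluated` (comma-separated
#'   absent annotations), `error` (logical).
#' @examples
#' applyHardFilters(data.frame(QD = c(1.5, 2.0), MQ = 55, FS = 1,
#'                             SOR = 1, MQRankSum = 0,
#'                             ReadPosRankSum = 0, QUAL = 100))
#' @export
applyHardFilters <- function(variants, thresholds = hardFilterDefaults()) {
    ann <- if (is(variants, "GenotypeData"))
        as.data.frame(S4Vectors::mcols(rowRanges(variants)))
    else if (is(variants, "GRanges"))
        as.data.frame(S4Vectors::mcols(variants))
    else as.data.frame(variants)
    n <- nrow(ann)
    clauses <- list(
        QD = function(v) v < thresholds$qd_min,
        MQ = function(v) v < thresholds$mq_min,
        FS = function(v) v > thresholds$fs_max,
        SOR = function(v) v > thresholds$sor_max,
        MQRankSum = function(v) v < thresholds$mqranksum_min,
        ReadPosRankSum = function(v) v < thresholds$readposranksum_min,
        QUAL = function(v) v < thresholds$qual_min)
    fail <- matrix(FALSE, n, length(clauses),
                   dimnames = list(NULL, names(clauses)))
    notEval <- matrix(FALSE, n, length(clauses),
                      dimnames = list(NULL, names(clauses)))
    err <- logical(n)
    for (key in names(clauses)) {
        if (!key %in% names(ann)) {
            notEval[, key] <- TRUE
            next
        }
        v <- ann[[key]]
        if (!is.numeric(v)) {
            vn <- suppressWarnings(as.numeric(as.character(v)))
            err <- err | (!is.na(as.character(v)) & is.na(vn))
            v <- vn
        }
        isna <- is.na(v)
        notEval[isna, key] <- TRUE
        res <- clauses[[key]](v)
        fail[!isna, key] <- res[!isna]
    }
    collapse <- function(m) apply(m, 1L, function(r)
        paste(colnames(m)[r], collapse = ","))
    DataFrame(pass = rowSums(fail) == 0L,
              reasons = collapse(fail),
              not_evaluated = collapse(notEval),
              error = err)
}

#' Sample-missingness, variant-missingness and MAF filter
#'
#' Filter order is fixed: (1) samples whose missing-call rate exceeds
#' `maxSampleMissing` are removed; (2) sites whose missing rate among
#' the retained samples exceeds `maxVariantMissing` are removed; (3)
#' sites whose minor-allele frequency among non-missing calls of the
#' retained samples falls below `minMaf` are removed. Defaults mirror a
#' PLINK-style `--mind/--geno/--maf` pass with per-sample 0.08%,
#' per-variant 2% and MAF 1%.
#'
#' @param x a [GenotypeData-class] object.
#' @param maxSampleMissing,maxVariantMissing,minMaf thresholds in [0,1].
#' @return list with the filtered object (`gd`) and a `report`
#'   data.frame of per-stage sample/site attrition.
#' @export
missingnessMafFilter <- function(x, maxSampleMissing = 0.0008,
                                 maxVariantMissing = 0.02,
                                 minMaf = 0.01) {
    stopifnot(is(x, "GenotypeData"))
    d <- dosage(x)
    n0s <- ncol(d); n0v <- nrow(d)
    sampMiss <- colMeans(is.na(d))
    keepS <- sampMiss <= maxSampleMissing
    if (!any(keepS)) stop("all samples removed by missingness filter")
    x <- x[, keepS]
    d <- dosage(x)
    varMiss <- rowMeans(is.na(d))
    keepMiss <- varMiss <= maxVariantMissing
    x <- x[keepMiss, ]
    d <- dosage(x)
    p <- altFreq(d)
    maf <- pmin(p, 1 - p)
    keepMaf <- !is.nan(maf) & maf >= minMaf
    x <- x[keepMaf, ]
    report <- data.frame(
        stage = c("input", "sample_missingness", "variant_missingness",
                  "maf"),
        n_samples = c(n0s, sum(keepS), sum(keepS), sum(keepS)),
        n_sites = c(n0v, n0v, sum(keepMiss),
                    sum(keepMaf)))
    list(gd = x, report = report)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the heterozygote count: given the observed
#' allele counts, the p-value sums the probabilities of all heterozygote
#' counts (same parity, same allele totals) whose conditional probability
#' does not exceed that of the observed configuration. Monomorphic sites
#' return 1 by convention. Mid-p is not applied.
#'
#' @param nAA,nAa,naa genotype counts (non-negative, total > 0).
#' @return exact p-value in (0, 1].
#' @examples
#' hweExactTest(5, 5, 5)
#' @export
hweExactTest <- function(nAA, nAa, naa) {
    stopifnot(nAA >= 0, nAa >= 0, naa >= 0)
    n <- nAA + nAa + naa
    stopifnot(n > 0)
    nA <- 2L * nAA + nAa
    na <- 2L * naa + nAa
    if (nA == 0L || na == 0L) return(1)
    rare <- min(nA, na)
    hets <- seq(rare %% 2L, rare, by = 2L)
    # log P(nAa = h | allele counts) up to a common constant
    lp <- vapply(hets, function(h) {
        hom1 <- (nA - h) / 2; hom2 <- (na - h) / 2
        if (nA < na) { a <- hom1; b <- hom2 } else { a <- hom2; b <- hom1 }
        h * log(2) - lfactorial(a) - lfactorial(h) - lfactorial(b)
    }, numeric(1))
    pr <- exp(lp - max(lp))
    pr <- pr / sum(pr)
    obs <- match(nAa, hets)
    min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' Hardy-Weinberg site filter
#'
#' Removes sites whose exact HWE p-value (pooled genotype counts over
#' non-missing calls) falls below `pMin` (default 1e-6).
#'
#' @param x a [GenotypeData-class] object.
#' @param pMin p-value threshold.
#' @return list with filtered `gd` and per-site `p` values.
#' @export
hweFilter <- function(x, pMin = 1e-6) {
    d <- dosage(x)
    p <- vapply(seq_len(nrow(d)), function(i) {
        g <- d[i, ]
        hweExactTest(sum(g == 0L, na.rm = TRUE),
                     sum(g == 1L, na.rm = TRUE),
                     sum(g == 2L, na.rm = TRUE))
    }, numeric(1))
    list(gd = x[p >= pMin, ], p = p)
}

.r2mat <- function(d) {
    suppressWarnings(cor(d, use = "pairwise.complete.obs"))^2
}

#' Prune sites in linkage disequilibrium
#'
#' Sliding-window LD pruning over sites sorted by (chrom, pos): within
#' each window of `window` SNPs advanced by `step`, while any pair has
#' dosage-correlation r-squared above `r2Max`, the member of the worst
#' pair with the lower MAF is removed (tie: the later position goes).
#' Defaults correspond to a 50-SNP window, step 5, r2 0.5 pass.
#'
#' @param x a [GenotypeData-class] object (sites must be position-sorted).
#' @param window,step window size and step in SNP count.
#' @param r2Max maximum tolerated r-squared.
#' @return integer vector of retained site indices (relative to `x`).
#' @export
ldPrune <- function(x, window = 50L, step = 5L, r2Max = 0.5) {
    stopifnot(window >= 2L, step >= 1L, window >= step)
    d <- dosage(x)
    m <- nrow(d)
    p <- altFreq(d)
    maf <- pmin(p, 1 - p)
    keep <- rep(TRUE, m)
    chrom <- as.character(seqnames(x))
    for (chr in unique(chrom)) {
        idx <- which(chrom == chr)
        for (s in seq(1L, length(idx), by = step)) {
            win <- idx[s:min(s + window - 1L, length(idx))]
            win <- win[keep[win]]
            while (length(win) >= 2L) {
                r2 <- .r2mat(t(d[win, , drop = FALSE]))
                r2[!upper.tri(r2)] <- NA
                worst <- which(r2 > r2Max, arr.ind = TRUE)
                if (!nrow(worst)) break
                w <- worst[order(-r2[worst]), , drop = FALSE][1L, ]
                i <- win[w[1L]]; j <- win[w[2L]]
                drop <- if (maf[i] < maf[j]) i
                        else if (maf[j] < maf[i]) j
                        else max(i, j)           # tie: later position
                keep[drop] <- FALSE
                win <- win[win != drop]
            }
        }
    }
    which(keep)
}

#' Genomic relationship matrix (VanRaden/GCTA form)
#'
#' Entry (j,k) averages `(x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1-p_i))`
#' over the sites with non-missing calls in both samples; p_i is the
#' cohort ALT frequency. Monomorphic sites are excluded.
#'
#' @param x a [GenotypeData-class] object or dosage matrix.
#' @return symmetric numeric matrix, samples x samples.
#' @export
grMatrix <- function(x) {
    d <- if (is(x, "GenotypeData")) dosage(x) else x
    p <- altFreq(d)
    use <- !is.nan(p) & p > 0 & p < 1
    d <- d[use, , drop = FALSE]; p <- p[use]
    z <- (d - 2 * p) / sqrt(2 * p * (1 - p))
    zz <- z; zz[is.na(zz)] <- 0
    obs <- (!is.na(z)) * 1
    num <- crossprod(zz)
    den <- crossprod(obs)
    g <- num / den
    g[den == 0] <- NA
    g
}

#' Exclude close relatives by GRM threshold
#'
#' For every off-diagonal GRM entry above `maxGrm`, the member of the
#' pair with the higher mean relatedness to all other samples is removed
#' first; the scan is greedy and deterministic. Pairs with no shared
#' sites are skipped with a warning.
#'
#' @param x a [GenotypeData-class] object.
#' @param maxGrm relatedness cutoff (default 0.3).
#' @return list: filtered `gd`, `removed` sample ids, `pairs` data.frame
#'   of the offending pairs, `grm` the full matrix.
#' @export
grmKinshipFilter <- function(x, maxGrm = 0.3) {
    g <- grMatrix(x)
    if (anyNA(g)) {
        warning("sample pairs with no shared sites were skipped")
        g[is.na(g)] <- 0
    }
    ids <- colnames(dosage(x))
    off <- g; diag(off) <- NA
    pairs <- which(off > maxGrm & upper.tri(off), arr.ind = TRUE)
    pairTab <- data.frame(a = ids[pairs[, 1]], b = ids[pairs[, 2]],
                          grm = off[pairs])
    removed <- character()
    active <- rep(TRUE, length(ids))
    repeat {
        cur <- off
        cur[!active, ] <- NA; cur[, !active] <- NA
        bad <- which(cur > maxGrm, arr.ind = TRUE)
        if (!nrow(bad)) break
        cand <- unique(as.vector(bad))
        meanRel <- vapply(cand, function(i)
            mean(cur[i, active & seq_along(active) != i], na.rm = TRUE),
            numeric(1))
        drop <- cand[order(-meanRel, cand)][1L]
        active[drop] <- FALSE
        removed <- c(removed, ids[drop])
    }
    list(gd = x[, active], removed = removed, pairs = pairTab, grm = g)
}
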