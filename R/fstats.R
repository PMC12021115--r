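#' Per-breed allele frequencies from a genotype container
#'
#' @param x a [GenotypeData-class] object.
#' @param by sample-sheet column defining the populations (default
#'   "breed").
#' @return list with `freq` (sites x populations ALT frequencies, NaN
#'   when a population has no call) and `n` (matrix of non-missing
#'   diploid call counts).
#' @export
breedFrequencies <- function(x, by = "breed") {
    pops <- as.character(sampleMeta(x)[[by]])
    d <- dosage(x)
    u <- unique(pops)
    freq <- sapply(u, function(p) altFreq(d[, pops == p, drop = FALSE]))
    n <- sapply(u, function(p)
        rowSums(!is.na(d[, pops == p, drop = FALSE])))
    list(freq = freq, n = n)
}

#' Weighted delete-one block jackknife
#'
#' The statistic is the mean of per-site values; blocks are contiguous
#' genomic chunks of possibly unequal size. Uses the weighted jackknife
#' for unequal block sizes: with g blocks, m_j sites in block j, n total
#' sites, full-sample mean theta and leave-block-out means theta_(-j),
#' pseudovalues tau_j = h_j*theta - (h_j - 1)*theta_(-j) with
#' h_j = n/m_j give
#' `var = (1/g) * sum_j (tau_j - theta_J)^2 / (h_j - 1)` where
#' `theta_J = g*theta - sum_j (1 - m_j/n) * theta_(-j)`.
#'
#' @param values per-site statistic contributions.
#' @param blocks block id per site (any label type).
#' @return list with `est` (overall mean), `se`, `n_blocks`.
#' @export
blockJackknife <- function(values, blocks) {
    ok <- !is.na(values)
    values <- values[ok]; blocks <- blocks[ok]
    bl <- factor(blocks)
    g <- nlevels(bl)
    n <- length(values)
    theta <- mean(values)
    if (g < 2L)
        return(list(est = theta, se = NA_real_, n_blocks = g))
    m <- as.numeric(tabulate(bl))
    sums <- as.numeric(tapply(values, bl, sum))
    thetaMinus <- (sum(values) - sums) / (n - m)
    h <- n / m
    thetaJ <- g * theta - sum((1 - m / n) * thetaMinus)
    tau <- h * theta - (h - 1) * thetaMinus
    v <- mean((tau - thetaJ)^2 / (h - 1))
    list(est = theta, se = sqrt(v), n_blocks = g)
}

#' Assign sites to contiguous physical jackknife blocks
#'
#' @param chrom,pos site coordinates.
#' @param blockSize block width in bp (default 5 Mb).
#' @return character block ids.
#' @export
physicalBlocks <- function(chrom, pos, blockSize = 5e6) {
    paste0(chrom, ":", floor((pos - 1) / blockSize))
}

.fstatCore <- function(prod, blocks, labels) {
    ok <- !is.na(prod)
    if (!sum(ok)) stop("no usable sites for ", paste(labels, collapse = ","))
    jk <- blockJackknife(prod[ok], blocks[ok])
    data.frame(as.list(stats::setNames(as.list(labels),
                                       paste0("pop", seq_along(labels)))),
               est = jk$est, se = jk$se,
               z = if (!is.na(jk$se) && jk$se > 0) jk$est / jk$se
                   else NA_real_,
               n_sites = sum(ok), n_blocks = jk$n_blocks,
               stringsAsFactors = FALSE)
}

#' Outgroup f3 statistic
#'
#' `f3(X, Y; O) = mean over sites of (pX - pO)(pY - pO)`, the shared
#' genetic drift of X and Y relative to the outgroup, with a block-
#' jackknife standard error. Sites lacking a defined frequency in any
#' of the three populations are dropped (complete cases per statistic).
#'
#' @param freq sites x populations frequency matrix.
#' @param X,Y,outgroup column names.
#' @param blocks per-site block ids (see [physicalBlocks()]); a single
#'   value disables the SE.
#' @return one-row data.frame: populations, `est`, `se`, `z`, `n_sites`,
#'   `n_blocks`.
#' @export
outgroupF3 <- function(freq, X, Y, outgroup, blocks) {
    prod <- (freq[, X] - freq[, outgroup]) *
            (freq[, Y] - freq[, outgroup])
    prod[is.nan(prod)] <- NA
    .fstatCore(prod, blocks, c(X, Y, outgroup))
}

#' f4 statistic
#'
#' `f4(P1, P2; P3, O) = mean over sites of (p1 - p2)(p3 - pO)`. Under a
#' tree ((P1,P2),(P3,O)) the expectation is 0; admixture between the
#' pairs drives it away from 0 with a sign given by the direction of
#' gene flow.
#'
#' @param freq sites x populations frequency matrix.
#' @param P1,P2,P3,outgroup column names.
#' @param blocks per-site block ids.
#' @return one-row data.frame as in [outgroupF3()].
#' @export
f4stat <- function(freq, P1, P2, P3, outgroup, blocks) {
    prod <- (freq[, P1] - freq[, P2]) * (freq[, P3] - freq[, outgroup])
    prod[is.nan(prod)] <- NA
    .fstatCore(prod, blocks, c(P1, P2, P3, outgroup))
}

#' Directional f4 breed-distance matrix
#'
#' `disf4(a, b)` averages `f4(a, i; b, outgroup)` over third breeds i.
#' By default i ranges over the included breeds excluding a and b (the
#' i = a term is identically 0 and i = b is self-referential; both only
#' dilute the mean); `includeSelf = TRUE` restores the literal
#' all-breeds sum for sensitivity analysis. Breeds flagged as
#' geographically adjacent to the Yakutian horse are removed up front
#' when `excludeFlagged` names a logical flag vector, mirroring their
#' exclusion from the pony-related network.
#'
#' @param freq sites x populations frequency matrix (outgroup included).
#' @param breeds breed columns to include.
#' @param outgroup outgroup column.
#' @param flagged optional character vector of breeds to drop before
#'   computation (e.g. Yakutia-adjacent ones).
#' @param includeSelf include i in {a,b} in the sum (default FALSE).
#' @return list: `disf4` (directional matrix, rows = a, cols = b), `n`
#'   (matrix of term counts).
#' @export
disf4Matrix <- function(freq, breeds, outgroup, flagged = NULL,
                        includeSelf = FALSE) {
    if (!is.null(flagged)) breeds <- setdiff(breeds, flagged)
    if (length(breeds) < 3L) stop("need at least 3 included breeds")
    k <- length(breeds)
    m <- matrix(NA_real_, k, k, dimnames = list(breeds, breeds))
    nM <- matrix(0L, k, k, dimnames = list(breeds, breeds))
    pO <- freq[, outgroup]
    for (a in breeds) for (b in breeds) {
        if (a == b) { m[a, b] <- 0; next }
        third <- if (includeSelf) breeds else setdiff(breeds, c(a, b))
        if (!length(third)) stop("no third breeds for pair ", a, ",", b)
        vals <- vapply(third, function(i) {
            prod <- (freq[, a] - freq[, i]) * (freq[, b] - pO)
            mean(prod[!is.nan(prod)], na.rm = TRUE)
        }, numeric(1))
        m[a, b] <- sum(vals) / length(third)
        nM[a, b] <- length(third)
    }
    list(disf4 = m, n = nM)
}

#' Symmetrized f4 distance network
#'
#' `disedge(a, b) = (disf4(a, b) + disf4(b, a)) / 2`, the non-directional
#' breed distance. Edges are ranked by strength (larger shared drift =
#' stronger) and binned into quintile classes for rendering; the full
#' edge table is always returned.
#'
#' @param dis result of [disf4Matrix()] (or a square directional matrix).
#' @param nBins number of strength classes (default 5).
#' @return data.frame of edges: `breed_a`, `breed_b`, `disf4_ab`,
#'   `disf4_ba`, `disedge`, `n`, `strength_bin` (`nBins` = strongest,
#'   i.e. largest shared drift).
#' @export
disedgeNetwork <- function(dis, nBins = 5L) {
    m <- if (is.list(dis)) dis$disf4 else dis
    nM <- if (is.list(dis)) dis$n else NULL
    breeds <- rownames(m)
    pairs <- which(upper.tri(m), arr.ind = TRUE)
    out <- data.frame(
        breed_a = breeds[pairs[, 1]], breed_b = breeds[pairs[, 2]],
        disf4_ab = m[pairs], disf4_ba = t(m)[pairs],
        stringsAsFactors = FALSE)
    out$disedge <- (out$disf4_ab + out$disf4_ba) / 2
    out$n <- if (!is.null(nM)) nM[pairs] else NA_integer_
    rk <- rank(out$disedge, ties.method = "first")
    out$strength_bin <- as.integer(ceiling(rk / max(1, nrow(out)) *
                                           nBins))
    out
}
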