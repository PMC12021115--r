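#' Per-sample depth indices for genomic sex assignment
#'
#' From a per-chromosome depth table computes, per sample: the Y covered
#' fraction (`cov_y`), the per-bp depth ratios ChrX/Chr1 and ChrY/Chr1,
#' `Rx` (X per-bp rate over the mean autosomal per-bp rate) and
#' `Ry` (Y reads over X + Y reads). All indices are invariant to a
#' global rescaling of read counts.
#'
#' @param depth data.frame with columns `sample`, `chrom`,
#'   `total_reads`, `covered_bp`, `chrom_len`; chromosomes named "chrX"
#'   and "chrY" are the sex chromosomes, "chr1" anchors the Chr1 ratios,
#'   all non-X/Y chromosomes count as autosomes for Rx.
#' @return data.frame: `sample`, `cov_y`, `x_chr1`, `y_chr1`, `rx`,
#'   `ry`.
#' @export
sexIndices <- function(depth) {
    need <- c("sample", "chrom", "total_reads", "covered_bp",
              "chrom_len")
    stopifnot(all(need %in% names(depth)))
    out <- lapply(split(depth, depth$sample), function(d) {
        rate <- d$total_reads / d$chrom_len
        names(rate) <- d$chrom
        auto <- setdiff(d$chrom, c("chrX", "chrY"))
        if (!all(c("chr1", "chrX", "chrY") %in% d$chrom))
            stop("need chr1, chrX and chrY rows per sample")
        if (sum(d$total_reads[d$chrom %in% auto]) == 0)
            stop("zero autosomal reads for ", d$sample[1])
        readsX <- d$total_reads[d$chrom == "chrX"]
        readsY <- d$total_reads[d$chrom == "chrY"]
        data.frame(
            sample = d$sample[1],
            cov_y = d$covered_bp[d$chrom == "chrY"] /
                d$chrom_len[d$chrom == "chrY"],
            x_chr1 = rate[["chrX"]] / rate[["chr1"]],
            y_chr1 = rate[["chrY"]] / rate[["chr1"]],
            rx = rate[["chrX"]] / mean(rate[auto]),
            ry = readsY / (readsX + readsY),
            stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Call genomic sex from depth indices
#'
#' Primary rule: a Y covered fraction above `covYMale` (default 0.94)
#' calls a male. Corroboration uses Ry (male-consistent at or above
#' 0.075, female-consistent at or below 0.016) and Rx (male-consistent
#' near 0.5, female-consistent near 1.0, within `rxTol`). When the
#' primary call and the corroborating indices disagree the sample is
#' called `ambiguous` with both rules named in the rationale — never
#' the opposite sex. Mismatches against a recorded sex are reported.
#'
#' @param indices data.frame from [sexIndices()].
#' @param recorded optional named character vector of recorded sexes
#'   (names = sample ids) to compare against.
#' @param covYMale Y covered-fraction male threshold (default 0.94).
#' @param ryMale,ryFemale Ry corroboration thresholds (0.075 / 0.016).
#' @param rxMale,rxFemale,rxTol Rx corroboration centers and tolerance
#'   (0.5 / 1.0, tolerance 0.2).
#' @return data.frame: indices plus `call` ("male"/"female"/
#'   "ambiguous"), `rationale`, and `recorded_mismatch` when `recorded`
#'   is given.
#' @export
callSex <- function(indices, recorded = NULL, covYMale = 0.94,
                    ryMale = 0.075, ryFemale = 0.016,
                    rxMale = 0.5, rxFemale = 1.0, rxTol = 0.2) {
    call <- character(nrow(indices))
    why <- character(nrow(indices))
    for (i in seq_len(nrow(indices))) {
        covCallMale <- indices$cov_y[i] > covYMale
        ryOk <- if (covCallMale) indices$ry[i] >= ryMale
                else indices$ry[i] <= ryFemale
        rxOk <- if (covCallMale)
            abs(indices$rx[i] - rxMale) <= rxTol
        else abs(indices$rx[i] - rxFemale) <= rxTol
        if (ryOk && rxOk) {
            call[i] <- if (covCallMale) "male" else "female"
            why[i] <- sprintf("covY %s %.2f; Ry/Rx consistent",
                              if (covCallMale) ">" else "<=", covYMale)
        } else {
            call[i] <- "ambiguous"
            why[i] <- sprintf(
                "covY rule says %s but %s",
                if (covCallMale) "male" else "female",
                paste(c(if (!ryOk) sprintf("Ry=%.3f inconsistent",
                                           indices$ry[i]),
                        if (!rxOk) sprintf("Rx=%.2f inconsistent",
                                           indices$rx[i])),
                      collapse = " and "))
        }
    }
    out <- cbind(indices, call = call, rationale = why,
                 stringsAsFactors = FALSE)
    if (!is.null(recorded)) {
        rec <- recorded[as.character(indices$sample)]
        out$recorded <- unname(rec)
        out$recorded_mismatch <- !is.na(rec) & call != "ambiguous" &
            call != rec
    }
    out
}

#' Filter Y-chromosome genotypes for haplotype analysis
#'
#' The Y is hemizygous in males, so a heterozygous diploid-coded call
#' is a genotyping artifact: any site heterozygous in any male is
#' dropped outright. The survivors then pass sample-missingness
#' (> `maxSampleMissing` removes the sample), variant-missingness
#' (> `maxVariantMissing`) and MAF (< `minMaf`) filters; finally, for
#' haplotype identification, sites with any remaining missing genotype
#' are excluded so the matrix is complete-case.
#'
#' @param x a [GenotypeData-class] restricted to Y-chromosome sites.
#' @param males sample selector (ids) of genomically male samples.
#' @param maxSampleMissing,maxVariantMissing,minMaf thresholds
#'   (defaults 0.0008, 0.02, 0.005).
#' @return list: `gd` the complete-case filtered object, `attrition`
#'   data.frame of per-stage site/sample counts.
#' @export
msyFilter <- function(x, males, maxSampleMissing = 0.0008,
                      maxVariantMissing = 0.02, minMaf = 0.005) {
    x <- x[, males]
    d <- dosage(x)
    stages <- data.frame(stage = "input", n_samples = ncol(d),
                         n_sites = nrow(d))
    het <- rowSums(d == 1L, na.rm = TRUE) > 0
    x <- x[!het, ]
    stages <- rbind(stages, data.frame(stage = "drop_heterozygous",
                                       n_samples = ncol(x),
                                       n_sites = nrow(x)))
    d <- dosage(x)
    keepS <- colMeans(is.na(d)) <= maxSampleMissing
    if (!any(keepS)) stop("all samples removed; attrition: ",
                          paste(stages$n_sites, collapse = "->"))
    x <- x[, keepS]
    stages <- rbind(stages, data.frame(stage = "sample_missingness",
                                       n_samples = ncol(x),
                                       n_sites = nrow(x)))
    d <- dosage(x)
    x <- x[rowMeans(is.na(d)) <= maxVariantMissing, ]
    stages <- rbind(stages, data.frame(stage = "variant_missingness",
                                       n_samples = ncol(x),
                                       n_sites = nrow(x)))
    p <- altFreq(x)
    maf <- pmin(p, 1 - p)
    x <- x[!is.nan(maf) & maf >= minMaf, ]
    stages <- rbind(stages, data.frame(stage = "maf",
                                       n_samples = ncol(x),
                                       n_sites = nrow(x)))
    x <- x[rowSums(is.na(dosage(x))) == 0L, ]
    stages <- rbind(stages, data.frame(stage = "complete_case",
                                       n_samples = ncol(x),
                                       n_sites = nrow(x)))
    if (!nrow(x)) stop("zero sites survive; attrition: ",
                       paste(stages$n_sites, collapse = "->"))
    list(gd = x, attrition = stages)
}

#' Count distinct haplotypes
#'
#' A haplotype is the full allele vector over the retained sites; the
#' count and a sample-to-haplotype membership map are returned. The
#' count is invariant to sample order and to duplicated samples.
#'
#' @param x a complete-case [GenotypeData-class] (one allele per site,
#'   e.g. MSY dosages) or a samples-in-columns matrix.
#' @return list: `n` distinct haplotypes, `membership` data.frame
#'   (`sample`, `haplotype` id in order of first appearance).
#' @export
countHaplotypes <- function(x) {
    m <- if (is(x, "GenotypeData")) dosage(x) else as.matrix(x)
    if (anyNA(m)) stop("matrix must be complete-case")
    key <- apply(m, 2L, paste, collapse = ",")
    hap <- match(key, unique(key))
    list(n = length(unique(key)),
         membership = data.frame(sample = colnames(m) %||%
                                     as.character(seq_along(key)),
                                 haplotype = hap,
                                 stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise P-distance matrix
#'
#' The distance between two samples averages, over the sites non-missing
#' in both, a per-site genotype distance: identical genotypes 0; one
#' shared allele (homozygote vs heterozygote) 0.5; no shared allele
#' (opposite homozygotes) 1. Pairs sharing no sites get NA with a
#' warning.
#'
#' @param x a [GenotypeData-class] object or dosage matrix.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pDistanceMatrix <- function(x) {
    d <- if (is(x, "GenotypeData")) dosage(x) else as.matrix(x)
    n <- ncol(d)
    dist <- matrix(0, n, n, dimnames = list(colnames(d), colnames(d)))
    for (j in seq_len(n - 1L)) for (k in (j + 1L):n) {
        ok <- !is.na(d[, j]) & !is.na(d[, k])
        if (!any(ok)) {
            warning("no shared sites for pair ", j, ",", k)
            dist[j, k] <- dist[k, j] <- NA
            next
        }
        dist[j, k] <- dist[k, j] <- mean(abs(d[ok, j] - d[ok, k]) / 2)
    }
    dist
}

#' Neighbor-joining tree rooted on an outgroup
#'
#' Saitou-Nei neighbor joining on a P-distance (or any) matrix, rooted
#' on the branch leading to the named outgroup tip (or to the most
#' recent common ancestor of several outgroup tips).
#'
#' @param D symmetric distance matrix with taxon dimnames.
#' @param outgroup tip label(s) to root on.
#' @return an `ape::phylo` tree (use `ape::write.tree()` for Newick).
#' @export
njTree <- function(D, outgroup) {
    if (!all(outgroup %in% rownames(D)))
        stop("outgroup label absent from the matrix")
    tr <- ape::nj(stats::as.dist(D))
    ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
}

#' Relative depth of target genes against single-copy genes
#'
#' Scores each target gene's mean per-bp depth against the average
#' per-bp depth over a single-copy gene set: a score near 1 supports
#' single-copy presence, near 0 supports loss, near 0.5 a hemizygous
#' or half-copy state.
#'
#' @param geneDepth data.frame with columns `gene`, `total_reads`,
#'   `length_bp`.
#' @param singleCopy character vector of gene ids forming the
#'   single-copy baseline.
#' @return data.frame `gene`, `relative_depth` for all genes in
#'   `geneDepth`.
#' @export
relativeDepth <- function(geneDepth, singleCopy) {
    stopifnot(all(singleCopy %in% geneDepth$gene))
    rate <- geneDepth$total_reads / geneDepth$length_bp
    base <- mean(rate[geneDepth$gene %in% singleCopy])
    if (base <= 0) stop("zero single-copy depth")
    data.frame(gene = geneDepth$gene, relative_depth = rate / base,
               stringsAsFactors = FALSE)
}
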