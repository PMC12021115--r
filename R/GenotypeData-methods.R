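#' Construct a GenotypeData object
#'
#' Assembles the package's central container from a dosage matrix, a
#' variant GRanges and a sample sheet. Phased haplotype matrices are
#' optional; when supplied their sum must reproduce the dosage.
#'
#' @param dosage integer matrix, sites x samples, values 0/1/2/NA.
#' @param variants `GRanges` of length `nrow(dosage)`; mcols may carry
#'   `ref`, `alt`, `QUAL` and the INFO annotations QD, MQ, FS, SOR,
#'   MQRankSum, ReadPosRankSum.
#' @param samples `data.frame` or `DataFrame` with one row per sample;
#'   a `sample` column (or rownames) gives sample ids.
#' @param hapA,hapB optional 0/1 matrices of per-haplotype ALT alleles.
#' @return A [GenotypeData-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 200), width = 1))
#' d <- matrix(c(0L, 1L, 2L, 1L), 2, 2,
#'             dimnames = list(NULL, c("s1", "s2")))
#' gd <- makeGenotypeData(d, gr, data.frame(sample = c("s1", "s2"),
#'                                          breed = "Debao"))
#' dosage(gd)
#' @export
makeGenotypeData <- function(dosage, variants, samples,
                             hapA = NULL, hapB = NULL) {
    if (!is.matrix(dosage))
        dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "integer"
    if (is.null(colnames(dosage)) && !is.null(samples$sample))
        colnames(dosage) <- as.character(samples$sample)
    cd <- DataFrame(samples)
    if (!is.null(cd$sample)) rownames(cd) <- as.character(cd$sample)
    assays <- list(dosage = dosage)
    if (!is.null(hapA) || !is.null(hapB)) {
        stopifnot(!is.null(hapA), !is.null(hapB))
        storage.mode(hapA) <- "integer"
        storage.mode(hapB) <- "integer"
        dimnames(hapA) <- dimnames(dosage)
        dimnames(hapB) <- dimnames(dosage)
        assays <- c(assays, list(hapA = hapA, hapB = hapB))
    }
    se <- SummarizedExperiment(assays = assays, rowRanges = variants,
                               colData = cd)
    new("GenotypeData", se)
}

#' Accessors for GenotypeData
#'
#' `dosage()` returns the sites x samples diploid dosage matrix,
#' `hapA()`/`hapB()` the phased haplotype matrices (error when unphased),
#' `isPhased()` whether haplotypes are present, and `sampleMeta()` the
#' sample sheet as a `DataFrame`.
#'
#' @param x a [GenotypeData-class] object.
#' @return See the individual descriptions.
#' @name GenotypeData-accessors
NULL

#' @rdname GenotypeData-accessors
#' @export
setMethod("dosage", "GenotypeData", function(x) assay(x, "dosage"))

#' @rdname GenotypeData-accessors
#' @export
setMethod("hapA", "GenotypeData", function(x) {
    if (!isPhased(x)) stop("object is not phased")
    assay(x, "hapA")
})

#' @rdname GenotypeData-accessors
#' @export
setMethod("hapB", "GenotypeData", function(x) {
    if (!isPhased(x)) stop("object is not phased")
    assay(x, "hapB")
})

#' @rdname GenotypeData-accessors
#' @export
setMethod("isPhased", "GenotypeData", function(x)
    all(c("hapA", "hapB") %in% assayNames(x)))

#' @rdname GenotypeData-accessors
#' @export
setMethod("sampleMeta", "GenotypeData", function(x) colData(x))

setMethod("show", "GenotypeData", function(object) {
    cat("GenotypeData:", nrow(object), "sites x", ncol(object),
        "samples;", if (isPhased(object)) "phased" else "unphased", "\n")
    br <- sampleMeta(object)$breed
    if (!is.null(br)) {
        tb <- table(br)
        cat("  breeds:", paste(sprintf("%s(%d)", names(tb), tb),
                               collapse = ", "), "\n")
    }
    sw <- metadata(object)$sweeps
    if (!is.null(sw) && nrow(sw))
        cat("  implanted sweeps:", nrow(sw), "\n")
})

#' Per-site ALT allele frequencies
#'
#' Frequencies are computed from non-missing diploid calls; an optional
#' sample subset restricts the computation (e.g. to one breed).
#'
#' @param x a [GenotypeData-class] object or a dosage matrix.
#' @param samples optional sample ids / indices / logical mask.
#' @return numeric vector of ALT frequencies, `NaN` where no calls.
#' @export
altFreq <- function(x, samples = NULL) {
    d <- if (is(x, "GenotypeData")) dosage(x) else x
    if (!is.null(samples)) d <- d[, samples, drop = FALSE]
    rowSums(d, na.rm = TRUE) / (2 * rowSums(!is.na(d)))
}

#' Build a HaplotypePanel from phased GenotypeData
#'
#' Interleaves each sample's two haplotypes into a haplotypes x sites
#' 0/1 matrix restricted to one chromosome.
#'
#' @param x a phased [GenotypeData-class] object.
#' @param samples sample ids / indices selecting the panel's population.
#' @param chrom chromosome to extract (default: the first one present).
#' @param population label stored on the panel.
#' @return A [HaplotypePanel-class].
#' @export
haplotypePanel <- function(x, samples = NULL, chrom = NULL,
                           population = "pop") {
    stopifnot(is(x, "GenotypeData"), isPhased(x))
    if (is.null(chrom))
        chrom <- as.character(seqnames(x)[1])
    keep <- as.character(seqnames(x)) == chrom
    xx <- x[keep, ]
    if (!is.null(samples)) xx <- xx[, samples]
    ha <- t(hapA(xx)); hb <- t(hapB(xx))
    n <- nrow(ha)
    h <- matrix(0L, 2L * n, ncol(ha))
    h[seq(1L, 2L * n, by = 2L), ] <- ha
    h[seq(2L, 2L * n, by = 2L), ] <- hb
    if (anyNA(h)) stop("panel haplotypes contain missing calls")
    new("HaplotypePanel", haplotypes = h,
        positions = as.numeric(start(xx)), population = population)
}

#' Accessors for HaplotypePanel
#'
#' @param x a [HaplotypePanel-class].
#' @return `haplotypes()` the 0/1 matrix, `positions()` the bp positions,
#'   `population()` the label.
#' @name HaplotypePanel-accessors
NULL

#' @rdname HaplotypePanel-accessors
#' @export
setMethod("haplotypes", "HaplotypePanel", function(x) x@haplotypes)

#' @rdname HaplotypePanel-accessors
#' @export
setMethod("positions", "HaplotypePanel", function(x) x@positions)

#' @rdname HaplotypePanel-accessors
#' @export
setMethod("population", "HaplotypePanel", function(x) x@population)

setMethod("show", "HaplotypePanel", function(object) {
    cat("HaplotypePanel '", object@population, "': ",
        nrow(object@haplotypes), " haplotypes x ",
        ncol(object@haplotypes), " sites\n", sep = "")
})
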