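#' Write a GenotypeData object as VCFv4.2
#'
#' Emits bi-allelic SNPs with GT genotypes (phased `0|1` style when the
#' object carries haplotypes, `0/1` otherwise), QUAL, and the six INFO
#' keys consumed by hard filtering (QD, MQ, FS, SOR, MQRankSum,
#' ReadPosRankSum). Missing calls become `./.`.
#'
#' @param x a [GenotypeData-class] object.
#' @param file output path (plain text).
#' @return `file`, invisibly.
#' @export
writeGenotypeVcf <- function(x, file) {
    mc <- S4Vectors::mcols(rowRanges(x))
    infoKeys <- c("QD", "MQ", "FS", "SOR", "MQRankSum",
                  "ReadPosRankSum")
    hdr <- c("##fileformat=VCFv4.2",
             paste0("##contig=<ID=", unique(as.character(seqnames(x))),
                    ">"),
             vapply(infoKeys, function(k) paste0(
                 "##INFO=<ID=", k,
                 ",Number=1,Type=Float,Description=\"", k, "\">"),
                 character(1)),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT",
                     colnames(dosage(x))), collapse = "\t"))
    fmtNum <- function(v) ifelse(is.na(v), ".",
                                 formatC(v, digits = 6, format = "g"))
    info <- do.call(paste, c(lapply(infoKeys, function(k) {
        v <- if (k %in% names(mc)) mc[[k]] else rep(NA_real_, nrow(x))
        paste0(k, "=", fmtNum(v))
    }), sep = ";"))
    if (isPhased(x)) {
        ha <- assay(x, "hapA"); hb <- assay(x, "hapB")
        gt <- matrix(paste0(ha, "|", hb), nrow(x), ncol(x))
        gt[is.na(ha)] <- ".|."
    } else {
        d <- dosage(x)
        gt <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow(x), ncol(x))
        gt[is.na(d)] <- "./."
    }
    qual <- if ("QUAL" %in% names(mc)) fmtNum(mc$QUAL)
            else rep(".", nrow(x))
    body <- cbind(as.character(seqnames(x)), start(x), ".",
                  if ("ref" %in% names(mc)) as.character(mc$ref) else "A",
                  if ("alt" %in% names(mc)) as.character(mc$alt) else "T",
                  qual, "PASS", info, "GT", gt)
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
    invisible(file)
}

#' Read a VCF into a GenotypeData object
#'
#' Parses a (possibly gzipped) VCF with `vcfR`, keeps bi-allelic SNPs,
#' converts GT fields to dosages (and to haplotype matrices when every
#' genotype is phased) and lifts QUAL plus the hard-filter INFO keys
#' into the variant ranges. Sample metadata may be supplied as a
#' data.frame (keyed by `sample`) or a TSV path.
#'
#' @param file VCF path.
#' @param meta optional sample sheet (data.frame or TSV path with a
#'   `sample` column).
#' @return A [GenotypeData-class] object.
#' @export
readGenotypeVcf <- function(file, meta = NULL) {
    v <- vcfR::read.vcfR(file, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    biallelic <- !grepl(",", fix[, "ALT"]) &
        nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L
    v <- v[biallelic, ]
    fix <- vcfR::getFIX(v)
    gt <- vcfR::extract.gt(v, element = "GT")
    phased <- all(grepl("\\|", gt[!is.na(gt) & gt != "." ]))
    splitGt <- function(which) {
        a <- substr(gt, which, which)
        m <- suppressWarnings(matrix(as.integer(a), nrow(gt), ncol(gt)))
        m
    }
    a1 <- splitGt(1L); a2 <- splitGt(3L)
    dos <- a1 + a2
    dimnames(dos) <- dimnames(gt)
    num <- function(x) suppressWarnings(as.numeric(x))
    getInfo <- function(key) num(vcfR::extract.info(v, element = key))
    gr <- GRanges(fix[, "CHROM"],
                  IRanges(as.integer(fix[, "POS"]), width = 1L),
                  ref = fix[, "REF"], alt = fix[, "ALT"],
                  QUAL = num(fix[, "QUAL"]),
                  QD = getInfo("QD"), MQ = getInfo("MQ"),
                  FS = getInfo("FS"), SOR = getInfo("SOR"),
                  MQRankSum = getInfo("MQRankSum"),
                  ReadPosRankSum = getInfo("ReadPosRankSum"))
    if (is.character(meta)) meta <- readSampleMeta(meta)
    samples <- if (!is.null(meta))
        meta[match(colnames(dos), meta$sample), , drop = FALSE]
    else data.frame(sample = colnames(dos), stringsAsFactors = FALSE)
    if (phased)
        makeGenotypeData(dos, gr, samples, hapA = a1, hapB = a2)
    else
        makeGenotypeData(dos, gr, samples)
}

#' @rdname readSampleMeta
#' @param x data.frame to write.
#' @param file TSV path.
#' @export
writeSampleMeta <- function(x, file) {
    utils::write.table(x, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Read or write the sample-metadata TSV
#'
#' Columns: `sample`, `breed`, `region`, `height_class`, `sex`,
#' `yakutia_adjacent` (logical).
#'
#' @param file TSV path.
#' @return data.frame.
#' @export
readSampleMeta <- function(file) {
    utils::read.delim(file, stringsAsFactors = FALSE)
}

#' @rdname readDepthTable
#' @param x depth data.frame to write.
#' @export
writeDepthTable <- function(x, file) {
    utils::write.table(x, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Read or write the per-chromosome depth TSV
#'
#' Columns: `sample`, `chrom`, `total_reads`, `covered_bp`,
#' `chrom_len`.
#'
#' @param file TSV path.
#' @return data.frame.
#' @export
readDepthTable <- function(file) {
    utils::read.delim(file, stringsAsFactors = FALSE)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param gr `GRanges` (extra mcols become additional columns).
#' @param file BED path.
#' @return `file`, invisibly.
#' @export
writeBed <- function(gr, file) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr))
    mc <- as.data.frame(S4Vectors::mcols(gr))
    if (ncol(mc)) df <- cbind(df, mc)
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(file)
}

#' Read a BED file as GRanges
#'
#' @param file BED path (0-based half-open).
#' @return `GRanges`.
#' @export
readBed <- function(file) {
    df <- utils::read.delim(file, header = FALSE,
                            stringsAsFactors = FALSE)
    GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]))
}
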