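#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width ranges
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges colData
#'   assay assays assayNames "assays<-"
NULL

#' GenotypeData: genotypes, variants and sample metadata in one object
#'
#' `GenotypeData` extends `RangedSummarizedExperiment`. Rows are bi-allelic
#' SNP sites, columns are samples. The `"dosage"` assay holds diploid ALT
#' dosages coded 0/1/2 with `NA` for missing calls; phased objects
#' additionally carry `"hapA"` and `"hapB"` assays of per-haplotype ALT
#' alleles (0/1) whose sum reproduces the dosage. `rowRanges()` stores the
#' site coordinates together with REF/ALT alleles, QUAL and the INFO
#' annotations used by hard filtering (QD, MQ, FS, SOR, MQRankSum,
#' ReadPosRankSum). `colData()` stores the cohort sheet: breed, region,
#' withers-height class, recorded sex and the `yakutia_adjacent` exclusion
#' flag.
#'
#' @slot int_elementMetadata,int_colData,assays inherited from
#'   \linkS4class{RangedSummarizedExperiment}.
#' @seealso [makeGenotypeData()], [dosage()], [hapA()], [isPhased()]
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
    msg <- character()
    an <- assayNames(object)
    if (!("dosage" %in% an))
        msg <- c(msg, "assay 'dosage' is required")
    if ("dosage" %in% an) {
        d <- assay(object, "dosage")
        bad <- d[!is.na(d)]
        if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
            msg <- c(msg, "dosage values must be in {0,1,2,NA}")
    }
    phased <- all(c("hapA", "hapB") %in% an)
    if (xor("hapA" %in% an, "hapB" %in% an))
        msg <- c(msg, "phased objects need both 'hapA' and 'hapB'")
    if (phased) {
        s <- assay(object, "hapA") + assay(object, "hapB")
        d <- assay(object, "dosage")
        ok <- is.na(s) == is.na(d)
        if (!all(ok) || !all(s[!is.na(s)] == d[!is.na(d)]))
            msg <- c(msg, "hapA + hapB must equal dosage at every call")
    }
    if (length(msg)) msg else TRUE
})

#' HaplotypePanel: phased haplotypes for one population
#'
#' A rectangular panel of phased binary haplotypes (rows = haplotypes,
#' two per diploid sample; columns = sites) with strictly increasing
#' physical positions. This is the substrate of the EHH/iHH/XP-EHH
#' machinery.
#'
#' @slot haplotypes integer matrix of 0/1 alleles, haplotypes x sites.
#' @slot positions numeric vector of bp positions, strictly increasing.
#' @slot population single population label.
#' @seealso [haplotypePanel()], [ehhCurve()], [xpehhScores()]
#' @export
setClass("HaplotypePanel",
    slots = c(haplotypes = "matrix", positions = "numeric",
              population = "character"))

setValidity("HaplotypePanel", function(object) {
    h <- object@haplotypes
    msg <- character()
    if (ncol(h) != length(object@positions))
        msg <- c(msg, "ncol(haplotypes) must equal length(positions)")
    if (length(object@positions) > 1L &&
        any(diff(object@positions) <= 0))
        msg <- c(msg, "positions must be strictly increasing")
    if (length(h) && !all(h %in% c(0L, 1L)))
        msg <- c(msg, "haplotype alleles must be 0/1")
    if (length(object@population) != 1L)
        msg <- c(msg, "population must be a single label")
    if (length(msg)) msg else TRUE
})

#' AdmixtureGraph: drift/admixture topology for the simulator
#'
#' Describes the population history the Balding-Nichols simulator walks:
#' a rooted acyclic graph whose drift edges carry an F parameter in [0,1)
#' and whose admixture events mix two parent populations with weight
#' alpha in [0,1]. Ancestral allele frequencies are drawn uniformly on
#' `ancRange`.
#'
#' @slot nodes character vector of population labels.
#' @slot edges data.frame with columns `parent`, `child`, `f`.
#' @slot admixtures data.frame with columns `child`, `parentA`, `parentB`,
#'   `alpha` (possibly zero rows).
#' @slot ancRange numeric length-2 range for ancestral frequencies.
#' @slot nSites integer number of independent sites.
#' @slot seed integer RNG seed.
#' @seealso [admixtureGraph()], [simulateGraphFrequencies()]
#' @export
setClass("AdmixtureGraph",
    slots = c(nodes = "character", edges = "data.frame",
              admixtures = "data.frame", ancRange = "numeric",
              nSites = "integer", seed = "integer"))

setValidity("AdmixtureGraph", function(object) {
    msg <- character()
    ed <- object@edges
    ad <- object@admixtures
    children <- c(as.character(ed$child),
                  if (nrow(ad)) as.character(ad$child))
    parents <- c(as.character(ed$parent),
                 if (nrow(ad)) c(as.character(ad$parentA),
                                 as.character(ad$parentB)))
    if (!all(c(children, parents) %in% object@nodes))
        msg <- c(msg, "edge endpoints must be declared nodes")
    if (anyDuplicated(children))
        msg <- c(msg, "each node may have at most one incoming event")
    roots <- setdiff(object@nodes, children)
    if (length(roots) != 1L)
        msg <- c(msg, "graph must have exactly one root")
    if (nrow(ed) && (any(ed$f < 0) || any(ed$f >= 1)))
        msg <- c(msg, "drift parameters must satisfy 0 <= F < 1")
    if (nrow(ad) && (any(ad$alpha < 0) || any(ad$alpha > 1)))
        msg <- c(msg, "admixture weights must lie in [0,1]")
    if (length(object@ancRange) != 2L ||
        object@ancRange[1] >= object@ancRange[2] ||
        object@ancRange[1] < 0 || object@ancRange[2] > 1)
        msg <- c(msg, "ancRange must be an increasing pair inside [0,1]")
    if (object@nSites < 1L) msg <- c(msg, "nSites must be positive")
    # acyclicity: peel nodes with no unresolved parents
    if (!length(msg)) {
        resolved <- roots
        pending <- setdiff(object@nodes, resolved)
        repeat {
            par_of <- function(x) {
                p <- as.character(ed$parent[ed$child == x])
                if (nrow(ad) && x %in% ad$child) {
                    i <- match(x, ad$child)
                    p <- c(as.character(ad$parentA[i]),
                           as.character(ad$parentB[i]))
                }
                p
            }
            ready <- pending[vapply(pending, function(x)
                all(par_of(x) %in% resolved), logical(1))]
            if (!length(ready)) break
            resolved <- c(resolved, ready)
            pending <- setdiff(pending, ready)
        }
        if (length(pending))
            msg <- c(msg, paste("graph contains a cycle involving:",
                                paste(pending, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' SweepSpec: where and how hard to implant a selective sweep
#'
#' @slot population target population label (carriers are drawn here).
#' @slot chrom chromosome name.
#' @slot start,end 0-based half-open sweep interval in bp.
#' @slot carrierFreq fraction of target haplotypes carrying the shared
#'   core haplotype, in (0,1].
#' @slot seed integer RNG seed.
#' @seealso [sweepSpec()], [implantSweep()]
#' @export
setClass("SweepSpec",
    slots = c(population = "character", chrom = "character",
              start = "numeric", end = "numeric",
              carrierFreq = "numeric", seed = "integer"))

setValidity("SweepSpec", function(object) {
    msg <- character()
    if (object@end <= object@start)
        msg <- c(msg, "end must exceed start")
    if (object@carrierFreq <= 0 || object@carrierFreq > 1)
        msg <- c(msg, "carrierFreq must lie in (0,1]")
    if (length(msg)) msg else TRUE
})

#' DepthProfile: sex-specific sequencing-depth generator settings
#'
#' @slot sex "male" or "female".
#' @slot meanDepth mean autosomal depth in read-bases per bp.
#' @slot chromLens named numeric vector of chromosome lengths (bp); names
#'   "chrX"/"chrY" mark the sex chromosomes, everything else is autosomal.
#' @slot overdispersion gamma-Poisson overdispersion of per-chromosome
#'   read counts (coefficient of variation of the latent rate).
#' @slot yResidual residual Y mismapping rate for females, as a fraction
#'   of the autosomal per-bp rate.
#' @slot seed integer RNG seed.
#' @seealso [depthProfile()], [simulateDepthTable()]
#' @export
setClass("DepthProfile",
    slots = c(sex = "character", meanDepth = "numeric",
              chromLens = "numeric", overdispersion = "numeric",
              yResidual = "numeric", seed = "integer"))

setValidity("DepthProfile", function(object) {
    msg <- character()
    if (!object@sex %in% c("male", "female"))
        msg <- c(msg, "sex must be 'male' or 'female'")
    if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be > 0")
    if (any(object@chromLens <= 0) || is.null(names(object@chromLens)))
        msg <- c(msg, "chromLens must be a named vector of positive lengths")
    if (object@yResidual < 0 || object@yResidual > 1)
        msg <- c(msg, "yResidual must lie in [0,1]")
    if (length(msg)) msg else TRUE
})
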