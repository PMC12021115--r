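#' Specify an admixture graph for the Balding-Nichols simulator
#'
#' Drift along each edge is modelled with the Balding-Nichols Beta
#' parameterization: a child frequency is drawn with mean equal to the
#' parent frequency p and variance F * p * (1 - p). An admixed node's
#' frequency is the deterministic mixture alpha * parentA + (1 - alpha)
#' * parentB. This gives closed-form expectations for f2/f3/f4 in terms
#' of shared drift paths, which the test suite exploits.
#'
#' @param nodes character vector of population labels.
#' @param edges data.frame with columns `parent`, `child`, `f` (drift, in
#'   [0,1); `f = 0` copies the parent exactly).
#' @param admixtures optional data.frame with columns `child`, `parentA`,
#'   `parentB`, `alpha`.
#' @param ancRange range of the uniform ancestral frequency draw.
#' @param nSites number of independent sites.
#' @param seed integer RNG seed (mandatory; the generator is reproducible).
#' @return An [AdmixtureGraph-class].
#' @examples
#' g <- admixtureGraph(
#'   nodes = c("anc", "pony", "horse"),
#'   edges = data.frame(parent = "anc", child = c("pony", "horse"),
#'                      f = 0.1),
#'   nSites = 1000, seed = 1)
#' f <- simulateGraphFrequencies(g)
#' colMeans(f)
#' @export
admixtureGraph <- function(nodes, edges,
                           admixtures = data.frame(child = character(),
                                                   parentA = character(),
                                                   parentB = character(),
                                                   alpha = numeric()),
                           ancRange = c(0.05, 0.95),
                           nSites = 10000L, seed) {
    if (missing(seed)) stop("a seed is mandatory")
    new("AdmixtureGraph", nodes = nodes, edges = edges,
        admixtures = admixtures, ancRange = as.numeric(ancRange),
        nSites = as.integer(nSites), seed = as.integer(seed))
}

#' @rdname implantSweep
#' @param population target population label.
#' @param chrom chromosome name.
#' @param start,end sweep interval, 0-based half-open, bp.
#' @param carrierFreq fraction of target haplotypes carrying the core
#'   haplotype, in (0,1].
#' @param seed integer RNG seed.
#' @export
sweepSpec <- function(population, chrom, start, end, carrierFreq,
                      seed) {
    new("SweepSpec", population = population, chrom = chrom,
        start = as.numeric(start), end = as.numeric(end),
        carrierFreq = carrierFreq, seed = as.integer(seed))
}

#' @rdname simulateDepthTable
#' @param sex "male" or "female".
#' @param meanDepth mean autosomal depth (read-bases per bp).
#' @param chromLens named vector of chromosome lengths in bp; "chrX" and
#'   "chrY" are recognized as the sex chromosomes.
#' @param overdispersion CV of the latent per-chromosome rate (gamma
#'   mixing); 0 gives pure Poisson counts.
#' @param yResidual female residual Y mismapping rate as a fraction of
#'   the autosomal rate (default 0.5%).
#' @param seed integer RNG seed.
#' @export
depthProfile <- function(sex, meanDepth = 10,
                         chromLens = c(chr1 = 5e6, chr2 = 5e6,
                                       chrX = 3e6, chrY = 1e6),
                         overdispersion = 0.05, yResidual = 0.005,
                         seed) {
    new("DepthProfile", sex = sex, meanDepth = meanDepth,
        chromLens = chromLens, overdispersion = overdispersion,
        yResidual = yResidual, seed = as.integer(seed))
}

topoOrder <- function(graph) {
    ed <- graph@edges; ad <- graph@admixtures
    parents_of <- function(x) {
        if (x %in% ed$child)
            return(as.character(ed$parent[ed$child == x]))
        if (nrow(ad) && x %in% ad$child) {
            i <- match(x, ad$child)
            return(c(as.character(ad$parentA[i]),
                     as.character(ad$parentB[i])))
        }
        character()
    }
    ord <- character()
    pending <- graph@nodes
    while (length(pending)) {
        ready <- pending[vapply(pending, function(x)
            all(parents_of(x) %in% ord), logical(1))]
        ord <- c(ord, ready)
        pending <- setdiff(pending, ready)
    }
    ord
}

#' Draw per-population allele frequencies along an admixture graph
#'
#' Walks the graph in topological order. For a drift edge with parameter
#' F > 0 the child frequency is Beta with mean p and variance F*p*(1-p),
#' i.e. shape parameters p*(1-F)/F and (1-p)*(1-F)/F; F = 0 copies the
#' parent. Admixed children mix their parents deterministically. Sites
#' fixed at 0 or 1 in the parent stay fixed. Frequencies are clipped
#' (not reflected) into [0,1].
#'
#' @param graph an [AdmixtureGraph-class].
#' @return numeric matrix, `nSites` x populations (all graph nodes,
#'   root included).
#' @export
simulateGraphFrequencies <- function(graph) {
    stopifnot(is(graph, "AdmixtureGraph"))
    validObject(graph)
    ord <- topoOrder(graph)
    n <- graph@nSites
    freq <- matrix(NA_real_, n, length(graph@nodes),
                   dimnames = list(NULL, graph@nodes))
    ed <- graph@edges; ad <- graph@admixtures
    withr_seed <- graph@seed
    old <- .saveRNGState()
    on.exit(.restoreRNGState(old))
    set.seed(withr_seed)
    root <- setdiff(graph@nodes,
                    c(as.character(ed$child),
                      if (nrow(ad)) as.character(ad$child)))
    freq[, root] <- runif(n, graph@ancRange[1], graph@ancRange[2])
    for (node in setdiff(ord, root)) {
        if (nrow(ad) && node %in% ad$child) {
            i <- match(node, ad$child)
            freq[, node] <- ad$alpha[i] * freq[, as.character(ad$parentA[i])] +
                (1 - ad$alpha[i]) * freq[, as.character(ad$parentB[i])]
        } else {
            i <- match(node, ed$child)
            p <- freq[, as.character(ed$parent[i])]
            f <- ed$f[i]
            if (f == 0) {
                freq[, node] <- p
            } else {
                k <- (1 - f) / f
                q <- ifelse(p <= 0 | p >= 1, p,
                            rbeta(n, p * k, (1 - p) * k))
                freq[, node] <- pmin(pmax(q, 0), 1)
            }
        }
    }
    freq
}

.saveRNGState <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
}
.restoreRNGState <- function(old) {
    if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv())
}

# pass/fail INFO mixtures: passing sites draw comfortably inside the
# hard-filter envelope, failing sites violate one or more clauses
.drawInfo <- function(nSites, failFrac) {
    fail <- runif(nSites) < failFrac
    info <- data.frame(
        QD = runif(nSites, 10, 35),
        MQ = runif(nSites, 55, 60),
        FS = runif(nSites, 0, 10),
        SOR = runif(nSites, 0.5, 2),
        MQRankSum = rnorm(nSites, 0, 1),
        ReadPosRankSum = rnorm(nSites, 0, 1),
        QUAL = runif(nSites, 100, 2000))
    nf <- sum(fail)
    if (nf) {
        which_clause <- sample(7L, nf, replace = TRUE)
        idx <- which(fail)
        info$QD[idx[which_clause == 1L]] <- runif(sum(which_clause == 1L), 0, 1.9)
        info$MQ[idx[which_clause == 2L]] <- runif(sum(which_clause == 2L), 20, 49)
        info$FS[idx[which_clause == 3L]] <- runif(sum(which_clause == 3L), 61, 200)
        info$SOR[idx[which_clause == 4L]] <- runif(sum(which_clause == 4L), 3.1, 8)
        info$MQRankSum[idx[which_clause == 5L]] <- runif(sum(which_clause == 5L), -12, -5.1)
        info$ReadPosRankSum[idx[which_clause == 6L]] <- runif(sum(which_clause == 6L), -12, -5.1)
        info$QUAL[idx[which_clause == 7L]] <- runif(sum(which_clause == 7L), 1, 29)
    }
    info
}

#' Simulate a genotyped cohort from per-population frequencies
#'
#' Haplotype alleles are drawn independently per site with the source
#' population's frequency; diploid dosage is the haplotype-pair sum.
#' Site positions are uniform draws on one chromosome, sorted and made
#' unique; VCF-style QUAL/INFO annotations are drawn from configurable
#' pass/fail mixtures so hard-filter code sees both classes.
#'
#' @param freqs matrix of allele frequencies, sites x populations (as
#'   from [simulateGraphFrequencies()]).
#' @param nPerPop named integer vector: diploid sample count per
#'   population (names must match `freqs` columns).
#' @param phased keep per-haplotype alleles (default TRUE).
#' @param seed integer RNG seed.
#' @param chrom chromosome name for all sites.
#' @param chromLen chromosome length in bp.
#' @param missingRate per-call missing-data rate (default 0).
#' @param infoFailFrac fraction of sites drawn from the hard-filter
#'   failing mixture.
#' @param meta optional data.frame keyed by population with extra sample
#'   annotation columns (breed, region, height_class, sex,
#'   yakutia_adjacent); defaults set breed = population.
#' @return A phased [GenotypeData-class]; `metadata()$chromLen` records
#'   the simulated chromosome length.
#' @export
simulateGenotypes <- function(freqs, nPerPop, phased = TRUE, seed,
                              chrom = "chr1", chromLen = 2e6,
                              missingRate = 0, infoFailFrac = 0,
                              meta = NULL) {
    stopifnot(all(nPerPop > 0), all(names(nPerPop) %in% colnames(freqs)),
              all(freqs >= 0 & freqs <= 1))
    old <- .saveRNGState()
    on.exit(.restoreRNGState(old))
    set.seed(seed)
    m <- nrow(freqs)
    pos <- sort(sample.int(chromLen - 1L, m)) # 1-based, unique
    nTot <- sum(nPerPop)
    ha <- matrix(0L, m, nTot)
    hb <- matrix(0L, m, nTot)
    pops <- rep(names(nPerPop), nPerPop)
    col <- 0L
    for (p in names(nPerPop)) {
        fp <- freqs[, p]
        for (j in seq_len(nPerPop[[p]])) {
            col <- col + 1L
            ha[, col] <- as.integer(runif(m) < fp)
            hb[, col] <- as.integer(runif(m) < fp)
        }
    }
    dos <- ha + hb
    if (missingRate > 0) {
        miss <- matrix(runif(m * nTot) < missingRate, m, nTot)
        dos[miss] <- NA_integer_
        ha[miss] <- NA_integer_
        hb[miss] <- NA_integer_
    }
    ids <- sprintf("%s_%02d", pops, unlist(lapply(nPerPop, seq_len)))
    colnames(dos) <- ids
    info <- .drawInfo(m, infoFailFrac)
    alleles <- matrix(sample(c("A", "C", "G", "T"), 2L * m, replace = TRUE),
                      m, 2L)
    same <- alleles[, 1] == alleles[, 2]
    alleles[same, 2] <- chartr("ACGT", "CGTA", alleles[same, 1])
    gr <- GRanges(chrom, IRanges(pos, width = 1L),
                  ref = alleles[, 1], alt = alleles[, 2],
                  QUAL = info$QUAL, QD = info$QD, MQ = info$MQ,
                  FS = info$FS, SOR = info$SOR,
                  MQRankSum = info$MQRankSum,
                  ReadPosRankSum = info$ReadPosRankSum)
    samples <- data.frame(sample = ids, breed = pops, region = NA_character_,
                          height_class = NA_character_, sex = NA_character_,
                          yakutia_adjacent = FALSE,
                          stringsAsFactors = FALSE)
    if (!is.null(meta)) {
        for (colname in setdiff(names(meta), "population")) {
            samples[[colname]] <-
                meta[[colname]][match(pops, meta$population)]
        }
    }
    gd <- if (phased)
        makeGenotypeData(dos, gr, samples, hapA = ha, hapB = hb)
    else
        makeGenotypeData(dos, gr, samples)
    metadata(gd)$chromLen <- chromLen
    gd
}

#' Implant a hard selective sweep into phased haplotypes
#'
#' A fraction `carrierFreq` of the target population's haplotypes have
#' their alleles inside the sweep interval replaced by one shared core
#' haplotype (the interval alleles of the first selected carrier). This
#' produces the three signal classes a multi-metric scan intersects:
#' reduced nucleotide diversity, elevated FST against other populations,
#' and extended haplotype homozygosity around the interval center.
#' Non-target populations are untouched.
#'
#' @param x a phased [GenotypeData-class] with a `breed` column.
#' @param spec a [SweepSpec-class] (see `sweepSpec()`).
#' @return The modified object; `metadata()$sweeps` accumulates the truth
#'   intervals.
#' @export
implantSweep <- function(x, spec) {
    stopifnot(is(x, "GenotypeData"), isPhased(x), is(spec, "SweepSpec"))
    validObject(spec)
    chromLen <- metadata(x)$chromLen
    if (!is.null(chromLen) && spec@end > chromLen)
        stop("sweep interval outside simulated coordinates")
    inReg <- as.character(seqnames(x)) == spec@chrom &
        start(x) > spec@start & start(x) <= spec@end
    if (!any(inReg)) stop("no sites in sweep interval")
    target <- which(sampleMeta(x)$breed == spec@population)
    if (!length(target)) stop("target population absent")
    ha <- assay(x, "hapA"); hb <- assay(x, "hapB")
    # haplotype slots: 2 per sample, interleaved
    hapIds <- rbind(target * 2L - 1L, target * 2L)[seq_len(2 * length(target))]
    old <- .saveRNGState()
    on.exit(.restoreRNGState(old))
    set.seed(spec@seed)
    nCarry <- max(1L, round(spec@carrierFreq * length(hapIds)))
    carriers <- sample(hapIds, nCarry)
    getHap <- function(slot) {
        s <- (slot + 1L) %/% 2L
        if (slot %% 2L == 1L) ha[inReg, s] else hb[inReg, s]
    }
    core <- getHap(carriers[1L])
    for (slot in carriers) {
        s <- (slot + 1L) %/% 2L
        if (slot %% 2L == 1L) ha[inReg, s] <- core else hb[inReg, s] <- core
    }
    dos <- ha + hb
    dimnames(dos) <- dimnames(dosage(x))
    assays(x)$hapA <- ha
    assays(x)$hapB <- hb
    assays(x)$dosage <- dos
    truth <- data.frame(chrom = spec@chrom, start = spec@start,
                        end = spec@end, population = spec@population,
                        carrierFreq = spec@carrierFreq)
    metadata(x)$sweeps <- rbind(metadata(x)$sweeps, truth)
    validObject(x)
    x
}

#' Simulate per-chromosome read-depth summaries for one individual
#'
#' Emulates sex-specific coverage: males carry one X and one Y, so their
#' per-bp rates on chrX and chrY are half the autosomal rate and the Y is
#' near-fully covered; females have a full-rate X and only residual
#' mismapped Y reads. Per-chromosome counts are gamma-Poisson
#' overdispersed; the covered fraction follows the Poisson coverage law
#' 1 - exp(-depth).
#'
#' @param spec a [DepthProfile-class] (see `depthProfile()`).
#' @param sample sample id recorded in the table.
#' @return data.frame with columns `sample`, `chrom`, `total_reads`
#'   (read-bases), `covered_bp`, `chrom_len`.
#' @export
simulateDepthTable <- function(spec, sample = "s1") {
    stopifnot(is(spec, "DepthProfile"))
    validObject(spec)
    old <- .saveRNGState()
    on.exit(.restoreRNGState(old))
    set.seed(spec@seed)
    lens <- spec@chromLens
    rate <- rep(spec@meanDepth, length(lens))
    names(rate) <- names(lens)
    if (spec@sex == "male") {
        if ("chrX" %in% names(rate)) rate["chrX"] <- spec@meanDepth / 2
        if ("chrY" %in% names(rate)) rate["chrY"] <- spec@meanDepth / 2
    } else {
        if ("chrY" %in% names(rate))
            rate["chrY"] <- spec@meanDepth * spec@yResidual
    }
    mu <- rate * lens
    cv <- spec@overdispersion
    lam <- if (cv > 0)
        mu * rgamma(length(mu), shape = 1 / cv^2, rate = 1 / cv^2)
    else mu
    reads <- rpois(length(lam), lam)
    depth <- reads / lens
    covered <- rbinom(length(lens), size = as.integer(lens),
                      prob = 1 - exp(-depth)) # Poisson coverage law
    data.frame(sample = sample, chrom = names(lens),
               total_reads = reads, covered_bp = covered,
               chrom_len = unname(lens), row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Simulate a mixed-sex cohort of depth tables
#'
#' Convenience wrapper around [simulateDepthTable()]: one row-block per
#' individual, sexes as given, per-individual seeds derived from `seed`.
#'
#' @param sexes character vector of "male"/"female" per individual.
#' @param meanDepth,chromLens,overdispersion,yResidual passed to
#'   [depthProfile()].
#' @param seed integer base seed.
#' @return list with `depth` (stacked data.frame) and `truth`
#'   (data.frame sample/sex).
#' @export
simulateDepthCohort <- function(sexes, meanDepth = 10,
                                chromLens = c(chr1 = 5e6, chr2 = 5e6,
                                              chrX = 3e6, chrY = 1e6),
                                overdispersion = 0.05,
                                yResidual = 0.005, seed) {
    ids <- sprintf("ind_%03d", seq_along(sexes))
    tabs <- lapply(seq_along(sexes), function(i) {
        sp <- depthProfile(sexes[i], meanDepth = meanDepth,
                           chromLens = chromLens,
                           overdispersion = overdispersion,
                           yResidual = yResidual,
                           seed = seed + i)
        simulateDepthTable(sp, sample = ids[i])
    })
    list(depth = do.call(rbind, tabs),
         truth = data.frame(sample = ids, sex = sexes,
                            stringsAsFactors = FALSE))
}

#' Default seeded sweep-scan fixture
#'
#' The package's reference study conditions for end-to-end scan tests:
#' a pony/horse split with Balding-Nichols drift F = 0.1 per branch,
#' 2,000 SNPs on a 2-Mb chromosome, 25 + 25 diploids (50 haplotypes per
#' group), and a hard sweep private to the pony group implanted at 90%
#' carrier frequency over a 20-kb interval spanning two 10-kb windows
#' at the chromosome midpoint.
#'
#' @param seed integer seed; every stochastic stage derives from it.
#' @param nSites,chromLen,nPerPop,f,carrierFreq,sweepStart,sweepEnd
#'   the study conditions, overridable.
#' @return list: `gd` (phased [GenotypeData-class] with the sweep),
#'   `truth` (`GRanges` of the implanted interval), `windows`
#'   (10-kb tiling), `chromLen`.
#' @export
sweepScanFixture <- function(seed, nSites = 2000L, chromLen = 2e6,
                             nPerPop = c(pony = 25L, horse = 25L),
                             f = 0.1, carrierFreq = 0.9,
                             sweepStart = 1.0e6, sweepEnd = 1.02e6) {
    g <- admixtureGraph(
        nodes = c("anc", names(nPerPop)),
        edges = data.frame(parent = "anc", child = names(nPerPop),
                           f = f),
        nSites = nSites, seed = seed)
    fr <- simulateGraphFrequencies(g)
    gd <- simulateGenotypes(fr, nPerPop, seed = seed + 1000L,
                            chromLen = chromLen)
    gd <- implantSweep(gd, sweepSpec(names(nPerPop)[1], "chr1",
                                     sweepStart, sweepEnd,
                                     carrierFreq, seed = seed + 2000L))
    list(gd = gd,
         truth = GRanges("chr1", IRanges(sweepStart + 1, sweepEnd)),
         windows = tileWindows(stats::setNames(chromLen, "chr1")),
         chromLen = chromLen)
}

#' Simulate a cohort from a YAML configuration
#'
#' The configuration mirrors the constructor arguments: top-level keys
#' `nodes`, `edges` (list of parent/child/f), optional `admixtures`,
#' `n_sites`, `seed` (mandatory), `n_per_pop` (map), optional `chrom`,
#' `chrom_len`, `missing_rate`, `info_fail_frac`, and an optional
#' `sweep` block (population/chrom/start/end/carrier_freq/seed).
#'
#' @param file YAML path.
#' @return A phased [GenotypeData-class] object.
#' @export
simulateFromConfig <- function(file) {
    if (!requireNamespace("yaml", quietly = TRUE))
        stop("the yaml package is required for config input")
    cfg <- yaml::read_yaml(file)
    if (is.null(cfg$seed)) stop("config must set a seed")
    ed <- do.call(rbind, lapply(cfg$edges, as.data.frame))
    ad <- if (!is.null(cfg$admixtures))
        do.call(rbind, lapply(cfg$admixtures, as.data.frame))
    else data.frame(child = character(), parentA = character(),
                    parentB = character(), alpha = numeric())
    g <- admixtureGraph(nodes = unlist(cfg$nodes), edges = ed,
                        admixtures = ad,
                        nSites = cfg$n_sites %||% 10000L,
                        seed = cfg$seed)
    fr <- simulateGraphFrequencies(g)
    gd <- simulateGenotypes(
        fr, unlist(cfg$n_per_pop), seed = cfg$seed + 1L,
        chrom = cfg$chrom %||% "chr1",
        chromLen = cfg$chrom_len %||% 2e6,
        missingRate = cfg$missing_rate %||% 0,
        infoFailFrac = cfg$info_fail_frac %||% 0)
    if (!is.null(cfg$sweep)) {
        sw <- cfg$sweep
        gd <- implantSweep(gd, sweepSpec(sw$population, sw$chrom %||%
                                             "chr1", sw$start, sw$end,
                                         sw$carrier_freq,
                                         seed = sw$seed %||%
                                             (cfg$seed + 2L)))
    }
    gd
}
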