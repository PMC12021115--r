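makeDepth <- function(sample, reads, covered = NULL,
                      lens = c(chr1 = 1e6, chr2 = 1e6, chrX = 5e5,
                               chrY = 2e5)) {
    if (is.null(covered)) covered <- pmin(lens, reads)
    data.frame(sample = sample, chrom = names(lens),
               total_reads = unname(reads),
               covered_bp = unname(covered),
               chrom_len = unname(lens), stringsAsFactors = FALSE)
}

test_that("depth indices are scale-invariant and sex-separating", {
    lens <- c(chr1 = 1e6, chr2 = 1e6, chrX = 5e5, chrY = 2e5)
    male <- makeDepth("m", c(chr1 = 1e7, chr2 = 1e7, chrX = 2.5e6,
                             chrY = 1e6),
                      covered = c(1e6, 1e6, 5e5, 1.98e5), lens)
    fem <- makeDepth("f", c(chr1 = 1e7, chr2 = 1e7, chrX = 5e6,
                            chrY = 0),
                     covered = c(1e6, 1e6, 5e5, 0), lens)
    im <- sexIndices(male)
    expect_equal(im$y_chr1, 0.5)
    expect_equal(im$rx, 0.5)
    expect_equal(im$ry, 1e6 / 3.5e6)
    if_ <- sexIndices(fem)
    expect_equal(if_$ry, 0)
    expect_equal(if_$cov_y, 0)
    expect_equal(if_$rx, 1)
    # multiplying every read count by 10 changes nothing
    male10 <- male; male10$total_reads <- male10$total_reads * 10
    expect_equal(sexIndices(male10)[-1], im[-1])
})

test_that("sex calls follow the covY rule with Rx/Ry corroboration", {
    idx <- data.frame(sample = c("a", "b", "c"),
                      cov_y = c(0.99, 0.01, 0.99),
                      x_chr1 = c(0.5, 1, 0.5),
                      y_chr1 = c(0.5, 0.001, 0.5),
                      rx = c(0.51, 0.98, 0.5),
                      ry = c(0.2, 0.001, 0.001))
    calls <- callSex(idx)
    expect_equal(calls$call, c("male", "female", "ambiguous"))
    # the conflicted sample names both rules in its rationale
    expect_match(calls$rationale[3], "covY rule says male")
    expect_match(calls$rationale[3], "Ry")
    # recorded-sex mismatches are reported
    calls2 <- callSex(idx, recorded = c(a = "female", b = "female",
                                        c = "male"))
    expect_true(calls2$recorded_mismatch[1])
    expect_false(calls2$recorded_mismatch[2])
    expect_false(calls2$recorded_mismatch[3])  # ambiguous never flips
})

test_that("simulated cohorts are sexed perfectly at depth and safely below", {
    co <- simulateDepthCohort(rep(c("male", "female"), 50),
                              meanDepth = 10, seed = 601)
    calls <- callSex(sexIndices(co$depth))
    expect_equal(unname(calls$call[match(co$truth$sample,
                                         calls$sample)]),
                 co$truth$sex)
    # far below 1x: calls may go ambiguous but never to the wrong sex
    lo <- simulateDepthCohort(rep(c("male", "female"), 25),
                              meanDepth = 0.3, seed = 602)
    callsLo <- callSex(sexIndices(lo$depth))
    truth <- lo$truth$sex[match(callsLo$sample, lo$truth$sample)]
    wrong <- callsLo$call != "ambiguous" & callsLo$call != truth
    expect_equal(sum(wrong), 0L)
})

test_that("MSY filtering attrition matches the constructed fixture", {
    # 10 sites x 4 males; planned attrition 10 -> 7 -> 7 -> 6 -> 5 -> 5
    d <- matrix(0L, 10, 4, dimnames = list(NULL, paste0("m", 1:4)))
    d[2, ] <- c(2L, 2L, 2L, 2L)
    d[3, 2] <- 1L                      # het in one male: dropped
    d[4, ] <- c(1L, 1L, 0L, 0L)        # het sites: dropped
    d[5, 3] <- 1L                      # het: dropped
    d[6, 1] <- NA                      # 25% missing > 2%: dropped
    d[7, ] <- c(2L, 0L, 0L, 0L)        # MAF 0.25: kept
    d[8, ] <- c(2L, 2L, 0L, 0L)
    gd <- toyGenotypes(d, chrom = "chrY")
    r <- msyFilter(gd, paste0("m", 1:4), maxSampleMissing = 0.5,
                   minMaf = 0.2)
    expect_equal(r$attrition$n_sites, c(10L, 7L, 7L, 6L, 2L, 2L))
    expect_equal(r$attrition$stage,
                 c("input", "drop_heterozygous", "sample_missingness",
                   "variant_missingness", "maf", "complete_case"))
    expect_equal(nrow(r$gd), 2L)
})

test_that("haplotype counting equals the distinct-row-string oracle", {
    m <- cbind(a = c(0, 0), b = c(0, 0), c = c(0, 2), d = c(2, 0),
               e = c(0, 2))
    r <- countHaplotypes(m)
    expect_equal(r$n, 3L)
    expect_equal(r$membership$haplotype, c(1, 1, 2, 3, 2))
    # duplicates never change the count; order never changes it
    expect_equal(countHaplotypes(cbind(m, f = m[, "c"]))$n, 3L)
    expect_equal(countHaplotypes(m[, 5:1])$n, 3L)
    set.seed(603)
    mm <- matrix(sample(c(0, 2), 8 * 20, replace = TRUE), 8, 20)
    colnames(mm) <- paste0("s", 1:20)
    expect_equal(countHaplotypes(mm)$n,
                 length(unique(apply(mm, 2, paste, collapse = ""))))
})

test_that("P-distance follows the shared-allele scoring", {
    d <- cbind(s1 = c(0L, 0L, 2L, 1L), s2 = c(0L, 2L, 2L, 1L))
    pd <- pDistanceMatrix(d)
    expect_equal(pd["s1", "s2"], 0.25)
    expect_equal(pd, t(pd))
    expect_true(all(diag(pd) == 0))
    expect_equal(pDistanceMatrix(cbind(a = c(0L, 1L),
                                       b = c(0L, 1L)))["a", "b"], 0)
})

test_that("neighbor joining recovers additive trees exactly", {
    # 4-taxon additive matrix from a hand-drawn tree:
    # ((A:1,B:2):1.5,(C:1,D:3):0.5) unrooted
    D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    D["A", "B"] <- D["B", "A"] <- 3
    D["A", "C"] <- D["C", "A"] <- 1 + 1.5 + 0.5 + 1
    D["A", "D"] <- D["D", "A"] <- 1 + 1.5 + 0.5 + 3
    D["B", "C"] <- D["C", "B"] <- 2 + 1.5 + 0.5 + 1
    D["B", "D"] <- D["D", "B"] <- 2 + 1.5 + 0.5 + 3
    D["C", "D"] <- D["D", "C"] <- 4
    tr <- njTree(D, "D")
    expect_s3_class(tr, "phylo")
    expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(D),
                                                      colnames(D)],
                 D, tolerance = 1e-12)
    # battery: random additive trees with up to 8 leaves
    set.seed(604)
    for (n in 4:8) for (rep in 1:5) {
        t0 <- ape::rtree(n)
        DD <- as.matrix(ape::cophenetic.phylo(t0))
        tr2 <- njTree(DD, t0$tip.label[1])
        expect_equal(as.matrix(
            ape::cophenetic.phylo(tr2))[rownames(DD), colnames(DD)],
            DD, tolerance = 1e-8)
        expect_equal(ape::dist.topo(ape::unroot(tr2),
                                    ape::unroot(t0)), 0,
                     ignore_attr = TRUE)
    }
    expect_error(njTree(D, "Z"), "outgroup")
})

test_that("relative depth scores gene presence against single-copy genes", {
    gdep <- data.frame(gene = c("sc1", "sc2", "sc3", "lost", "half"),
                       total_reads = c(1000, 1100, 900, 0, 505),
                       length_bp = c(100, 110, 90, 120, 101))
    r <- relativeDepth(gdep, c("sc1", "sc2", "sc3"))
    expect_equal(r$relative_depth[r$gene == "sc1"], 1)
    expect_equal(r$relative_depth[r$gene == "lost"], 0)
    expect_equal(r$relative_depth[r$gene == "half"], 0.5)
    # half-copy fixture via the depth simulator at binomial noise scale
    set.seed(605)
    reads <- rpois(3, c(2000, 2000, 1000))
    r2 <- relativeDepth(data.frame(gene = c("a", "b", "target"),
                                   total_reads = reads,
                                   length_bp = c(200, 200, 200)),
                        c("a", "b"))
    expect_lt(abs(r2$relative_depth[3] - 0.5), 0.1)
})
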