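Package: ponypop
Title: Population-Genomic Selection Scans, F-Statistic Networks and
    Genomic Sex Inference for Pony and Horse Cohorts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Variant quality control (GATK-style hard filters, missingness,
    minor-allele-frequency, Hardy-Weinberg exact test, LD pruning, GRM
    kinship exclusion), windowed differentiation and diversity statistics
    (Weir-Cockerham FST, nucleotide diversity and pi ratio, LD decay, runs
    of homozygosity), a from-first-principles cross-population extended
    haplotype homozygosity (XP-EHH) scan, outgroup f3/f4 statistics with
    block-jackknife uncertainty and a symmetrized f4 distance network over
    breeds, multi-metric selective-sweep calling with an interval-overlap
    Fisher/permutation test, and genomic sex assignment plus Y-chromosome
    haplotype analysis from read-depth tables. A Balding-Nichols
    admixture-graph simulator with sweep implantation and sex-specific depth
    profiles provides synthetic cohorts with known ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    ape,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    knitr
Config/testthat/edition: 3
biocViews: PopulationGenetics, SNP, Genetics, Sequencing, QualityControl
RoxygenNote: 7.3.3
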