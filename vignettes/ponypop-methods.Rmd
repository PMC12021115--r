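---
title: "Methods: selection scans, f-statistics and sex inference in ponypop"
author: "ponypop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection scans, f-statistics and sex inference in ponypop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ponypop)
```

`ponypop` re-implements, as a tested and reusable pipeline, the
population-genetics core of a body-size selection study in horses and
ponies: variant QC, windowed differentiation and diversity statistics,
a cross-population haplotype scan, outgroup f-statistics with an
f4-based breed network, multi-metric sweep calling with a permutation
overlap test, and genomic sex / Y-haplotype analysis. This vignette
explains the models, the tunable parameters, the synthetic-data
generator that supplies ground truth, and the numerical and design
choices behind the code.

## The data container

`GenotypeData` extends `RangedSummarizedExperiment`: rows are bi-allelic
SNPs (a `GRanges` carrying REF/ALT, QUAL and the INFO annotations QD,
MQ, FS, SOR, MQRankSum, ReadPosRankSum), columns are samples (breed,
region, height class, recorded sex, a Yakutia-adjacency flag), and the
assays hold diploid ALT dosages 0/1/2 with `NA` for missing calls, plus
`hapA`/`hapB` per-haplotype alleles when phased. Class validity enforces
`hapA + hapB == dosage` at every call, so phased and unphased views can
never drift apart. VCFv4.2 is read through `vcfR` and written by a small
text emitter that preserves phase (`0|1`) and the six INFO keys.

## Variant and sample QC

**Hard filtering.** A site fails when any clause of
`QD < 2 || MQ < 50 || FS > 60 || SOR > 3 || MQRankSum < -5 ||
ReadPosRankSum < -5 || QUAL < 30` triggers. All comparisons are strict,
so `QD = 2.0` passes. An absent annotation never triggers its clause; it
is recorded as "not evaluated" instead, and a non-numeric value is
reported as a per-site evaluation error without aborting the run. These
semantics matter for joint-genotyped VCFs, where rank-sum annotations
are routinely missing at invariant-in-some-cohort sites.

**Missingness/MAF.** The order is fixed and documented: samples above
the per-sample missingness threshold are removed first, then sites above
the per-variant threshold, then sites below the MAF floor, with MAF
recomputed on the retained samples. The defaults (0.08% per sample, 2%
per variant, MAF 0.01) mirror a strict PLINK pass; the per-sample value
is unusually tight and deliberately configurable — an 8% reading of the
same threshold is one argument away. Because every decision is a
per-site count, the retained-site set is invariant to sample order.

**Hardy–Weinberg.** The exact conditional test on the heterozygote
count: given the allele totals, the p-value sums the probabilities of
all same-parity heterozygote counts whose conditional probability does
not exceed the observed one (no mid-p). The test suite checks it to
1e-12 against an independent absolute-probability enumeration for every
genotype configuration with up to 30 individuals.

**LD pruning** slides a 50-SNP window by 5 SNPs; while any pair in the
window exceeds r² = 0.5 (squared Pearson correlation of dosages over
shared non-missing samples), the member of the worst pair with the lower
MAF is removed, ties dropping the later position. The named tool leaves
the pair-removal rule to the implementation; fixing it makes the output
deterministic, which the suite asserts.

**Kinship.** The GRM is the VanRaden/GCTA form
g<sub>jk</sub> = mean over sites of
(x<sub>ij</sub>−2p<sub>i</sub>)(x<sub>ik</sub>−2p<sub>i</sub>)/(2p<sub>i</sub>(1−p<sub>i</sub>)).
Because p is estimated from the cohort itself the matrix is centered:
unrelated pairs average −1/(n−1), not 0, and the tests check that
analytic value. Pairs above 0.3 are resolved greedily, removing the
member with the higher mean relatedness first — the source analysis
does not state which member was dropped, so determinism was the
criterion.

## Windowed statistics

Windows tile each chromosome from coordinate 0 in 10-kb non-overlapping
bins (0-based half-open internally; GRanges/report tables are 1-based
inclusive, BED output half-open).

**FST** uses the Weir–Cockerham (1984) two-population variance
components computed from observed heterozygosity; window estimates are
ratio-of-sums Σa/Σ(a+b+c), the weighted estimator of the standard
tooling, with mean-of-ratios behind a flag for comparison. The
estimator corrects for sampling noise, so identical samples score near
— not exactly at — zero, and slightly negative windows are legitimate.
On the package's reference two-population fixture (Balding–Nichols
drift F = 0.1 per branch, 50,000 sites, 25 + 25 diploids) the
genome-wide ratio-of-sums estimate recovers 0.10 within ±0.02.

**θπ** divides summed site π by window length in bp (not by SNP count),
so sparse windows read as low-diversity rather than undefined; windows
with zero eligible chromosomes are flagged undefined instead. The
π ratio θπ<sub>pony</sub>/θπ<sub>horse</sub> is undefined where the
reference diversity is 0 or fewer than `minSnps` (default 1) sites
segregate, and undefined windows are excluded from quantile ranking —
whether the original analysis excluded low-SNP windows is unstated, so
the knob is exposed.

**ROH.** A 50-SNP scanning window is a hit when it contains ≤1
heterozygous call (and ≤5 missing, the tool default, configurable); a
SNP is in-ROH when ≥5% of its overlapping windows are hits, and a
heterozygous call itself can never be in-ROH. Runs split at
between-variant gaps above 100 kb — the "≤100" parameter is read in kb,
consistent with the tool's units — and segments must reach 500 kb, 50
SNPs and ≤50 kb/SNP. One edge property is worth knowing: at a sharp
homozygous/heterozygous boundary the hit-fraction rule trims one or two
SNPs from each end of the tract, so constructed-truth tests assert
containment and near-complete SNP recovery rather than exact endpoints.

## XP-EHH

EHH at extension x is the probability that two random haplotypes are
identical over [core..x]: Σ<sub>g</sub>C(n<sub>g</sub>,2)/C(n,2) over
the partition of haplotypes by identity, grouped at the core by core
allele. Each added site refines the partition, so the curve is monotone
non-increasing; the implementation updates group labels incrementally
and is checked exhaustively against a pair-enumeration oracle on small
panels. iHH integrates the curve trapezoidally over physical position,
per side, stopping at the cutoff crossing (integrating down to the
interpolated crossing point), at the 1-Mb maximum extension
(integrating up to the boundary), or at a >200-kb gap; cores whose EHH
is still above the cutoff at the panel edge are flagged truncated. The
cutoff (0.05), extension and gap defaults mirror the conventional
scan-tool settings, since only the tool and version are on record; all
three are arguments.

The raw score is ln(iHH<sub>query</sub>/iHH<sub>ref</sub>); iHH is
integrated for the whole population rather than per core allele,
matching the cross-population statistic's standard definition.
Normalization is genome-wide (single standardized track, not
frequency-binned), giving mean 0 and SD 1 by construction. Cores are
restricted to pooled MAF ≥ 0.05, and cores where either population's
iHH is 0 are skipped with a reason rather than scored ±∞. With ponies
as query, positive normalized scores localize pony-side selection;
swapping query and reference negates every raw score exactly.

## f-statistics and the breed network

Outgroup f3 and f4 are per-site frequency products averaged over
complete cases for that statistic (sites missing a frequency in any
required population are dropped per quartet). Uncertainty is a weighted
delete-one block jackknife over contiguous 5-Mb physical blocks (block
size unstated in the source analysis; 5 Mb comfortably exceeds LD range
and is configurable), with Z = estimate/SE.

The directional breed distance averages f4(a, i; b, O) over third
breeds i. The index set excludes i ∈ {a, b} by default: the i = a term
is identically zero and i = b is self-referential, so both only dilute
the mean; a flag restores the literal all-breeds summation for
sensitivity analysis. disedge symmetrizes the two directions, and edges
are ranked into quintile strength classes (larger shared drift =
stronger) purely for rendering — raw values are always emitted. Breeds
flagged Yakutia-adjacent can be removed before computation, mirroring
their exclusion from the pony-related network.

Under the Balding–Nichols generator these statistics have closed-form
expectations via shared drift paths: with ancestral frequencies
U(0.05, 0.95), E[p(1−p)] = 0.1825, so a shared branch with drift F
contributes F·0.1825 to f3, and a 30% admixture edge P3→P2 gives
E[f4(P1,P2;P3,O)] = −0.3·F<sub>P3</sub>·0.1825. The acceptance suite
verifies both to within three jackknife SEs, plus |Z| < 3 for unadmixed
quartets.

## Sweep calling and the overlap test

Per metric, windows beyond the empirical top-1% threshold (computed
over defined windows only; flagging strict, ties at the threshold not
flagged — degenerate all-equal tracks therefore flag nothing) merge
into regions; a candidate needs support from at least two of FST
(upper tail), π ratio (lower tail for a query-side sweep) and mean
XP-EHH (upper tail for the query). SNP-level XP-EHH flags can first be
merged at <100 bp for the interval-overlap analysis mode.

The interval-overlap test builds the 2×2 table interval-wise: A-with-B
overlaps, A misses, B misses, and an estimated count of comparably
sized empty genome slots, `round(L/(mean_len_A + mean_len_B))` minus
the first three — an approximation in the style of the standard
interval-Fisher tool, reported alongside the raw counts. The p-value is
the two-sided Fisher exact test; odds ratios apply a Haldane 0.5
correction at zero cells. The permutation null re-places set A
uniformly `nShuffles` times (default 10,000), preserving each
interval's length and chromosome and forbidding self-overlap (free
placement behind a flag), and reports the empirical p
(1 + #{OR<sub>null</sub> ≥ OR<sub>obs</sub>})/(n + 1) — never a literal
zero; the attainable floor is 1/(n+1).

Genotype gradients tabulate 0/1/2 genotype and ALT-allele frequencies
per ordered height group and flag monotonicity of the allele frequency.
With four groups, a random relabeling is monotone with probability
about 2/4! ≈ 8%, so shuffling labels breaks an implanted gradient in
roughly 9 of 10 shuffles — the calibration the tests assert.

## Genomic sex and the Y chromosome

From per-chromosome read counts ("reads" are read-base units, so
rate = reads/length is depth): covY (covered fraction of Y), X/Chr1 and
Y/Chr1 rate ratios, Rx (X rate over mean autosomal rate) and
Ry = reads<sub>Y</sub>/(reads<sub>X</sub>+reads<sub>Y</sub>). All are
invariant to global rescaling. The primary call is covY > 0.94 ⇒ male —
the printed "coverage exceeding 94%" value, with covered fraction (not
mean depth) chosen because that is what a coverage axis measures;
Rx/Ry corroborate with the thresholds established for those indices
(Ry ≥ 0.075 male / ≤ 0.016 female; Rx near 0.5 vs 1.0, tolerance 0.2).
Disagreement yields "ambiguous" with both rules named — never the
opposite sex, which is the property the tests enforce down to 0.3×
depth. Recorded-sex mismatches are reported, not silently corrected.

MSY filtering treats heterozygous diploid-coded Y calls as genotyping
artifacts (the Y is hemizygous in males): any site heterozygous in any
male is dropped, then sample missingness, variant missingness (>2%) and
MAF (<0.005) filters apply, and finally sites with any remaining
missing call are excluded so haplotypes are complete-case vectors. The
attrition report lists counts per stage. Haplotype counting is exact
string identity over retained sites; the median-joining network drawing
is out of scope, but the membership map exports for external tools.

P-distance scores site pairs 0 / 0.5 / 1 (identical / one shared allele
/ opposite homozygotes), averaged over shared non-missing sites — made
explicit here because the source names only a tool. Neighbour joining
is delegated to `ape::nj` (Saitou–Nei with the standard Q-criterion)
and rooted on the named outgroup; the test battery confirms exact
recovery of additive matrices for trees up to 8 leaves. Relative depth
scores a gene's per-bp depth against the mean over a single-copy gene
set: ≈1 single-copy, ≈0.5 hemizygous, ≈0 absent.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the
package's study conditions. Drift follows the Balding–Nichols Beta
parameterization (child mean p, variance F·p(1−p)); admixed nodes mix
parents deterministically; frequencies are clipped, not reflected, at
the boundaries, and sites fixed in all populations are retained so
downstream filters must handle them. Balding–Nichols was chosen over a
coalescent simulator precisely because it yields closed-form
f-statistic and FST expectations for acceptance testing; it does not
model linkage between sites (sites are independent draws), mutation,
or recombination-map realism, so LD-decay curves on generator output
show only finite-sample r² (≈1/n), and the XP-EHH background comes from
random haplotype identity rather than genealogical structure. Passing
tests on this generator therefore validate the estimators and the
intersection logic, not the demographic realism of any particular
horse cohort.

Sweep implantation copies one carrier's interval haplotype into a
fraction of target-population haplotypes — simple, deterministic, and
it produces all three scan signals at once. The reference fixture uses
a 2-Mb chromosome, 2,000 SNPs, 25 + 25 diploids, drift F = 0.1, carrier
frequency 0.9 and a 20-kb interval aligned to two 10-kb windows at the
chromosome midpoint; the interval length is a generator default chosen
so that a top-1% rule over 200 windows (two windows per metric) can
represent the full truth interval. Depth profiles give males half-rate
X and Y with near-complete Y coverage and females a residual Y
mismapping rate (default 0.5% of the autosomal rate), gamma-Poisson
overdispersion per chromosome, and the Lander–Waterman coverage law
1−e^(−depth) for covered fractions.

Every stochastic stage takes a mandatory seed and restores the caller's
RNG state, so pipelines are bit-reproducible and composable.

## Problem sizes and numerical choices

The test and acceptance workloads are sized for a single CPU: 50,000
sites for frequency-level recovery checks, 20 seeds of the 2,000-SNP
sweep fixture for end-to-end recovery (Jaccard ≥ 0.5 against truth in
at least 18), 200 independent interval-set pairs with 99 shuffles each
for permutation calibration (the empirical-p floor 1/100 sits below the
0.05 significance level), and exhaustive oracle sweeps only where the space is
genuinely small (HWE totals ≤ 30; EHH panels ≤ 12 haplotypes × 10
sites are sampled, since enumerating all binary panels is infeasible).
Tie-breaks are fixed everywhere a choice exists (LD pruning drops the
later position on MAF ties; greedy GRM removal orders by mean
relatedness then index; NJ inherits `ape`'s deterministic joins), and
degenerate inputs — monomorphic sites, empty windows, zero-iHH cores,
single jackknife blocks, all-equal quantile tracks — return defined
values or flagged NAs rather than errors wherever the pipeline can
meaningfully continue.

## Known limitations

Sites are simulated without linkage, so the generator cannot calibrate
LD-decay expectations beyond the finite-sample baseline. The
interval-Fisher n22 slot count is an explicit approximation. XP-EHH
uses physical distance only (no genetic map), normalization is not
frequency-binned, and unphased data cannot enter the haplotype scan.
The ROH caller inherits the scanning-window edge attrition discussed
above. Phasing, alignment, variant calling, PCA/ADMIXTURE embeddings
and ML admixture-graph search are out of scope: the pipeline consumes
an annotated, optionally phased VCF.
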