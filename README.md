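# ponypop

Population-genomic selection scans, f-statistic networks and genomic sex
inference for pony and horse cohorts.

Small ponies and tall horses sit at the extremes of a single
domesticated species, and the genomic regions that drive that body-size
difference leave three distinct footprints in resequencing data:
elevated differentiation between the groups, a local loss of diversity
in the selected group, and unusually long shared haplotypes around the
selected allele. `ponypop` implements the full desk-side pipeline that
turns a filtered multi-sample SNP set into such selective-sweep
candidates, plus the breed-relationship and sex/Y-chromosome analyses
that surround a scan of this kind. It is aimed at population geneticists
who want every statistic recomputable from first principles on data they
can simulate, inspect and perturb.

## What it computes

* **Variant and sample QC** — GATK-style hard filtering
  (`QD < 2 || MQ < 50 || FS > 60 || SOR > 3 || MQRankSum < -5 ||
  ReadPosRankSum < -5 || QUAL < 30`, evaluated clause by clause with
  absent annotations never triggering), PLINK-style missingness/MAF
  filters, an exact conditional Hardy–Weinberg test, sliding-window LD
  pruning, and GRM-based kinship exclusion (off-diagonal relatedness
  above 0.3).
* **Windowed statistics** — Weir–Cockerham *F*<sub>ST</sub> from the
  1984 variance components *a*, *b*, *c* with ratio-of-sums window
  weighting (Σ*a* / Σ(*a*+*b*+*c*)); nucleotide diversity θπ per 10-kb
  window (site π = *c*<sub>ref</sub>*c*<sub>alt</sub> / C(*n*,2),
  divided by window length); the diversity ratio
  θπ<sub>pony</sub>/θπ<sub>horse</sub>; LD-decay curves; and a
  PLINK-style scanning-window ROH caller (≥500 kb, ≥50 SNPs, ≤1 het per
  50-SNP window, hit rate ≥0.05, gap ≤100 kb, ≤50 kb/SNP).
* **XP-EHH from first principles** — EHH by haplotype-partition
  refinement, iHH as its trapezoidal integral over physical distance
  (cutoff 0.05, max extension 1 Mb, max gap 200 kb), raw score
  ln(iHH<sub>query</sub>/iHH<sub>ref</sub>) and genome-wide
  standardization; with ponies as the query, positive scores point at
  pony-side selection.
* **f-statistics and the breed network** — outgroup
  *f3*(X, Y; O) = E[(p<sub>X</sub>−p<sub>O</sub>)(p<sub>Y</sub>−p<sub>O</sub>)]
  and *f4*(P1, P2; P3, O) with weighted block-jackknife standard errors;
  the directional breed distance
  disf4(a,b) = Σ<sub>i</sub> f4(a, i; b, O)/n and its symmetrization
  disedge(a,b) = (disf4(a,b) + disf4(b,a))/2, with optional exclusion of
  Yakutia-adjacent breeds.
* **Sweep calling** — per-metric top-1% empirical-quantile thresholds,
  region merging, and the ≥2-of-3-metrics intersection rule; genotype
  frequency gradients across withers-height groups; interval-overlap
  Fisher exact tests with a length- and chromosome-preserving
  permutation null (empirical p never reported as a literal zero).
* **Genomic sex and the Y** — coverage fraction on Y (male above 0.94),
  ChrX/Chr1 and ChrY/Chr1 depth ratios, Rx and Ry corroboration,
  MSY SNP filtering with stage-by-stage attrition, distinct Y-haplotype
  counting, P-distance matrices and neighbour-joining trees rooted on an
  outgroup, and relative-depth scoring of gene presence.
* **A ground-truth simulator** — Balding–Nichols admixture-graph allele
  frequencies (child ~ Beta with mean *p*, variance *F p*(1−*p*)),
  phased genotype cohorts with VCF INFO annotations, hard-sweep
  implantation, and sex-specific depth profiles; every stage is
  bit-reproducible under its seed.

## Worked example

Simulate the default study conditions — a pony/horse split with drift
F = 0.1 per branch, 2,000 SNPs on a 2-Mb chromosome, 25 + 25 diploids,
and a 20-kb hard sweep implanted in ponies at 90% carrier frequency —
then run the three-metric scan:

```r
library(ponypop)
fx <- sweepScanFixture(seed = 1)
fx$gd
#> GenotypeData: 2000 sites x 50 samples; phased
#>   breeds: horse(25), pony(25)
#>   implanted sweeps: 1

pony <- sampleMeta(fx$gd)$breed == "pony"
scan <- sweepScan(fx$gd, pony, !pony, windows = fx$windows)
as.data.frame(scan$candidates)
#>   seqnames   start     end width strand           supports n_supports
#> 1     chr1 1000001 1020000 20000      * FST,PI_RATIO,XPEHH          3
```

The single candidate is exactly the implanted interval, supported by all
three metrics. The two windows it spans stand far outside the genome
background (genome-wide mean window FST here is 0.107, matching the
simulated drift):

```r
as.data.frame(scan$windows)[101:102, ]
#>       start     end n_snps    fst pi_ratio mean_xpehh
#> 101 1000001 1010000     11 0.5356   0.1450     4.8922
#> 102 1010001 1020000      6 0.2715   0.2393     3.8198
```

FST jumps five-fold, pony diversity collapses to ~15% of the horse
level, and the mean normalized XP-EHH of ~4–5 SD is what a hard sweep at
90% frequency should produce. The swept allele also grades across
groups, which `genotypeGradient()` summarizes per height class.

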