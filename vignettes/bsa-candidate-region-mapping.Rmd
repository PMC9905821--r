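---
title: "Bulk-segregant candidate-region mapping: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bulk-segregant candidate-region mapping: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsaqtl)
```

## The problem

In a bi-parental cross segregating for a quantitative trait, pooling the
phenotypic extremes and sequencing the two pools turns QTL localisation into
an allele-frequency problem: away from trait loci the two bulks are random
draws from the population and their allele frequencies agree up to sampling
noise; near a trait locus, selection of the tails drives the frequencies
apart. `bsaqtl` implements the statistics of this comparison for
bulk-segregant analysis by sequencing (BSA-seq) in F2 and BC1F2 designs, as
used to narrow a node-of-the-first-fruiting-branch (NFFB) earliness locus in
upland cotton from a ~24.7 Mb QTL interval to a ~92.4 Kb candidate region.

## Pool statistics

At each SNP, let $M$ and $P$ be the pooled read depths supporting the
maternal (JF914-type) and paternal (JF173-type) allele in one pool. The
per-pool SNP-index and its between-pool difference are

$$\mathrm{SI}_{high} = \frac{M_{high}}{M_{high}+P_{high}},\qquad
  \mathrm{SI}_{low} = \frac{M_{low}}{M_{low}+P_{low}},\qquad
  \Delta \mathrm{SI} = \mathrm{SI}_{low}-\mathrm{SI}_{high},$$

with $\Delta$ oriented low-minus-high. The Euclidean distance uses the full
four-base frequency vectors of the two pools,

$$ED = \sqrt{(A_h-A_l)^2+(T_h-T_l)^2+(C_h-C_l)^2+(G_h-G_l)^2} \in [0,\sqrt 2],$$

and is raised to the fourth power ($ED^4$) to suppress background noise; the
fourth power is monotone, so it reorders nothing but compresses the noise
floor relative to signal. When both pools are biallelic for the same two
parental alleles, $ED = \sqrt 2\,\lvert\Delta \mathrm{SI}\rvert$ exactly;
the test suite asserts this identity to $10^{-12}$, which is the strongest
internal consistency check between the two statistic families.

The genome-scan cutoff for each statistic is the genome-wide
$\mathrm{median} + 3\,\mathrm{SD}$ of its per-SNP values. Three choices here
were genuinely open and are resolved as documented defaults:

* **Sign handling.** $\Delta \mathrm{SI}$ is thresholded on its absolute
  value, so enrichment toward either parent is detected; the raw signed
  track is retained in the output.
* **SD convention.** The sample (n−1) standard deviation; population SD is
  available via `sd_type = "population"` and differs negligibly at genomic
  SNP counts.
* **Scope.** Genome-wide by default, per-chromosome behind
  `per_chromosome = TRUE`. With few chromosomes and a strong locus the
  causal chromosome is globally elevated, and a per-chromosome cutoff on it
  would chase its own signal; genome-wide is the robust default.

On a Gaussian null track the expected exceedance of median+3SD is
$P(Z>3) \approx 0.00135$; the suite verifies this on $20 \times 10^5$-SNP
tracks within Monte-Carlo error. Missingness: SNP-index needs informative
depth $M+P \ge$ `min_depth` (default 4) per pool, ED needs total depth
$\ge$ `min_depth`; zero-depth SNPs are missing, never zero.

No sliding-window smoothing is applied by default; regions are called
directly from per-SNP exceedances (below), which keeps the method's
resolution at the marker spacing.

## Region calling and intersection

Above-threshold SNPs (strictly `>` the cutoff) are clustered per chromosome:
consecutive exceedances at most `max_gap` bp apart (default 200 kb) share a
region; regions with fewer than `min_snps` exceedances (default 3) are
dropped. A region spans its first to last contributing SNP. Neither
parameter is part of the published analysis, so both are explicit, logged
configuration rather than buried constants. Candidate regions are the
intersection of the $\lvert\Delta \mathrm{SI}\rvert$ and $ED^4$ region sets,
computed on `GenomicRanges`; intersection is commutative, associative and
idempotent, and the tests pin the implementation against a naive per-base
oracle on random instances.

All coordinates are 1-based inclusive with length $end - start + 1$ — the
convention under which the two published D3 regions
(41,779,195–41,836,120 and 41,836,768–41,872,287) total
$56{,}926 + 35{,}520 = 92{,}446$ bp ≈ 92.4 Kb and the QTL interval
(17,130,008–41,839,226) is 24,709,219 bp ≈ 24.7 Mb. BED export converts to
0-based half-open.

## The simulator

The simulator exists so that every downstream stage can be exercised, and
calibrated, without the deposited sequencing data. It emulates the study
design, not the raw reads:

* **Meiosis.** Haldane map function (crossovers without interference),
  implemented as a two-state Markov chain along each chromosome with switch
  probability $r = (1-e^{-2d})/2$ per adjacent-marker interval of $d$
  Morgans. No map function is stated for the original cross; Haldane is the
  standard interference-free choice and adjacent-marker recombination is
  verified against it in the tests.
* **Populations.** F2 plants draw two gametes from a heterozygous F1. BC1
  founders are modeled as fully heterozygous at all segregating markers —
  the BC1 was described but not genotyped, and its F2:4 maternal line's
  genome-wide genotype is unknown, so the fully-heterozygous model (under
  which BC1F2 segregates 1:2:1 like an F2) is the default and
  `segregating_regions` lets users fix chosen tracts for the maternal
  allele instead.
* **Phenotype.** $y = \mu + \sum_l a_l(d_l-1) + \delta_l[d_l=1] + N(0,\sigma^2)$
  with additive/dominance effects in trait units (nodes).
* **Bulks.** Stable sort by (phenotype, plant id); low bulk = first
  `bulk_size`, high bulk = last `bulk_size`, so ties never overlap the
  bulks.
* **Depth.** Poisson per SNP per pool (overdispersion-free default) with
  binomial sampling of allele-supporting reads from the bulk's true
  frequency, plus a small per-read error rate (default 0.001) that converts
  reads to uniformly random other bases — this is what populates the third
  and fourth base dimensions of the ED statistic on real-ish data.

What the simulator does **not** model: read-level artifacts (mapping error,
reference bias, duplicated fragments), linked minor loci, epistasis,
genotyping batch effects, and overdispersed depth. Passing the recovery
property below therefore demonstrates the pipeline's correctness and
calibration under the idealised generative model, not robustness to every
failure mode of field data.

## Reference settings and the recovery property

`reference_sim_config()` freezes the package's calibration conditions: a
BC1F2 of 561 plants with 30/30 tail bulks and 30x pooled depth — the study's
design — on a desk-scale genome of 3 chromosomes × 100 Mb × 160 cM with
2000 markers each, one causal locus at chr1:90,000,000 with additive effect
1.0 node ($\sigma_{res} = 0.5$, so 1.15 trait SD), dominance 0. The
chromosome map length matches the study's per-chromosome ~150–179 cM; the
locus is placed telomere-proximally (0.9 of the chromosome), like the D3
locus at ~0.9 of its chromosome; the effect size is consistent with a
~3-node parental difference carried substantially by one major locus.

Two points deserve honesty. First, with only 3 chromosomes one third of the
genome is linked to the locus, which inflates a genome-wide median+3SD
relative to the 26-chromosome original; the telomere-proximal placement and
major-effect locus are what keep the peak decisively above the cutoff.
Second, the per-SNP statistics on the causal chromosome are strongly
autocorrelated through the bulks' genomic composition, so region counts are
not comparable between genomes of different chromosome number.

The core acceptance property, run at these settings in the test suite and
the acceptance script: across 50 seeded replicates the
$\Delta \cap ED$ common region must contain the causal position in ≥ 90%,
and across 50 null replicates (no causal locus) a common region larger than
10% of the genome may appear in ≤ 5%.

## Read QC and the marker engine

Two rule sets reproduce the published read filters. GBS: remove reads with
≥ 10% N (inclusive, as printed), > 50% of bases below Phred 5 (strict), any
10-nt window matching the adapter with ≤ 10% mismatches, or containing a
HaeIII/EcoRI recognition site. Re-sequencing: > 10% N (strict, as printed)
and > 40% of bases at Q ≤ 20. The recognition sequences are not printed in
the original methods and default to HaeIII = GGCC, EcoRI = GAATTC
(configurable); the adapter rule scans every read window against every
adapter window, ungapped; paired-end filtering drops the pair when either
mate fails (the common convention; the original is silent). Filtering is
idempotent and per-rule counts tally every rule a read trips.

The marker engine classifies parental genotype pairs into the eight CP
segregation codes (aa×bb, ab×cc, ab×cd, cc×ab, ef×eg, hk×hk, lm×ll, nn×np,
plus uninformative); the mapping is enumerated over all 100 ordered
genotype pairs in the tests for exhaustiveness and mutual exclusivity.
aa×bb markers then pass: an abnormal-base rule (progeny alleles absent from
both parents are blanked; markers > 5% abnormal dropped — the published
filter names the concept without a threshold, so 5% is explicit
configuration), the integrity rule (call rate ≥ 40%, boundary kept), the
1:2:1 chi-square distortion test (df = 2, no continuity correction,
removal at p < 0.001; type-I rate ≈ 0.1% verified on simulated undistorted
markers), and last the same-fragment deduplication (one representative per
cluster of markers within 150 bp — "same read" is not defined precisely in
the original, so the fragment length is configurable and the step is
documented as order-sensitive and applied last). Collinearity between map
order and physical position is the Spearman rank correlation.

## Phenotype summaries

`pheno_summarize()` reports max/min/mean and bias-corrected sample skewness
and excess kurtosis (the Excel/SPSS convention, e1071 type 2; the simple
moment estimators sit behind `bias_corrected = FALSE`). The parental
comparison is a Welch t-test — the original does not name its test, and
unequal variances between a cultivar and an inbred line are the safe
assumption — starred `**`/`*` at p < 0.01 / 0.05. Constant data yields
undefined skew/kurtosis (NA), and the degenerate both-constant comparison
returns p = 1 for equal means.

## Bundled verification data

`genetic_map_summary()` ships the published per-linkage-group map summary
(26 rows plus At/Dt/total) and `map_summary_checks()` recomputes the
subtotals and every per-chromosome mean interval (map length / (markers−1)).
Two caveats found by this arithmetic: the At length subtotal recomputes to
2117.73 vs the stated 2117.74 (accumulated rounding of 13 cells printed at
2 decimals — the checks allow 0.02 cM on sums), and the stated At/Dt mean
interval cells (0.74, 0.61) do not follow the length/(markers−1) convention
of the per-chromosome cells, so they are not recomputed.
`candidate_interval_report()` does the D3 interval arithmetic shown above.

## Problem sizes

The shipped tests and the acceptance script use: 100 causal + null
replicates at the reference settings (~6000 SNPs × 561 plants each),
$10^4$ SNPs for the ED/Δ identity, $20 \times 10^5$ SNPs for threshold
calibration, 200 random instances for the region oracles, and
$5 \times 10^4$ markers for distortion-filter calibration — sizes chosen so
the whole battery completes in a few minutes while keeping Monte-Carlo error
well inside the asserted bounds.

## Limitations

* Region-calling parameters (`min_snps`, `max_gap`) and the SNP filters are
  this package's explicit configuration; the original analysis does not
  state its equivalents, so region *counts* should not be compared
  numerically against the published 197/99/39.
* QTL intervals are consumed as input (BED-like tables); linkage-map
  construction and interval-mapping scans are out of scope.
* The simulator's idealisations listed above; in particular Poisson depth
  underestimates the variance of real pooled libraries.
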