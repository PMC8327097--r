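---
title: "ovisweep: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ovisweep: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind each stage of the
package, the parameters that matter (with units and defaults), the design
decisions taken where conventions diverge, and what the synthetic-data
generator does and does not emulate. It states no numbers that the test
suite and `scripts/acceptance.R` do not themselves compute.

## Data model and coordinates

Genotypes are diploid biallelic calls coded 0/1/2 (copies of the alternate
allele) or missing, held in a `GenotypeDataset`
(`RangedSummarizedExperiment`: variants x samples, 1-based bp positions,
`population` labels in `colData`). Phased data live in a `HaplotypeSet`
(two binary haplotype columns per sample, no missing alleles, and a genetic
map in cM). All internal coordinates are 1-based inclusive; BED export
converts to 0-based half-open, and region sizes are reported as
`(stop − start)/10^6` rounded half-away-from-zero to 3 decimals — the span
between first and last position, without the +1.

Allele orientation is fixed at load time: the alternate allele is the minor
allele (ties broken toward the lexicographically later allele). Every
downstream statistic used here (F_ST, r², EHH homozygosity) is invariant to
this orientation. When no genetic map is supplied, a constant 1 cM/Mb is
assumed (`c = bp x 1e-8` Morgan), the usual default for array scans without
a species map. Non-autosomal and unmapped variants are dropped (with a
reported count) by `keepAutosomes()`; all scans here are autosomal.

## Quality control

Defaults: samples with **more than 10 %** missing genotypes removed (a
sample at exactly 10 % is retained); variants kept when call rate ≥ 0.90,
MAF ≥ 0.01, and Hardy–Weinberg exact p ≥ 1e-10. The HWE test is the exact
conditional test (sum of probabilities of heterozygote counts no more
probable than observed, same parity, allele counts fixed), using the plain
rather than the mid-p value — the conservative reading at a 1e-10
threshold. It is checked against full enumeration for all configurations
with n ≤ 20.

Relatedness uses the method-of-moments Pi-HAT: IBS0/1/2 counts over
mutually genotyped SNPs are equated to their allele-frequency expectations
to solve P(IBD = 0, 1, 2), each truncated to [0, 1] and renormalized;
`PI_HAT = P(IBD=2) + P(IBD=1)/2`. Allele frequencies come from the full
sample set; no small-sample bias correction is applied, which is accurate
at the SNP counts (≥ 10⁴) the estimator is intended for. The reporting
window [0.05, 1] affects the pair report only, never the pruning
arithmetic. The pruning cutoff 0.1875 is the midpoint of expected Pi-HAT
for 2nd-degree (0.25) and 3rd-degree (0.125) relatives; removal is greedy —
always the member of an exceeding pair with more exceeding partners, ties
broken by higher missingness, then later sample order — because the exact
heuristic used by the common tooling is not documented.

LD pruning slides a 50 kb window in 5 kb steps (units are kb, not SNP
counts — a documented interpretation, since window conventions are
ambiguous across tools) and removes, from the strongest pair with
genotype-dosage r² > 0.5, the variant with lower MAF (tie: later
position). r² is the squared Pearson correlation of dosages (composite LD,
no EM haplotyping) — standard for unphased array data.

## Diversity and differentiation

Per individual, H_O is the heterozygous fraction of non-missing calls and
F = (O_hom − E_hom)/(M − E_hom), with E_hom accumulated from sample allele
frequencies over the individual's M non-missing SNPs. Per population, H_E
is the mean across SNPs of the unbiased expected heterozygosity
`2pq·n/(n−1)`. Because the axis over which an H_E dispersion is taken is a
genuine ambiguity, the SD axis (across SNPs, default, or across
individuals) is a flag and is recorded in the output header.

Pairwise differentiation is Weir–Cockerham (1984) θ with two populations:
per-locus variance components a (between populations), b (between
individuals within), c (within individuals), combined as
`θ = Σa / Σ(a+b+c)` — the ratio-of-averages form, which is what the
standard population-genetics tools report. Significance comes from
permuting population labels: `p = (1 + #{θ* ≥ θ}) / (n_perm + 1)` with
1,000 permutations by default, seeded.

## Runs of homozygosity

The consecutive method scans each sample and chromosome SNP-by-SNP, with
budgets per run: at most 1 heterozygous call, at most 5 missing calls, no
inter-SNP gap above 1 Mb; closed runs are kept when they have ≥ 50 SNPs,
span ≥ 1 Mb, and have density ≥ 1 SNP/100 kb. Because run feasibility is
monotone (budgets only grow under extension), the greedy rule — extend to
the maximal feasible end, close, restart after the violating SNP (or at the
next SNP after a gap violation) — is well defined, and the detector is
pinned by an exhaustive brute-force sub-run oracle in the tests. The
window-based "minimum SNPs per sliding window" parameter of window-style
detectors is redundant under the consecutive method and is recorded only.
Segment length is `stop − start` (no +1), matching the size convention
used for reported candidate-region tables.

`F_ROH` divides the per-sample total ROH length by 2.45 Gb, the ovine
autosomal genome length. ROH islands are maximal runs of consecutive SNPs
whose within-group ROH occupancy is ≥ 50 %; island bounds are the span of
the qualifying SNPs themselves (not midpoints to the neighbouring
non-qualifying SNPs — a documented choice where practice varies). Private
islands are the parts of one group's islands with zero bp overlap with any
other group's islands, with whole-vs-segment retention recorded.

## LD decay and N_E

`pairwiseR2()` computes dosage r² for all within-chromosome pairs up to
5 Mb apart. `neTrajectory()` applies Sved's relation
`N_E(t) = (1/(4c)) (1/r̄² − 1)` on the grid `c = 1/(2t)`: pairs within a
±10 % band around the target c contribute their mean r², and bins with
fewer than 50 pairs are flagged unreliable (both knobs configurable — the
binning is not standardized anywhere). The 1/n chromosome-sample
adjustment to r̄² is off by default (the bare relation is the published
form) and available as a flag; parameter-recovery checks against the
forward Wright–Fisher simulator use it, since at desk-scale sample sizes
the sampling term is not negligible. Because single c-bins are noisy at
desk scale, recovery checks summarize a trajectory by the median over the
recent bins rather than asserting every bin. Sved's 1/(1+4Nc) is itself an
approximation to drift–recombination equilibrium; at true constant N the
estimator is biased modestly upward, which is why recovery is asserted
within a factor of 2 rather than a tight band.

## Selection scans

**Windowed F_ST.** Per-SNP F_ST follows
`1 − (p₁q₁ + p₂q₂) / (2 p_r q_r)` with `p_r` the unweighted mean of the two
group frequencies (a sample-size-weighted pooling is available as a flag).
Windows of 200 kb tile each chromosome from bp 1 in 60 kb steps and are
kept while they fit inside the chromosome span; windows with fewer than 3
informative SNPs are dropped. Window means are Z-standardized over all
retained windows of a comparison (so mean 0 / SD 1 hold by construction and
are asserted to 1e-9), and candidates are the top 0.1 % positive ZF_ST
windows — implemented as exactly `ceiling(0.001 × windows)` top-ranked
windows, so the candidate count is deterministic.

**EHH / iHH / XP-EHH.** EHH among the carriers of a core allele at
displacement j is the fraction of carrier pairs identical over the span
core..j (`Σ C(n_h,2) / C(n,2)`), non-increasing outward, computed by
incremental group refinement and pinned by a string-counting enumeration
oracle. iHH is the trapezoidal integral of EHH over genetic distance (cM),
truncated after the first trapezoid whose right endpoint falls below 0.05
(a standard truncation level). The site-level statistic weights the two
core alleles by their frequency; alleles with fewer than 2 carriers
contribute nothing. For the cross-population scan both populations are
integrated over the *same* interval on each side — integration stops where
the weighted EHH is below the truncation level in both populations — so
`ln(iHH_A/iHH_B)` compares like with like; this shared-boundary convention
is the field standard and materially stabilizes the null. Raw scores are
standardized over all defined SNPs of the scan and one-sided p-values per
tail are taken from the standard normal, with p < 0.001 flagged significant
and the direction (A vs B) recorded. Cores with pooled MAF < 0.05 are
skipped (near-fixed cores carry no haplotype information).

Two known limitations, both visible in the acceptance outputs rather than
hidden:

- *Normal-approximation tails.* The standardized XP-EHH null is
  leptokurtic, so standard-normal p-values over-reject at the 0.001 level
  by a small factor (the acceptance script reports the measured null tail
  fraction). Empirical top-quantile thresholds are preferable in practice;
  the normal p is kept because it is the published procedure this package
  reproduces.
- *Localization of hard sweep tracts.* The sweep injector replaces a fixed
  interval with a donor haplotype, so carrier homozygosity is uniform
  across the tract and the iHH profile is flat over it: every core inside
  the tract integrates roughly the full tract plus neutral tails. The
  arg-max SNP therefore localizes the *tract*, not the core within it —
  the acceptance script reports the within-100-kb hit rate, which is low
  by construction for a 1 Mb tract. Real sweeps, with recombination-eroded
  edges, peak at the core; the hard tract is the price of an exactly
  checkable generator contract.

Significant SNPs of the same direction within 200 kb are merged into
candidate intervals (the merge gap is an assumption, documented and
configurable, since the grouping of per-SNP significances into regions is
not standardized).

## Structure

PCA mean-imputes missing genotypes per SNP, centers columns by 2p̂ and, by
default, applies Patterson scaling `sqrt(2p̂(1−p̂))` (plain centering is a
flag); coordinates are eigenvectors of the sample covariance scaled by the
square roots of their eigenvalues, and variance fractions are eigenvalue
shares. Neighbor joining runs on the pairwise F_ST matrix (negative
pairwise estimates floored at zero). Negative NJ branch lengths — a known
artifact of near-zero distances — are clamped to zero with the deficit
moved to the adjacent branch, preserving the tree's total length; ties in
agglomeration are resolved deterministically by label order.

## Consensus regions

Tagged intervals from the three evidence streams are merged by
single-linkage bp overlap; a merged locus is retained when it is supported
by at least 2 distinct methods **or** at least 2 distinct comparisons
(mode `"and"` available). The operation is idempotent and independent of
input order, and is checked against a direct per-locus tag recount. Gene
annotation is strictly local (user-supplied BED); there is no network
access anywhere in the package.

## The synthetic-data generator

`simulateDivergentPops()` draws ancestral frequencies Uniform(0.05, 0.95)
and per-population frequencies from the Balding–Nichols beta distribution
`Beta(p(1−F)/F, (1−p)(1−F)/F)` (exactly p when F = 0), so the target F_ST
is an explicit, recoverable parameter. Haplotypes are Markov mosaics over a
population-specific founder pool: a switch to a random founder occurs
between adjacent SNPs with probability `1 − exp(−rate × gap)`. Defaults:

- `mosaic_switch_rate = 1e-6`/bp — LD decaying over a few hundred kb,
  qualitatively matching dense livestock arrays;
- `founders_per_pop = 2 × n_per_pop` — with a smaller pool (say 20), the
  realized pool frequency carries extra variance `pq/pool` around the
  Balding–Nichols draw, inflating Weir–Cockerham θ well beyond its sampling
  correction; matching the pool to the sample count makes the generator's F
  parameter recoverable by the estimator, which is what the acceptance
  checks require;
- missingness applies to genotypes only; haplotype sets stay complete, as
  the haplotype scans require.

The generator emulates allele-frequency divergence, blocky haplotype LD,
sweeps (fixed donor tract at a chosen carrier fraction), autozygosity
(second haplotype overwritten by the first over programmed tracts, merged
when overlapping, truth returned), relatedness (by construction duplicating
or mixing haplotypes in tests) and missingness. It does **not** emulate
coalescent genealogies, mutation-age structure, recombination hotspots,
genotyping error, or ascertainment bias of array SNP selection — so
passing recovery tests demonstrate estimator correctness under the stated
models, not robustness to real-data artifacts. Recovery scenarios that
require an outbred background (e.g. programmed-autozygosity recovery) raise
the switch rate to 1e-5 and widen the founder pool so that chance ROH are
effectively absent; the "study-condition" defaults above are otherwise
used unchanged.

`forwardWrightFisher()` is a desk-scale discrete-generation neutral model
(≤ 200 diploids, ≤ 500 generations): each offspring haplotype is a
Poisson-recombined gamete of a random parent with symmetric per-site
mutation. It serves as the independent oracle for the Sved N_E stage.

## Problem sizes and determinism

All simulations in the tests and the acceptance script run at desk scale,
chosen as the smallest sizes at which the estimators' sampling noise is
comfortably inside the asserted bands: 100 diploids/population × 5,000
SNPs for θ recovery, 40/population × 1,500 SNPs for sweep scans, 8,000
SNPs for ROH recovery, 50 diploids × 1,200 sites × 200 generations for the
Wright–Fisher oracle, and 2,500-SNP scans (3 pooled replicates) for null
calibration. Every generator takes a mandatory seed and is bit-reproducible
given it; the pipeline driver (`runPipeline()`) derives all stage seeds
from one integer and stamps every artifact with a provenance header.
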