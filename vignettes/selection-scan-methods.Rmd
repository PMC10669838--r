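---
title: "Methods: selection-signature scanning with sweepscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection-signature scanning with sweepscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## The problem

Resequenced populations of a domesticated species that have been under
different selection regimes (here, Chinese You-type chickens versus
European-origin broilers) accumulate localized genomic signatures:
elevated allele-frequency differentiation, unusually long shared
haplotypes, and allele-frequency spectra distorted toward fixation.
`sweepscan` implements the combined three-track scan for such signatures
on a phased multi-sample VCF with a sample-to-population map, together
with the population-diversity statistics used to characterize the
populations, and a seeded simulator so that every stage is testable
without external data.

## Statistics

### Per-SNP and genome-wide FST

Per SNP, `wc_fst_site()` computes the Weir–Cockerham variance-components
estimator \(\hat\theta = a/(a+b+c)\), where \(a\), \(b\), \(c\) are the
among-population, among-individual and within-individual components
estimated from per-population sample sizes, allele frequencies and
observed heterozygote frequencies. Sites monomorphic across all
populations are undefined (`NA`) and excluded from rankings; negative
estimates are kept as computed rather than clamped, since the
classification thresholds (below) are unaffected. Genome-wide and
pairwise values use the ratio-of-sums form \(\sum a / \sum(a+b+c)\), the
"weighted" estimate printed by VCFtools.

Allele-frequency differences are additionally tested per SNP with a
two-sided Fisher exact test on the 2×2 table of allele counts
(point-probability rule: the p-value sums all hypergeometric outcomes no
more probable than the observed table, with probabilities within a
relative \(10^{-7}\) counted as ties — the convention of standard exact
test implementations, pinned so results are bit-reproducible), followed
by Bonferroni correction over the number of SNPs in the comparison.

### XP-EHH

Extended haplotype homozygosity at distance \(x\) from a core SNP is the
probability that two haplotypes drawn without replacement are identical
at every site from the core out to \(x\):
\(\mathrm{EHH}(x) = \sum_h \binom{c_h}{2} / \binom{n}{2}\) over identity
classes \(c_h\). The cross-population statistic uses the joint
(unpartitioned-by-core-allele) variant, so \(\mathrm{EHH}(0) = 1\) over
all haplotypes; this is the form that enters XP-EHH, distinct from the
within-allele EHH of iHS. The curve is truncated when it falls below a
cutoff (default 0.05, linearly interpolated to the crossing), when an
inter-SNP gap exceeds 200 kb, or at the chromosome end; `ihh()`
integrates it by trapezoids over physical distance (no genetic map is
assumed), both directions summed. The per-SNP statistic is
\(\ln \mathrm{iHH}_A - \ln \mathrm{iHH}_B\) with the *object* population
A in the numerator, z-normalized genome-wide. Computing the raw score as
a difference of logarithms (not the log of the ratio) makes the
population-swap antisymmetry exact in floating point. Normalization is
genome-wide rather than per chromosome because the moments of small
simulated chromosomes are unstable; on whole-genome data the two choices
converge.

### Windowed composite likelihood ratio (XP-CLR style)

Chromosomes are tiled with non-overlapping 25 kb windows from position
1 (final partial window kept if it contains a SNP), each capped at 500
SNPs by deterministic uniform thinning. SNPs in a window are
down-weighted for linkage: single-linkage clusters on pairwise
\(r^2 > 0.95\) in the reference haplotypes share weight \(1/k\).
The neutral model drifts the object-population frequency \(q\) around
the reference frequency \(p\) with variance \(\omega\,p(1-p)\) (normal
approximation integrated on a 64-point grid with boundary point masses);
the sweep model mixes that density, with probability
\(c = e^{-\alpha d}\) at distance \(d\) from the window center, toward
fixation of either allele (weights \(p\) and \(1-p\)). The window score
is twice the weighted composite log-likelihood ratio maximized over a
log-spaced grid of \(\alpha \in [10^{-6}, 10^{-2}]\) per bp, floored at
zero (the \(\alpha \to \infty\) limit is the neutral model). Window
scores are z-normalized (`xpclr_norm`) and the top 1% of windows (the
\(k\)-th largest with \(k = \max(1, \lfloor 0.01\,n\rfloor)\), ties at
the threshold included) are called candidate windows; adjacent called
windows merge into regions. The drift scale is set from genome-wide
FST as \(\omega = F/(1-F)\), since the two quantities coincide to first
order under pure drift. Exact numeric parity with the original XPCLR
binary is not a goal; the contract is the window geometry, weighting,
normalization and top-fraction rule, validated by rank/recovery
behavior on simulated sweeps.

### Tiers and the seed-and-extend region caller

Per comparison, SNPs are classified per method:

* **FST track** — *extremely significant*: top 0.01% of FST **and**
  corrected \(p < 0.01\); *significant*: FST ≥ 0.4 **and** corrected
  \(p < 0.01\).
* **XP-EHH track** — *extremely significant*: top 0.1% of |normalized
  XP-EHH|; *significant*: |normalized XP-EHH| ≥ 1.

Quantiles are computed genome-wide over finite scores (per-chromosome
quantiles would be noisy on small genomes and the published rule names
no stratification); values exactly at the cutoff are included; `NA`
sites are nonsignificant and excluded from quantile computation.

Regions grow from each extreme SNP outward, crossing runs of one or two
nonsignificant SNPs (any significant or extreme SNP resets the counter)
and stopping at the first run of three ("more than two") consecutive
nonsignificant SNPs; a stretch delimited the same way containing more
than five significant SNPs and no extreme SNP is also a region. Region
boundaries sit on the outermost significant-or-extreme member SNP, so
regions never include trailing nonsignificant positions — the
conservative choice where the rule is silent, recorded in output
headers. After splitting each chromosome at runs of ≥ 3 nonsignificant
SNPs these two rules reduce to a closed form (a fragment is a region iff
it contains ≥ 1 extreme or > 5 significant SNPs, spanning its outermost
classified SNPs); the test suite proves the closed form equal to a
literal seed-walk implementation on **every** tier string of length 12
(531,441 cases), including the exactly-five rejection and the
three-in-a-row stop. Extension that absorbs further extreme SNPs
restarts the stop counter (the natural reading; the exhaustive test pins
it).

### Genes

Regions are annotated against `gene`-type GFF3 features by ≥ 1 bp
gene-body overlap, 1-based inclusive on both sides (no promoter/flank
extension by default; a `flank` argument exists). Per comparison, genes
supported by at least two of the three methods are the final candidates;
the intersection of two comparisons' final sets isolates signatures
specific to the shared object population.

### Diversity statistics

Observed heterozygosity is the unweighted mean over individuals of
per-individual heterozygous-call rates (per-individual `--het`
semantics averaged). Gene diversity is per-locus Nei diversity
\(1 - p^2 - q^2\) averaged over callable loci; because the published
description does not say whether a small-sample correction was applied,
both forms are computed and the \(2n/(2n-1)\)-corrected one is the
default report. IBS distance between two diploids is
\(\mathrm{mean}(|g_1 - g_2|)/2\) over pairwise-callable sites. QC
filters (MAF floor, exact Hardy–Weinberg test, missingness ceiling) are
applied in that order with first-failing-filter attribution; the HWE
test is the exact conditional test on heterozygote counts given allele
counts. The HWE and missingness cutoffs are not published; defaults are
\(10^{-6}\) and 0.1, both configurable and echoed into output headers.

## The simulator

`simulate_populations()` draws panels under the Balding–Nichols model:
ancestral frequency \(p \sim U(\mathrm{maf_{floor}}, 1-\mathrm{maf_{floor}})\),
population frequency \(\sim \mathrm{Beta}(p\frac{1-F}{F},
(1-p)\frac{1-F}{F})\), haplotype alleles i.i.d. Bernoulli. Per-population
\(F_i\) are solved from the requested pairwise matrix by least squares
under the small-\(F\) approximation \(F_{ij} \approx (F_i+F_j)/2\)
(exact for three populations); only realized FST is ever asserted.
\(F = 0\) degenerates cleanly to identical frequencies. Defaults mirror
the study conditions: three populations of 31/32/40 diploids, pairwise
FST targets 0.1681/0.1231/0.0946, a uniform-with-floor MAF spectrum,
and sweeps of 50 kb half-width reaching derived-allele frequency 0.98
with 90% carrier haplotypes.

A sweep overwrites the carrier fraction of target-population haplotypes
with one shared all-derived core haplotype across the span — haplotype
*identity*, not just frequency shift, because XP-EHH responds to
extended homozygosity — and redraws non-carriers at
\((f_{\mathrm{final}} - c)/(1 - c)\) so the realized site frequency
lands near \(f_{\mathrm{final}}\). What the generator does **not**
emulate: recombination and linkage decay (sites are independent outside
sweep cores), demography, mutation-rate heterogeneity, genotyping error,
and realistic LD structure. Passing tests therefore demonstrate
correctness of the statistics and callers and detection power under
idealized sweeps; they do not calibrate false-discovery rates for real
data, where background LD inflates haplotype statistics.

An option records BRA/BRB-style sub-line labels in the population map so
that the merge-on-read path is exercised; no claim is made about the
effect of merging on within-population variance.

## Numerical and design choices

* Coordinates are 1-based inclusive internally (VCF/GFF native); BED
  output converts to 0-based half-open at the boundary only.
* Multiallelic and non-SNP records are dropped (not split) with a
  logged count; all statistics here are biallelic.
* Chromosome order is natural-numeric where names permit, else
  lexicographic, recorded in output headers.
* Top-\(k\) selections use the \(k\)-th largest value with
  \(k = \max(1,\lfloor qn \rfloor)\) and ≥-comparison, so boundary ties
  are always included and a quantile never selects nothing.
* Z-normalization refuses fewer than two finite scores or zero
  variance rather than returning NaN.
* Monomorphic reference sites are excluded from window likelihoods
  (degenerate drift density); a window with none left is `NA`.
* Duplicating one sample set as "two populations" biases ratio-of-sums
  FST to about \(-\overline{p(1-p)}/(2(\bar n - 1))\) (zero
  between-population variance); near-zero FST is expected only for
  independent samples from one distribution.
* Scanning is deterministic: identical inputs give identical output
  files; the only randomness in the package is the simulator's seeded
  RNG.

## Problem sizes

The bundled tests and the acceptance script run entirely on simulated
panels: 20,000 SNP × 30-diploid pairs for parameter recovery (20 seeds
per nominal F), 5,000 SNP × 10 Mb panels for end-to-end sweep recovery
(20 seeds), exhaustive enumeration for the exact tests (all 2×2 tables
with total ≤ 60) and the region caller (all length-12 tier strings).
These sizes give stable Monte-Carlo acceptance margins while keeping a
full run in minutes on one core; all of them are package choices
declared in the scripts and tests, and scale linearly if enlarged.

## Known limitations

* The composite-likelihood scan is a re-derivation of the published
  construction, not a port; scores are comparable in rank, not value,
  with the original program's output.
* No genetic map: all distances are physical.
* The simulator's independence across sites makes neutral haplotype
  statistics better-behaved than in real data (see above).
* Unphased input is accepted for allele-frequency statistics only;
  haplotype statistics refuse it rather than guessing phase.
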