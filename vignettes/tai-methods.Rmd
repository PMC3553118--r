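---
title: "Quantifying genomic instability with the Total Aberration Index"
author: "taiseg package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying genomic instability with the Total Aberration Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taiseg)
```

## The problem

High-grade serous ovarian carcinomas are driven less by recurrent point
mutations than by widespread somatic copy-number aberration. A clinically
useful way to summarise that disorganisation is a single per-tumour burden
score that can be dichotomised (low/high) or entered continuously into
survival models. `taiseg` implements that workflow end to end: probe-level
log2-ratio profiles are segmented per chromosome, the per-sample burden is
summarised by the Total Aberration Index (TAI), and TAI is related to
clinicopathological variables and to progression-free and overall
survival.

## Segmentation model

Each chromosome of each sample is an ordered series $y_1, \dots, y_n$ of
log2 copy-number ratios. `pcf()` fits a piecewise-constant mean by exactly
minimising

$$\sum_{\text{segments } i}\;\sum_{j \in i} (y_j - \bar y_i)^2 \;+\;
  \gamma\,(k - 1),$$

over all segmentations into $k$ segments of at least `min_probes` probes
each. The penalty $\gamma$ per breakpoint controls the bias–variance
trade-off. The optimiser is an exact $O(n^2)$ dynamic program over the
last breakpoint (prefix sums for the within-segment sums of squares); no
pruning heuristics are used, because per-chromosome series at array
resolution (a few hundred to a few thousand probes) are well within reach
of the exact program. Cost ties are broken toward fewer segments, then
toward the earlier breakpoint, so results are deterministic.

Numerical choices:

* **Minimum segment size.** `min_probes = 3` by default, enforced inside
  the DP transitions. A chromosome with fewer than `min_probes` retained
  probes is returned as a single segment rather than discarded.
* **Penalty scale.** `gamma = 40` by default, interpreted on a
  noise-normalised scale: the penalty is multiplied by the square of a
  robust per-sample noise estimate (median absolute difference of
  consecutive probes divided by $\sqrt{2}\,\Phi^{-1}(3/4)$). This is
  algebraically identical to dividing the series by its noise SD before
  fitting, but keeps segment means on the original log2 scale, and it
  lets one default penalty serve platforms with different noise levels.
  Set `normalize = FALSE` to apply `gamma` on the raw scale.
* **Median centering.** Per-sample median centering (`center = TRUE` by
  default) anchors the diploid state at zero, making TAI a
  deviation-from-diploid measure even when a profile has a global offset.
* **Missing probes** are dropped per sample and chromosome before
  fitting; the DP needs a gap-free ordered series. Segments are still
  reported in bp over the retained probes.
* **Boundary convention.** A segment nominally spans first to last member
  probe; adjacent segments are extended to meet at the midpoint between
  flanking probes. Chromosome coverage is therefore gap-free, and the
  total span $\sum_i L_i$ does not depend on exactly where between two
  probes a breakpoint falls.

## The Total Aberration Index

With segment spans $L_i$ (bp) and means $\bar y_i$,

$$\mathrm{TAI} \;=\; \frac{\sum_i L_i\,\lvert \bar y_i \rvert}
                          {\sum_i L_i},$$

summed over all segments of all chromosomes (X included as
chromosome 23). TAI is the absolute deviation from the normal copy-number
state averaged over the genomic locations the platform covers; it grows
with both the abundance and the genomic size of aberrations, and is
insensitive to short focal events — it is a measure of broad genomic
disorganisation, not of driver-gene hits.

The denominator is the covered span rather than a fixed genome length.
Within one platform the two choices are monotone-equivalent, so the
median split and every rank-based comparison are unaffected; across
platforms absolute TAI values are not comparable (two cohorts on
different arrays have different medians as a matter of course).

Downstream, `tai_table()` attaches the cohort **median split** (high iff
strictly above the median; values exactly at the median go to the low
group, a deterministic tie rule that is flagged when it fires) and the
cohort **z-score** (n−1 SD), so Cox hazard ratios read "per 1 SD of
TAI".

## Group comparisons and survival

`build_table1()` reproduces the conventional cohort-characteristics
table: counts by TAI group with Mann–Whitney tests on grouped ordinal
characteristics (age group, stage, grade) and Fisher exact tests on
binary ones (chemotherapy response, progression). Two conventions are
fixed deliberately:

* The Mann–Whitney test uses midranks over the pooled grouped codes with
  tie-corrected variance, a 0.5 continuity correction and the normal
  approximation. On grouped ordinal data with heavy ties this — not the
  exact untied distribution — is the appropriate and reproducible
  convention; `soc_reference_counts()` carries printed counts from two
  published serous ovarian cancer cohorts on which this convention
  reproduces the published p-values to three decimals.
* The Fisher test is the two-sided sum-of-smaller-point-probabilities
  definition over the hypergeometric support.

`build_table2()` runs, per endpoint (PFS, OS): the log-rank test across
the median split, a univariate Cox model with TAI per SD, and a
multivariate Cox model adding age, stage and grade. Cox fits use Efron
tie handling (months-resolution follow-up ties heavily; Efron has lower
bias than Breslow under such ties). Stage and grade enter as numeric
ordinals by default; indicator coding is available
(`ordinal_covariates = FALSE`). Wald confidence intervals and p-values
are reported, as is conventional in such tables.

## The synthetic cohort generator

Because the package must be testable without array downloads,
`simulate_cohort()` generates cohorts with known truth. The generator
emulates:

* a probe map of 20,000 probes (default) allocated to 23 chromosomes in
  proportion to hg-like lengths totalling ~3.1 Gb;
* per sample, Poisson(15) non-overlapping aberrant intervals with
  log-uniform lengths of 2–120 Mb and discrete clean levels
  (±0.58 and ±1, i.e. one-copy gains/losses on a log2 scale, plus rare
  −3.3 homozygous deletions);
* attenuation by tumour-cell fraction $f \sim U(0.2, 0.9)$ via the
  linear-mixture formula $\log_2\!\left(f\,2^{\ell} + (1-f)\right)$,
  reproducing the damped ratios of impure tumour samples (the 20–90%
  purity range mirrors frozen-section tumour-cell percentages typical of
  such cohorts);
* probe-level Gaussian noise with SD 0.15, a realistic figure for
  two-channel aCGH ratios;
* clinical outcomes linked to the truth: overall survival exponential
  with log-hazard `beta_tai` per SD of true TAI (default −0.5,
  protective, the direction reported for high-grade serous disease)
  around a baseline of log(2)/32 per month (median survival 32 months),
  independent exponential censoring, PFS as a U(0.3, 1)-scaled copy of
  the latent survival time, and chemotherapy sensitivity from a logistic
  link on the same z-score.

The exponential/proportional-hazards generator is deliberately the
simplest model satisfying the assumptions the Cox stage makes, so
parameter-recovery tests are interpretable. The generator's "true TAI" is
computed by run-length encoding the clean (noise-free) probe profile and
applying the same TAI formula and boundary convention as the estimation
path, so in the zero-noise limit estimate and truth agree to numerical
precision.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: allele-specific signal, whole-genome
duplication and ploidy shifts, GC/wave artefacts, batch effects, probe
outliers, and semi-competing risks between progression and death (PFS is
a scaled copy of OS, adequate for exercising the survival plumbing but
not a clinical model).

## Verification strategy and problem sizes

The test suite checks each stage against an independent oracle at small
scale: the segmentation DP against exhaustive enumeration of all
admissible segmentations (series of ≤ 14 probes), Fisher p-values against
direct hypergeometric-support enumeration, the Mann–Whitney approximation
against the exact permutation distribution (groups of ≥ 5, where the
continuity-corrected normal approximation is within 0.02 of exact; below
that size the approximation error is larger and an exact test would be
preferred), Kaplan–Meier and log-rank against hand product-limit and
O/E/V computations, and the Cox fit against a grid search of the partial
likelihood.

Calibration runs use cohorts of 500 samples over 100 replicates for Cox
parameter recovery (mean bias below 0.05 log-hazard units, ~95% CI
coverage) and 500 replicates of 100 samples for log-rank null uniformity
(Kolmogorov–Smirnov), with small probe maps, since those checks exercise
the outcome link rather than segmentation. TAI fidelity (Pearson r
between estimated and true TAI above 0.95) is checked at full resolution:
100 samples, 20,000 probes, noise SD 0.15. These sizes keep the whole
suite comfortably reproducible on a laptop while leaving the statistical
checks well-powered.

## Known limitations

* The segmentation penalty has no universally correct value; the default
  (40 on the noise-normalised scale) is standard practice, but cohort
  TAI magnitudes shift with it. Comparisons within a cohort analysed at
  one setting are the supported use.
* Absolute TAI values are platform-specific (covered-span denominator);
  do not pool raw TAI across platforms.
* The grouped Mann–Whitney convention is intended for ordinal categories
  with many ties; for small untied samples use an exact test instead.
* No multi-sample joint segmentation, winsorisation, allele-specific
  fitting, proportional-hazards diagnostics or competing-risks handling.

## A worked example

```{r example, eval = FALSE}
co <- simulate_cohort(sim_params(n_samples = 40, seed = 1))
seg <- segment_profiles(co$cn, pipeline_config())
tai <- tai_table(seg)
t2 <- build_table2(co$clinical, tai)
t2
```

See the README for a full run with its printed output, and
`scripts/acceptance.R` for the script that recomputes the package's
headline quantities from scratch.
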