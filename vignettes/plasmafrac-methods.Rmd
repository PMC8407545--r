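---
title: "Methods: tumor-fraction estimation and classification from plasma cfDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-fraction estimation and classification from plasma cfDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmafrac)
```

## The problem

Malignant peripheral nerve sheath tumor (MPNST) is an aggressive sarcoma
that arises within benign plexiform neurofibroma (PN) in people with
neurofibromatosis type 1 (NF1). Because PN are common, anatomically complex
and only occasionally transform, and because imaging and biopsy both have
limited specificity for transformation, a blood-based marker is attractive.
`plasmafrac` implements an analysis of ultra-low-pass whole-genome
sequencing (ULP-WGS, ~0.1-1x) of plasma cell-free DNA (cfDNA) that exploits
two properties of circulating tumor DNA (ctDNA):

1. MPNST genomes carry copy-number alterations (CNAs) — arm-level gains
   (1q, 7p, 8q, 9q, 17q), arm losses (6p, 9p) and focal losses (*CDKN2A/B*,
   *MTAP*, *SMARCA2*, *SUZ12*, *NF1*) — whereas PN genomes are largely
   copy-neutral apart from the focal *NF1*-locus loss.
2. ctDNA fragments run shorter than the mono-nucleosomal (~167 bp)
   background, so an in silico size selection to 90-150 bp enriches the
   tumor-derived fraction of the fragment pool.

The pipeline: fragment records -> optional 90-150 bp size selection ->
counts in 1-Mb genome bins -> GC/mappability bias correction ->
panel-of-normals normalization -> per-bin log2 copy-number ratios ->
tumor-fraction inference by a two-component mixture with hidden-Markov
copy-number states -> ROC/Youden cutpoint classification of MPNST vs PN ->
serial monitoring against imaging (RECIST sum of longest diameters, SLD).

## The mixture model

A plasma sample is modeled as a mixture of tumor-derived fragments
(fraction $tf$) and non-tumor fragments (fraction $1-tf$, diploid). A bin
with tumor copy number $c$ then has expected depth ratio against a neutral
genome

$$r(c, tf) = \frac{tf \cdot c + (1 - tf)\cdot 2}{2},$$

and expected log2 ratio $\log_2 r$. Two anchors tie the model to the
gain/loss call thresholds: $\log_2 r(3, 1) = \log_2(3/2) \approx 0.58$ and
$\log_2 r(1, 1) = \log_2(1/2) = -1.0$; a bin is called a gain when its
corrected log2 ratio strictly exceeds 0.58 and a loss when strictly below
-1.0.

`fit_tumor_fraction()` treats the per-bin copy number as a hidden Markov
state (default states {1, 2, 3, 4}; the neutral state 2 is mandatory) with
Gaussian emissions centered on $\log_2 r(c, tf)$ and a shared,
re-estimated standard deviation. EM alternates forward-backward posteriors
(E-step) with a bounded 1-D maximization over $tf$ followed by a
closed-form variance update (M-step). Because each conditional step
increases the expected complete-data log-likelihood, the observed
log-likelihood is non-decreasing — asserted in the tests. The chain is
restarted from several initial $tf$ values (default
0.01...0.5) and the maximum-likelihood restart is reported. Chains restart
at chromosome boundaries; state transitions between adjacent bins keep
probability 0.9999 on the diagonal.

At $tf = 0$ every state mean collapses to 0 and the likelihood is flat in
$tf$, so arbitrarily small estimates are unidentifiable; estimates below a
detection floor (default 0.03) are reported as "not detected". The floor
sits below the classifier's typical operating cutpoint and above the
background produced by residual technical bias in the synthetic
non-malignant profiles.

Design choices made where the design was genuinely open: emissions are
Gaussian rather than Student-t (a simpler M-step at the scale this package
targets); $tf$ is shared genome-wide with no subclonal levels; the
non-tumor component is fixed diploid with no ploidy search; and the
transition matrix is a uniform small-switch-probability matrix rather than
a distance-dependent one. The forward-backward and Viterbi kernels are
compiled (Rcpp), as is usual for coverage HMMs.

## Bias correction and panel of normals

`correct_bias()` masks sex-chromosomal bins, bins with mappability below
0.9, and zero-count bins; fits a robust LOESS (span 0.3, two iterations)
of log2 count against GC over unmasked bins and subtracts it; divides by
mappability; and takes log2 against the sample median, re-centering so the
unmasked median is exactly 0. Median centering assumes a majority-neutral
genome — a documented limitation for extreme aneuploidy.
`panel_normalize()` subtracts the per-bin median of a healthy reference
panel (each sample is left out of its own panel) and masks bins whose
panel median absolute deviation exceeds a cap (default 0.2 log2 units).
The cap is calibrated for deep profiles; at shallow desk-scale depth the
counting-noise floor of the panel MAD approaches it, and the analysis
scripts raise it to ~2x the median panel MAD in that regime.

## The synthetic cohort generator

No sequencing data accompany the study this design targets, so the
generator is a first-class module that emulates the cohort's statistical
structure, and every claim the tests make is a claim about data with this
structure:

* **Cohort**: 16 healthy donors and 23 PN participants with one plasma
  sample each; 14 MPNST participants with serial draws assigned by
  permuting a fixed multiset totalling 46 samples (mean 3.3, maximum 6),
  giving 85 plasma samples in total.
* **Genome**: a 1.0-Gb toy genome of 8 autosomes (plus a masked chrX) in
  1-Mb bins; GC drawn from a smooth per-chromosome spatial process in
  [0.3, 0.6]; mappability near 1 with 3% low-mappability bins. Named
  focal loci (NF1, SUZ12, CDKN2A/B, MTAP, SMARCA2) sit at fixed toy
  coordinates; arm-level events map onto toy chromosome arms.
* **CNA profiles**: healthy draws are event-free; PN always carry the
  focal NF1-locus loss (copy 1) plus CDKN2B/SUZ12 losses with small
  probability (0.08) and SMARCA2 never at the default; MPNST carry NF1 and
  SUZ12 losses plus each arm/focal catalogue event with probability 0.5.
* **Tumor fraction**: MPNST baselines are Uniform(0.04, 0.40) with
  response, relapse or progression trajectory shapes over serial draws;
  healthy and PN shed no tumor DNA ($tf = 0$).
* **Fragments**: a fragment is tumor-derived with probability
  proportional to $tf \cdot c_b/2$ against $(1-tf)$; bins are chosen with
  weight copy number x GC bias x mappability; lengths come from the
  origin's component of the length model — healthy
  $0.85\,N(167, 25^2) + 0.15\,N(320, 40^2)$, tumor $N(145, 25^2)$,
  truncated to [60, 450] bp. These reproduce the qualitative facts
  (tumor-derived fragments shorter; enrichment below ~150 bp) without
  claiming the study's exact densities.
* **Depth and technical structure**: 400,000 fragments per sample, so
  that after 90-150 bp selection the per-bin counting noise (~0.16 log2
  units) does not dominate; a per-sample smooth coverage wave
  (sd 0.05 log2, ~10-bin correlation length) models residual
  sample-specific bias that survives GC correction and panel
  normalization. The wave — not counting noise — limits specificity, which
  is what produces a nonzero background tumor-fraction floor in
  non-malignant samples and motivates the detection floor, mirroring the
  background reported for real non-malignant plasma. A negative-binomial
  per-bin count shortcut (`simulate_bin_counts()`) bypasses fragments for
  fast parameter-recovery tests.
* **Imaging**: SLD (cm) is an affine function of true tumor fraction
  (intercept 3, slope 25, noise sd 1) observed at days jittered up to 15
  days from plasma draws; RECIST labels follow the standard +20%/-30%
  rules against baseline. Therapy begins shortly before each treated
  participant's second draw; washout labeling honors the 21-day rule.

All generators are pure functions of (config, seed); per-stage seeds
derive from the global seed as
`(seed * 7919 + FNV1a(stage)) mod (2^31 - 1)`.

What the generator does **not** emulate: real nucleosome-positioning
fragmentation structure, sequence-level errors, subclonal heterogeneity,
inter-patient variation in cfDNA yield, genuine hg19 GC/mappability
tracks, or the study's exact tumor-fraction distribution. Passing tests
therefore demonstrate that the pipeline inverts its own forward model
under study-shaped conditions — not clinical performance on real plasma.

## Statistical components

Group comparisons use the Kruskal-Wallis H test with Dunn pairwise z
tests, Bonferroni-adjusted and capped at 1. The ROC is the empirical curve
over midpoint thresholds with the rule score > threshold => malignant; AUC
is the trapezoid area (equal to the tie-corrected Mann-Whitney
concordance, asserted against enumeration in the tests) and the operating
point maximizes Youden's J with ties broken toward higher specificity —
the high-specificity choice a screening application favors. Cutpoints are
stored at full precision and rounded only for display.
Cross-validation is leave-one-out with a ridge-penalized logistic
regression (penalty chosen by inner 5-fold CV on each training fold; the
explicit penalized IRLS keeps degenerate training folds well-posed and
lets tests compare folds against direct penalized-likelihood
optimization); accuracy carries a Clopper-Pearson interval at the unit of
classification (participants). The multivariate model is a
maximum-likelihood logistic regression of status on tumor fraction, age,
sex and institution with Wald tests; perfect separation and rank
deficiency are reported as flags. Power analysis inverts the noncentral-F
power function of the one-way ANOVA (noncentrality $f^2 k n$). Follow-up
time uses the reverse Kaplan-Meier estimator.

The primary comparison takes one baseline sample per participant —
samples drawn before any treatment or at least 21 days after completing
chemo/radiotherapy; the serial variant takes each participant's maximum
tumor fraction over qualifying draws. Serial trajectories are normalized
per participant to the lowest detected value and log2-transformed;
undetected timepoints are drawn one log2 unit below the series minimum
rather than at $-\infty$. Plasma-to-imaging matching takes the nearest SLD
within 30 days (inclusive) with no therapy change strictly between the two
dates, breaking gap ties toward the earlier SLD. Molecular lead time is
the gap between re-detection of tumor fraction after an undetected nadir
and the first radiographic progression (first PD label by default, or the
first nonzero SLD after a zero-SLD interval for post-resection
surveillance).

## Numerical choices and degenerate inputs

Size-selection bounds are inclusive ([90, 150]). Kernel-density bandwidth
defaults to Silverman's rule. KS p-values use the asymptotic Kolmogorov
distribution at the effective sample size; D is computed exactly under
ties. Density ratios floor densities at 1e-8 before the log. Fragment
midpoints decide bin membership, so edge-spanning fragments are counted
once. Empty fragment files parse to empty tables; fits require at least
100 unmasked bins and corrections at least 50; EM non-convergence is
returned as a flag, never raised. Youden tie detection uses a 1e-9
tolerance so exact ties in sensitivity + specificity are recognized in
floating point.

## Problem sizes

The default study-scale run — 85 fragment-level samples of 400,000
fragments, fitted with and without size selection — completes in a few
minutes on one core; unit tests use smaller grids (hundreds of bins,
tens of thousands of fragments) and the count-level shortcut where only
single components are under test.

## Known limitations

Selected-mode tumor fractions estimate the tumor fraction of the
*size-selected* pool, which is systematically higher than the unselected
fraction — the enrichment is the point, but the two scales should not be
mixed. The detection floor is a reporting rule, not a statistical test.
Median centering biases profiles with pervasive aneuploidy. The Gaussian
emission model is sensitive to heavy-tailed outliers that a t emission
would absorb. The classifier is trained and evaluated on synthetic
cohorts; no claim about real-world sensitivity/specificity follows.
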