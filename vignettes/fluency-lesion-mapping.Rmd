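---
title: "Lesion-symptom mapping of verbal fluency: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-symptom mapping of verbal fluency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluencymap)
```

# The analysis model

`fluencymap` asks, voxel by voxel, whether stroke patients with a lesion at
that location perform worse on a behavioral test than patients without one.
The chain has five statistical stages, each with explicit assumptions.

## Behavioral scores and demographic adjustment

Semantic fluency is the count of correct, non-repeated animals named in
2 minutes; phonemic fluency is the sum of correct, non-repeated words over
the N and A letter trials (1 minute each), missing if either trial is
missing. Counts are then converted to z scores *within the cohort*: each
raw score is regressed on age, sex (0/1) and education (the 1–7 ordinal
scale entered as a single linear covariate; categorical coding is available
via `education_coding`), and

$$z_i = \frac{r_i}{\hat\sigma}, \qquad
  \hat\sigma^2 = \frac{\sum_i r_i^2}{n - p}$$

with \(r_i\) the least-squares residual. Two choices here were genuinely
open:

* **Residual-SD denominator.** We use the regression residual degrees of
  freedom \(n - p\). A plain \(n - 1\) denominator would change every z by
  the constant factor \(\sqrt{(n-p)/(n-1)}\) (about 1.6% at \(n = 93\),
  \(p = 4\)) and no downstream decision, since every analysis of z is
  scale-equivariant. The choice is recorded in the output metadata.
* **Sample- vs. norm-referenced adjustment.** The regression is fit on the
  cohort itself (sample-referenced): z means "performance relative to
  patients with the same demographics in this cohort". Published normative
  equations could be substituted upstream; only the dichotomization stage
  uses external norms.

Adjustment is per test with pairwise (per-test) deletion, so tests with
missing data keep their own n. Constant demographic covariates are aliased
and dropped with a warning (the adjustment then collapses toward plain
standardization); a zero-residual-variance test is rejected by name.

## Dichotomization

A score strictly below the normative 5th-percentile cutoff is impaired;
ties at the cutoff are not. Cutoffs are supplied as a `{test, cutoff}`
table because real normative values are language- and population-specific;
for synthetic cohorts `synthetic_norm_table()` derives them as the
empirical 5th percentile of a large lesion-free sample drawn from the same
generative model (fixed internal seed, so the norms are stable).

## Voxel-wise statistics

Voxels lesioned in fewer than `min_count = 3` patients are untested — with
fewer lesioned subjects the group comparison is meaningless, and because
no out-of-brain voxel is ever lesioned the count threshold doubles as a
brain mask. Voxels lesioned in *every* subject are likewise untested (no
intact group). At each tested voxel the default statistic is the
pooled-variance Student t comparing z between intact and lesioned subjects
(the classic VLSM choice; Welch is available via `var_equal = FALSE`),
signed so that **positive = lesioned worse**, with

* one-tailed p in the lesion-deficit direction by default. The signed map is
  retained for display, so a "lesioned better" voxel is visible but can
  never be significant. This matches the display logic of lesion-mapping
  software, where only the deficit direction is thresholded; the FDR is
  accordingly computed over one-tailed p values — an assumption, flagged
  here, since two-tailed FDR would be slightly more conservative
  (`tails = "two"` switches both).
* The Brunner–Munzel rank statistic (`statistic = "brunner_munzel"`) as the
  non-parametric alternative, with Satterthwaite degrees of freedom. It is
  invariant under monotone transforms of z. With group sizes under 10 the
  t approximation is anticonservative; the result records a caveat flag.
* Zero-variance voxels yield statistic 0 and p = 1 and are flagged rather
  than dropped, keeping the map total.
* Subjects missing the outcome are excluded from that outcome's analysis —
  equivalent to voxel-wise exclusion, since the same subjects are missing
  everywhere. Voxels whose lesioned or intact group empties after exclusion
  leave the tested set for that outcome.

The vectorized implementation (sufficient statistics via one matrix product
per moment) is contractually identical to a per-voxel loop; a test asserts
this against an independent per-voxel oracle.

## FDR control

Benjamini–Hochberg step-up over the tested voxels at `q = 0.05`: the
realized cutoff is the largest \(p_{(k)} \le kq/m\); all p at or below it
are significant; no qualifying k gives an empty set and cutoff 0. Plain BH
(no dependency correction) is the standard in this literature; under the
positive dependence induced by overlapping lesions it remains valid. A
200-cohort global-null simulation in the acceptance suite checks the
empirical false-discovery proportion against q.

## Subtraction maps and ROI regressions

The subtraction map is purely descriptive — percentage-point difference in
lesion prevalence between impaired and normal groups, in [−100, 100], with
no thresholding; display values round half-up to integer percent (3/18
impaired vs 0/75 normal shows as 17%) while exact values are retained.

Atlas regions with at least `min_sig = 100` significant voxels for an
outcome are selected; the union of selected regions is then modeled for
*both* outcomes so each reported region carries both fits. Per region the
hierarchical regression is

base: z ~ age + sex + education (+ total infarct volume, if adjusting)
full: base + regional infarct volume (ml)

with the ΔR² p value from the partial F test — for a single added regressor
identical to the coefficient's two-sided t test, which a test asserts to
1e-10 — and B reported per 1 ml with a t-based 95% CI. Listwise deletion
within each fit; n is recorded. A regional volume that is constant over the
complete cases is returned as a degenerate fit (ΔR² = 0, p = 1, B = NA)
rather than an error; genuine collinearity (e.g. regional volume equal to
total volume) is rejected with a diagnostic. Total-volume adjustment is
deliberately applied at the ROI stage, not in the voxel-wise tests: the
voxel stage adjusts the behavior for demographics only, and the ROI models
ask whether a region predicts performance *independent of* overall lesion
burden.

## Descriptives

Lesion laterality is classified from template-space coordinates: all
lesioned voxels strictly left (world x < 0) or right of the midline give
that hemisphere; a lesion confined to the infratentorial compartment (when
a compartment labeling is available, as in the toy space) is
infratentorial; anything spanning sides or compartments is "multiple". A
configurable midline band (default width 0 mm) can exclude paramedian
voxels from the side count. Percentages in the impairment-by-laterality
table are within impairment group and display with half-up integer
rounding.

# The synthetic cohort generator

The generator exists so that every stage has a testable ground truth; its
defaults describe the cohort the package emulates: 93 first-ever ischemic
stroke patients on a 32×32×32 toy grid at 2 mm (a half-resolution analogue
of a 1 mm template; voxel volume 8 mm³).

* **Space.** A deterministic ellipsoidal brain mask; the bottom 22% of
  axial slices form an infratentorial analogue; seven box-shaped atlas
  regions (left middle/inferior frontal, left temporal, left parietal,
  right frontal, right temporal, infratentorial) intersected with the mask.
* **Lesions.** Stochastic region growing: from a random seed voxel, a
  uniformly chosen 6-connected boundary voxel is added until the target
  volume (uniform in 50–800 voxels, i.e. 0.4–6.4 ml) is reached, confined
  to the site drawn per subject — left 0.37, right 0.43, infratentorial
  0.12, bilateral 0.08, echoing the right-leaning territory prevalence of
  such cohorts. Growth is a compiled kernel driven by R's RNG, so a single
  `set.seed()` makes the whole cohort reproducible.
* **Behavior.** raw = baseline + β_age(age−60) + β_sex·sex + β_edu(edu−5) +
  Σ_r w_r·(lesioned ml in region r) + N(0, σ), clipped at 0 and rounded to
  a count. Defaults: animals 24 ± 6 (w = −9/ml on the left temporal
  analogue), letter trials 8 ± 3 each (w = −3.5/ml each on the left middle
  frontal analogue), so the two fluency outcomes form a built-in double
  dissociation. Four additional test columns (list-learning, figure recall,
  naming, comprehension analogues) have their own causal regions and
  missing-completely-at-random rates of 4/93, 8/93, 2/93 and 8/93,
  exercising the pairwise-n bookkeeping.
* **Truth segregation.** Generative weights, causal regions and sites are
  stored in `cohort$truth` and written to a separate
  `synthetic_truth.json`; no analysis function reads them.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: registration and segmentation error (lesions are
exact), vascular-territory shapes (growth is isotropic within a
compartment), spatially correlated lesion co-occurrence beyond what random
overlap produces, and a shared cognitive factor across tests. The last
point is visible in the synthetic correlation table: after demographic
adjustment, semantic–phonemic correlations are near zero unless causal
regions overlap, whereas real fluency scores correlate strongly. The
correlation stage is therefore validated against closed-form oracles, not
against a target correlation structure.

# Numerical choices and degenerate inputs

* Affine comparison tolerance 1e-4 mm per element (absolute), configurable:
  tight enough to catch a wrong template, loose enough for float drift.
* Lesion binarization: any strictly positive voxel value becomes 1
  (interpolation can leave fractional values in nominally binary masks).
* All cross-volume operations require identical grids; there is no
  resampling — registration is out of scope by design.
* Percent displays round half away from zero; exact values are always kept
  alongside.
* Degenerate statistics (all-tied scores at a voxel, complete separation in
  the rank test, constant regional volumes) are returned as flagged,
  well-defined results wherever a total map or table is more useful than an
  error; impossible requests (empty groups, unknown regions or cutoffs,
  unattainable lesion volumes, collinear designs) fail loudly with names.

# Problem sizes

The test suite and acceptance script size their simulations to what the
statistics need rather than to imaging realism: 200 replicate cohorts
(n = 93, 32³ grid) for the null false-discovery check, 200 replicates of
n = 500 for CI coverage, n = 500–1000 for orthogonality and recovery
checks, and single fixed-seed cohorts of n = 93 for the end-to-end double
dissociation. On one CPU the full suite runs in about a minute.

# Known limitations

* One-tailed FDR is an interpretive choice (see above); two-tailed mode
  exists but is not the default.
* The Brunner–Munzel small-sample caveat is a flag, not a correction; no
  permutation inference is implemented.
* Education is modeled linearly by default; with few subjects per category
  the categorical mode can be rank-deficient.
* The toy atlas is rectangular and coarse; region-boundary effects of real
  parcellations (partial volume, interdigitation) are not represented.
* Lesion-size confounding is handled only via the total-volume covariate in
  the ROI stage, as in the design the package follows.
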