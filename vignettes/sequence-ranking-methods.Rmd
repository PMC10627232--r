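---
title: "Ranking MRI sequences by image quality: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking MRI sequences by image quality: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rubriq)
```

## The problem rubriq solves

When several candidate MRI sequences (for instance fat-suppressed SPAIR
T2-weighted variants for MR-guided radiotherapy) compete for a clinical
role, the choice should rest on measurable image quality per anatomical
structure — tumour, nodes, organs at risk — and not on a single reader's
impression. `rubriq` turns a multi-subject, multi-observer segmentation
study into a ranked verdict in four stages: metric computation, pooling,
distribution-adaptive significance testing, and a significance-gated rank
rubric. This vignette explains each model, its assumptions, the tunable
parameters, and the places where the design was genuinely open.

## Metrics

**SNR and CNR.** For each (sequence, structure, subject),
`SNR = mean(ROI)/SD(noise)`, where the noise SD comes from an air-cavity
segmentation (sample SD, denominator $n-1$) because the region outside the
patient is typically masked during postprocessing and cannot serve as a
noise estimate. All observers' ROI voxels contribute to the mean with
multiplicity, so duplicated contours do not bias it. CNR is the signed SNR
difference against a reference tissue — fat, or the pterygoid muscle. The
muscle-referenced CNR of the pterygoid itself is identically zero and is
excluded. The fat SNR is computed once per sequence as a fat-suppression
measure and is *lower-is-better*; it enters the SNR/CNR category of every
structure (structure-agnostic broadcast). One value per subject enters
statistics, so these metrics have sample size = number of subjects — they
are the least powered metrics in the pipeline, by design honest to the
study bookkeeping.

**Conspicuity.** Visibility of a structure against its local surround,
evaluated per axial slice (the delineation plane) from 3D spacing-aware
morphology of the observer's mask:

* core = mask contracted by 1 mm — a guard band that keeps
  partial-volume boundary voxels out of the structure estimate;
* ring = expansion by 2 mm minus expansion by 1 mm — the local surround,
  again guarded;
* conspicuity = `|mean(core) − mean(ring)| / SD(ring)` on the slice.

The contraction/expansion distances (default 1 and 2 mm) are the only
geometry parameters. Because several conspicuity formulations exist in the
literature, the ratio is isolated in `slice_conspicuity()` so an
alternative contrast or complexity reading can be swapped without touching
the pipeline. Slices whose core or ring is empty are skipped; a ring with
SD below `eps_floor` (default $10^{-6}\times$ the volume's intensity
range) caps the value at `contrast/eps_floor` instead of dividing by ~0 —
only noiseless synthetic images ever reach this floor. Slice values are
pooled over observers, subjects (and left/right sides), then trimmed to
the inner 90% band.

**Inter-observer agreement.** For all `choose(observers, 2)` pairs:
Dice `2|A∩B|/(|A|+|B|)` and HD95, the 95th percentile of the concatenated
bidirectional minimum surface-to-surface distances in mm. Surface voxels
are mask voxels with a face neighbour outside the mask (the grid border
counts as outside); distances use voxel centres and physical spacing; the
percentile interpolates linearly between order statistics — fixed and
documented so results are bit-stable. These are precision (consistency)
metrics: no ground truth is assumed on real data.

**Qualitative metrics.** Observer preference grades (rank 1 = most
preferred of the S sequences) are mapped to higher-is-better scores
`S + 1 − rank` so that every metric shares one direction convention.
The comment metric `(#positive − #negative)/#possible` summarises
free-text feedback that has already been classified into
positive/neutral/negative; classification itself is out of scope (it was a
manual step in the motivating study, and no classifier specification
exists). Neutral comments are deliberately absent from the numerator: the
baseline opinion of a sequence is taken to be neutral.

## Pooling and outlier handling

Slice-wise and pairwise metric stacks are trimmed to the symmetric inner
90% of their empirical distribution (`pool_and_filter()`, closed
[5th, 95th] percentile band, linear-interpolation percentiles). Two-sided
trimming is the natural reading of an outlier guard: single-sided trimming
would bias the central tendency. Applied to a `metric_sample` the filter
is idempotent — a filtered sample carries a flag and is never re-trimmed.
Expected sample sizes after pooling:

| metric | sample size |
|---|---|
| SNR, CNR, fat SNR | subjects |
| conspicuity | ≈ 0.9 × slices × subjects × observers |
| DSC, HD95 | ≈ 0.9 × subjects × C(observers, 2) |
| grade | observers × subjects |
| comment metric | subjects |

Left/right organs (parotids, pterygoids) are delineated per side but
pooled into a single bilateral structure before statistics, matching
summary tables that carry one parotid and one pterygoid column; the
alternative (per-side analysis followed by score averaging) would halve
every sample and was rejected for power reasons.

## The statistics gate

Pooled samples for one (metric, structure) across sequences pass through:

1. **Normality screen** — Kolmogorov–Smirnov in its Lilliefors form
   (mean and SD estimated from the sample, as they always are in
   practice; a plain KS test against fixed parameters would be
   anti-conservative). All groups must pass at α = 0.05 for the
   parametric branch. Groups with fewer than 5 values cannot be screened
   (the Lilliefors tables start at n = 5) and force the nonparametric
   branch with a warning — this affects subject-level metrics in small
   studies and is intentional: when normality cannot be assessed, the
   rank-based branch is the safe default.
2. **Omnibus + pairwise** — parametric: one-way ANOVA with Tukey HSD;
   nonparametric: Kruskal–Wallis with Dunn's rank-sum z tests
   (tie-corrected) and a Bonferroni-family multiplicity adjustment
   (`p_adjust_method`, any `p.adjust` family). Dunn's test is implemented
   in the package because no installed post-hoc package provides it; for
   two groups its squared z statistic equals the Kruskal–Wallis H, which
   the test suite uses as an independent cross-check.
3. **Gating** — pairwise significance is honoured only when the omnibus
   test is itself significant at α (`gate_omnibus = TRUE` by default,
   mirroring the "follow-up test" structure of classical workflows; it
   can be disabled).

Pooled values are treated as independent draws; repeated-measures
structure across subjects and observers is not modelled (no mixed
effects), which matches the sample-size bookkeeping above and keeps the
gate assumptions transparent. Central tendencies reported (and used for
ranking) are means/SDs on the parametric branch, medians/IQRs otherwise.
Fully degenerate inputs (all values identical everywhere) report p = 1
throughout.

## The scoring rubric

For each (metric, structure), sequences are ordered best-to-worst by
central tendency under the metric's direction (higher-better: SNR, CNRs,
conspicuity, DSC, grade, comment; lower-better: fat SNR, HD95). A tier
boundary between ordered positions *i* and *i+1* is placed only when
**every** sequence at or above *i* is pairwise-significant against
**every** sequence at or below *i+1*. This strong reading — rather than
requiring significance only against the adjacent sequence — is the only
one that is order-consistent (a boundary cannot depend on how ties above
it are resolved) and that reproduces the observed behaviour of fully
tied qualitative rows in the motivating study. Tiers receive descending
scores and are rescaled to the average of the consecutive ranks they span
({4, 2, 2, 1} → {4, 2.5, 2.5, 1}); every scoring stage therefore
conserves total rank mass S(S+1)/2 across sequences.

Aggregation proceeds: metric scores → (weighted) category sums → rank
across sequences within structure = **normalized category scores** →
(weighted) sums = **total scores** → rank = **normalized total scores** →
(structure-weighted) sums across structures = **combined total** and
**combined normalized** scores. Re-ranking at each joint means a category
with many metrics weighs the same as a category with one.

**Combined-normalized ambiguity.** Two readings of the final stage exist:
rank the combined totals, or rank the per-sequence sums of normalized
total scores. They genuinely differ (per-structure normalization
equalises structures before summing; raw totals do not) and the reference
summary table we reproduce is consistent only with the second. Both are
computed — `combined_normalized` (default, sums of normalized totals) and
`combined_normalized_alt` (combined totals) — so the choice is visible
rather than silent.

Weights default to 1 and can be applied per metric, per category, and per
structure at the three summation joints.

## The digital phantom

`generate_phantom()` emulates the study the pipeline expects: a cuboid of
soft tissue (default 48×48×30 voxels at 2 mm) holding axis-aligned
ellipsoids for the GTV, two lymph nodes, two parotids and two pterygoids,
two lateral fat pads, and a tubular air cavity for the noise ROI; by
default 4 sequences, 5 subjects and 5 observers, matching a typical
sequence-selection study. Voxels are `tissue mean + N(0, noise SD)`; the
fat mean is multiplied by a per-sequence suppression factor; a
per-sequence contrast scale multiplies every non-fat tissue's deviation
from background. Default means (background 150, muscle 120, parotid 250,
nodes 280, GTV 300, fat 420, noise SD 12) are plausible relative
T2-weighted tissue intensities in arbitrary scanner units; their absolute
scale is irrelevant because every metric is scale-invariant by
construction.

Observer variability is a random isotropic dilation/erosion (radius
uniform in ±1.5 mm by default) plus a Gaussian voxel translation
(SD 0.75 mm), which reproduces realistic Dice/HD95 ranges (~0.8–0.95 /
1–4 mm on 10–15 mm structures). An erosion that would empty a mask is
retried with halved radius and logged. All randomness flows from one
config seed.

The noise model is additive Gaussian, not Rician: the pipeline's noise
estimate is an SD over an air ROI on magnitude-like data and none of the
metrics assume a noise family, while Gaussian noise keeps the
SNR-recovery oracle exact. The phantom deliberately omits MRI physics —
no k-space, coil profiles, B0/B1 inhomogeneity, ghosting or burnout —
so passing phantom tests demonstrates that the *pipeline* measures what
it claims (parameter recovery, correct ordering under known contrast
advantages, calibrated type-I error) and not that any given clinical
sequence is superior; conclusions about real sequences require real data.

Voxel-centre distance conventions mean sub-voxel morphology is only
meaningful when morph distances are comparable to the spacing: at 3 mm
isotropic spacing a 1–2 mm expansion cannot reach a neighbouring voxel
centre and the conspicuity ring would be empty. The default 2 mm spacing
is chosen so the standard 1 and 2 mm morphs behave as intended.

## Numerical choices

* Distance transforms use the exact separable parabola-envelope algorithm
  (compiled, spacing-aware), cropped to padded bounding boxes for speed;
  equality at a morph threshold is resolved inclusively for expansion and
  exclusively for contraction, with a 10⁻⁷ mm tolerance against
  floating-point ties.
* All percentiles (inner-band filter, HD95) use linear interpolation
  between order statistics (R's type 7), stated once and used everywhere.
* Rank ties anywhere in scoring use average ranks.
* Sequence order is preserved from the input study; ranking ties in
  central tendency break stably by that order, which only matters when
  the gate already reports the pair indistinguishable.

## Problem sizes used in the test-suite

Simulation-based checks run on reduced designs chosen to keep the suite
quick while leaving the quantities being verified unchanged in
expectation: a 44×44×28-voxel phantom at 2 mm, 2–5 subjects, 2–3
observers, 2–3 sequences; ordering-recovery checks use 100 seeded
replicates and the gate-calibration check uses 1,000 null replicates at
n = 25 per group. The statistical tolerances (3 standard errors for
recovery checks, ±0.02 around the nominal level for calibration) are
stated in the tests themselves.

## Known limitations

* No registration or resampling: volumes and masks must share one grid.
* No DICOM RT-STRUCT ingestion; masks are NIfTI.
* Pooled values are treated as independent; observer and subject random
  effects are not modelled.
* The comment metric consumes pre-classified counts, not free text.
* The conspicuity formulation is one admissible reading of
  contrast-over-surround-complexity; it is isolated behind a single
  function precisely because the literature admits variants.
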