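---
title: "Simulating and decoding arithmetic fMRI in dyslexia and dyscalculia"
author: "arithmvpa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decoding arithmetic fMRI in dyslexia and dyscalculia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arithmvpa)
```

## The scientific question

Developmental dyslexia (DL) and developmental dyscalculia (DC) frequently
co-occur, and a central question is whether they reflect distinct or shared
neural alterations during arithmetic. Voxelwise group contrasts answer a
different question than pattern analysis does: two disorder groups can both
show no mean difference from controls voxel-by-voxel while still carrying
group information in the *spatial pattern* of activation across a region.
`arithmvpa` implements the full analysis chain for a four-group
block-design arithmetic study — typically developing children (TD), DL-only,
DC-only, and comorbid (DLDC) — together with a synthetic-cohort generator,
so every stage of the chain can be exercised and validated without access
to the original children's data, which are not publicly deposited.

The decisive instrument is the **subject-generalization test**: a linear
classifier trained to separate controls from one disorder group is tested
on separating controls from the *other* disorder group. It can only succeed
if the two disorders deviate from controls along similar pattern
directions. The simulator makes that similarity an explicit, tunable
parameter, so the test's behaviour can be verified against ground truth.

## The synthetic cohort

`simulate_cohort()` draws, under a single seed with per-component
substreams:

* **Task designs** (`generate_run_design()`). One run alternates 15-s
  fixation blocks with 15-s format blocks. A format block holds a 900-ms
  reference-magnitude presentation and three subtraction trials (300-ms
  fixation + 4400-ms item), so a block lasts
  $0.9 + 3 \times 4.7 = 15$ s, giving 12 trials per format per run across
  four blocks, in three formats (dot arrays, Arabic digits, number words),
  over four runs with reference magnitudes in the fixed order 4, 5, 4, 5.
  The number and placement of fixation blocks beyond strict alternation is
  a simulator convention (we lead and close with fixation, 25 blocks,
  375 s, 125 scans at TR = 3 s); block order within a run is a seeded
  permutation balanced in cycles of the three formats, avoiding order
  confounds.
* **Motion traces** (`generate_motion_trace()`): a six-parameter random
  walk (per-step sd `severity` mm; rotations scaled so their arc length at
  50 mm matches), with an optional spike (default 3 mm on two consecutive
  transitions) injected into a configurable fraction of runs (default 10%,
  matching the share of runs the QC stage is expected to discard).
* **Latent amplitude maps** (`generate_amplitude_maps()`). For subject $i$
  in group $g$ and format $f$:
  $$A_i = \mu_f + z_{DL}(g)\,d_{DL} + z_{DC}(g)\,d_{DC} + \varepsilon_i,
  \qquad \varepsilon_i \sim N(0, \sigma_s^2 I),$$
  with
  $d_{DL} = \delta(\sqrt{\rho}\,s + \sqrt{1-\rho}\,u_{DL})$ and
  $d_{DC} = \delta(\sqrt{\rho}\,s + \sqrt{1-\rho}\,u_{DC})$ built from
  orthonormal voxel patterns $s, u_{DL}, u_{DC}$, so
  $\mathrm{cor}(d_{DL}, d_{DC}) = \rho$ exactly. $\rho$ (`rho_shared`)
  is the shared-deviation fraction: 1 makes the disorders deviate
  identically, 0 orthogonally. The comorbid group's deviation is additive
  by default (`comorbid_rule = "average"` is available for sensitivity
  analyses). Group sizes default to 22/14/8/8 (52 children).
* **BOLD runs** (`synthesize_bold()`, on demand): voxel time series are
  baseline + amplitude-weighted format regressors (the same
  double-gamma-convolved boxcars the GLM uses) + optional motion coupling +
  stationary AR(1) noise with marginal sd `sigma_noise`.
* **Behaviour** (`generate_behavior()`): trial-level accuracy, RT
  (truncated Gaussian within the 4.4-s deadline) and non-response, from a
  per-group-by-format configuration whose defaults encode dyscalculia
  groups being most impaired on the dot format and all disorder groups
  responding more slowly.

### What the generator does and does not emulate

It reproduces the study's *design* (group sizes, timing, trial counts,
motion QC regime) and a controllable *hypothesis space* for pattern
similarity. It does not emulate anatomy, spatial autocorrelation of real
BOLD noise, slice timing, registration error, or the psychometric
selection of the groups. Green tests therefore certify the statistical
machinery and its calibration, not claims about real children's data.

### Choice of effect size

`effect_size_delta` defaults to 3.5 with `sigma_subject = 1` on a
552-voxel whole mask. This operating point was fixed once by calibration:
it puts leave-pair-out accuracy for the TD-vs-single-disorder comparisons
near 0.75 — comfortably above chance yet far from ceiling, the regime where
the permutation machinery is actually informative. Because the comorbid
deviation is additive, TD-vs-DLDC and the pooled comparisons run higher
(≈0.85–0.95) at the same δ.

## Motion quality control

Two run-exclusion rules operate on scan-to-scan displacements (rotations
as arc length on a 50-mm sphere; a translations-only mode exists because
how rotations enter a per-axis rule is convention, not physics):

1. **axis rule** — some axis moves by more than one voxel size (2.2 mm) on
   two *consecutive* transitions;
2. **Euclidean rule** — the Euclidean norm of the six displacement
   components exceeds one voxel size on any transition.

Both comparisons are strict: a displacement of exactly 2.2 mm triggers
nothing. "Two consecutive scans" is read as the same axis exceeding the
threshold on two consecutive scan-to-scan transitions — the most literal
reading. Subjects keeping fewer than half their runs are excluded;
exactly half counts as kept. After exclusion, `compare_group_motion()`
runs one-way ANOVAs across the four groups on mean per-transition
Euclidean motion, per-run cumulative motion, and retained-run count —
the residual-motion audit a group study must pass for motion not to be a
confound.

## First-level model

Each run is (optionally) smoothed with a separable Gaussian kernel
(`fwhm_mm`, sigma = FWHM/2.355 per axis in voxel units, reflective
boundaries so constants are preserved and small grids suffer no rim
attenuation). The GLM has one column per format — the block boxcar
convolved with a canonical double-gamma response (a no-convolution mode
exists for exact algebraic tests) — the six realignment parameters as
demeaned nuisance regressors, and per-run intercepts; fixation is the
implicit baseline, so each format's beta *is* the format-versus-fixation
contrast, with $t = \hat\beta / SE$. Runs surviving QC are combined by
concatenation with per-run intercepts (symmetric when QC removed runs;
per-run averaging is available as a switch). No autocorrelation
prewhitening is applied — a known limitation; the t-calibration tests
therefore use white noise.

## Group univariate analysis

Per voxel, a 2×2 between-subject factorial (dyslexia presence ×
dyscalculia presence) with sum-to-zero coding and Type III tests — each
term has one degree of freedom, so the Type III F is the squared
coefficient t of the effect-coded full model, exact under the unbalanced
22/14/8/8 design. Directional two-sample t maps cover the planned group
comparisons (TD vs DL+DLDC, TD vs DC+DLDC, TD vs each single group) plus
a one-way F across the three disorder groups. Thresholding is
Benjamini–Hochberg FDR at q = 0.05 over the in-brain mask (background must
not inflate the FDR denominator) per contrast map, with an uncorrected
p < 0.001 map alongside. No cluster-extent criterion is applied.

## MVPA: classification, permutation null, generalization

Patterns are the per-subject contrast estimates within an ROI, **mean
centered per subject** so that between-subject differences in overall
activation level cannot drive classification; everything below is
invariant to adding a constant to one subject's voxels.

**Leave-pair-out cross-validation (LPOCV).** For groups A and B with
$n = \min(n_A, n_B)$: per repetition the larger group is randomly
subsampled to $n$; a random bijection forms $n$ disjoint test pairs; each
fold trains on the remaining $2(n-1)$ subjects and tests the held-out
pair; the pass accuracy is the fraction of the $2n$ test subjects
classified correctly. The observed accuracy is the mean over 1000
repetitions (200 in the scaled-down suites). One pass is defined as a
random bijection covering each subject once; an all-cross-pairs variant
is provided since the pairing rule inside one pass admits both readings.

**Classifier.** A linear soft-margin support-vector machine with unit
regularization (C = 1), the dominant MVPA choice for this design's era
and sample size. Because the permutation suites need on the order of a
million fits, the C-SVC dual is solved by a compact sequential minimal
optimization routine in C++ (maximal-violating-pair selection); its
weight vector, offset and decision values are verified against
`e1071::svm` in the test suite. Ties on the decision boundary (score
exactly 0) deterministically go to the first class. A rank-reduced LDA
alternative (`classifier = "lda"`) is included.

**Permutation null.** Each of 1000 iterations runs one LPOCV pass with
the *training* labels randomly permuted per fold while test pairs are
scored against their true labels; the significance cutoff is the 95th
percentile of the null accuracies, and a result is significant when the
observed mean accuracy exceeds it. A full-relabeling scheme is available
as a sensitivity switch. The null mean sits at the 50% chance level (the
acceptance suite checks ±2%).

**Generalization.** For disorders X and Y with TD as anchor: per
repetition all three groups are subsampled to a common size $n$; training
uses $n-1$ controls versus the full X subsample, and each test pair
couples the held-out control with one Y subject — controls appearing in a
test pair are never in that fold's training set, preventing optimistic
bias. Both directions (X→Y and Y→X) are run and averaged. With
`rho_shared = 1` generalization tracks direct classification; with
`rho_shared = 0` it falls to chance while direct classification stays
high — the simulator's ground truth for what the test measures.

`run_mvpa_suite()` assembles the full grid: per ROI and format, six
classifications (TD vs DL+DLDC, TD vs DC+DLDC, TD vs DL, TD vs DC, TD vs
DLDC, DL vs DC) and three generalizations (DL↔DC, DL↔DLDC, DC↔DLDC),
each cell with its own seeded substream.

## Behavioural statistics

Non-response trials (no answer within the 4400-ms deadline) are excluded
from accuracy and RT and tallied per cell; RT averages correct trials by
default. The mixed 2 (dyslexia) × 2 (dyscalculia) × 3 (format, within)
ANOVA reports the seven effects with Type III between-subject sums of
squares and split-plot error strata, without sphericity correction
(format effects use the uncorrected 2 and 2(N−4) degrees of freedom), via
`car::Anova` on the multivariate linear model; a hand-computed
sums-of-squares oracle pins the balanced case to 1e-8 in the tests.
Pairwise format comparisons are paired t-tests on marginal subject means
with Bonferroni correction ($p_{adj} = \min(1, m\,p)$); marginal rather
than per-group means is the default, the other choice being available by
subsetting.

## Numerical and scale choices

* Grids default to 16³ voxels at 2.2 mm (desk scale while keeping the
  study's voxel geometry); validation suites that need ≥10⁴ voxels use
  22³. The MVPA acceptance experiment uses a 10³ grid (552 in-mask
  voxels), one ROI and one format per replicate — sizes chosen so the
  20-replicate suite completes in minutes on one CPU.
* AR(1) noise is parameterised by marginal sd; innovations are scaled by
  $\sqrt{1-\phi^2}$ and the first sample drawn from the stationary
  distribution.
* All generators accept a seed and restore the caller's RNG state;
  pipeline stages derive independent substreams from one global seed, so
  toggling a stage never shifts another stage's randomness.
* Degenerate inputs are defined, not fatal: zero within-cell variance
  yields infinite F with p = 0; identically-zero effect sums of squares
  yield F = 0; a fully non-responding behavioural cell is flagged missing.

## Known limitations and an honest negative result

At the calibrated ≈0.75 operating point, the package reproduces the
qualitative study pattern — pooled TD-vs-disorder classifications
significant, DL-vs-DC at chance, generalization cells mostly significant —
but the *conjunction* of all three generalization cells clearing their
permutation cutoffs in ≥90% of replicates is not attained (the acceptance
suite measures ~70%): with n = 8 per group a permutation cutoff sits near
0.64 while DL↔DC generalization runs near 0.70, leaving per-cell power
well short of what a three-cell conjunction at 90% requires. This is a
power statement about small-sample permutation testing at a moderate
effect size, not an implementation defect — the same suite passes every
component check, and raising δ trivially makes all cells significant.

Other limitations: no prewhitening in the GLM; no searchlight, feature
selection or nonlinear kernels; no anatomical labelling of clusters; the
behavioural simulator draws trials independently (no learning or fatigue
within runs).
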