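---
title: "Decoding saccade amplitude from multivoxel fMRI patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding saccade amplitude from multivoxel fMRI patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Frontal and parietal eye fields in the primate brain contain neuronal
populations tuned to saccade amplitude. Whether the human homologues carry
a readable representation of saccade *size* can be asked with regional
multivoxel pattern analysis (MVPA): if the spatial pattern of BOLD activity
across an oculomotor region differs reliably between blocks of small (~4°)
and large (~30°) saccades, a linear classifier trained on part of the data
will label held-out data above chance. `saccdecode` implements that entire
analysis chain — and, because no public recordings exist for this paradigm,
a synthetic-data generator with known ground truth, so every stage is
exercisable and its statistical behavior is testable end to end.

# The experiment being emulated

A run is 36 four-second mini-blocks — 6 conditions (small / large / mixed
amplitude × left / right hemifield) × 6 repeats — separated by 6–8 s of
central fixation, with 8 s of fixation at both ends. Each block contains 6
visually guided saccades (three centrifugal/centripetal pairs, mean rate
exactly 1.5 Hz) to boxes at 0/±5/±10/±30°. Blocks are ordered so that every
condition follows every other nearly equally often: a true m-sequence does
not exist for 6 conditions × 6 repeats (perfect pair balance needs 37
blocks), so `make_block_sequence()` builds an Eulerian path on the
transition digraph — every ordered pair once, plus a 5-edge Hamiltonian
walk — giving transition counts that differ by at most 1. Default: 17
subjects, 5 runs each (a `runs_per_subject_schedule` reproduces the 13×5 +
4×6 split when wanted), TR 2 s.

# Eye traces and quality control

`simulate_trace()` produces 60 Hz monocular horizontal gaze. Its parameters
and the reasoning behind the non-obvious ones:

* **Main sequence** `V(A) = vmax(1 − e^{−A/a0})`, `vmax = 500°/s`,
  `a0 = 14°` — standard textbook values; makes large saccades faster, one
  of the two behavioral effects the paired tests must reproduce.
* **Endpoint error** SD = 5% of movement amplitude, *truncated at ±2 SD*.
  The truncation exists because the QC classes (small 2–6°, medium 6–15°,
  large >20°) leave a 1° margin around the 5° target; untruncated Gaussian
  tails would occasionally push a detected amplitude across the 6° boundary
  and invalidate a genuinely clean block.
* **Post-saccadic corrective glissade** (exponential glide onto the visible
  target, τ = 0.1 s). Without it, landing errors — up to 3° after a 30°
  saccade — persist through fixation, so the *next* saccade starts from a
  displaced position and its detected amplitude leaves its class. A glide
  corrects the error without creating a separately detectable event
  (discrete corrective saccades, which we tried first, are counted by the
  detector as extra saccades). Because detection stabilizes before the
  glide finishes, larger landing errors still leave a proportionally larger
  footprint in the detected fixations, preserving the
  variability-grows-with-amplitude effect.
* **Refractory period** 0.2 s between saccades, so a stable 100 ms fixation
  window always exists for the detector. With these three mechanisms, clean
  traces are 100% QC-valid (verified over 3600 blocks), which is the
  contract the exclusion logic is tested against.

`detect_saccades()` is a stateful scan: fixation position is the median of
the trailing 100 ms; an excursion beyond 2° opens an event that closes when
a 100 ms window with range < 1° is found; amplitude is the
fixation-to-fixation displacement. `validate_block()` checks count (6),
amplitude classes, and directions (outward = block hemifield, return =
opposite; amplitudes in the rules' [15, 20]° gap are `unclassified` and
invalidate the block). `apply_exclusions()` drops invalid blocks, runs with
>50% invalid blocks, and subjects with >50% invalid blocks overall — the
run rule generalizes a single reported 30-of-36 case into a threshold.

# ROI atlas

The eight regions (L/R FEF, inferior precentral, SEF, parietal) are
synthesized as connected random voxel sets of fixed sizes inside their
literature-derived bounding boxes, because the meta-analysis maps that
defined the originals are unavailable. The grid is a 2 mm MNI-like template grid
(91×109×91): the canonical ROI sizes (SEF 564, parietal 1043 voxels) are
*impossible* inside the bounding boxes at the 3×3×3.3 mm acquisition
resolution (the left parietal box holds at most ~770 such voxels), and the
original regions were delineated on the standard template, so the template
grid is the faithful choice. FEF defaults to 900 voxels (exercising the
900-voxel feature-selection cap) and Prec to 700 — the largest round size
fitting the right precentral box (capacity 770). Masks are grown
tightest-fit-first and kept pairwise disjoint.

# BOLD simulation

Each subject draws one unit-norm pattern vector per amplitude class (small,
large, medium) over a random 30% of each informative ROI's voxels. A block
of class c contributes `(common_effect + pattern_effect × pattern_c[v])`
times an HRF-convolved boxcar (double-gamma, peak 5 s, undershoot 16 s,
ratio 6); mixed blocks use the mean of the three patterns — the true code
for a mixed block is undefined in principle, and the mean is the neutral
choice (configurable). Noise is AR(1) (ρ = 0.3, marginal SD 1) plus a
per-run baseline offset, linear drift, and a grand mean of 100. A
per-subject multiplicative effect scale (SD 0.25) gives group t-statistics
realistic between-subject variance. `adaptation_gain > 0` attenuates the
common effect of same-size blocks, enabling the mixed-vs-same contrast to
find true adaptation effects.

**Calibration.** The injected `pattern_effect` defaults (parietal 0.4, FEF
0.25, SEF and precentral 0) are the one deliberately tuned quantity: the
true effect size of the original experiment is unknowable, so the defaults
were chosen by a grid sweep to make the default pipeline reproduce the
qualitative dissociation the pipeline is designed around — parietal ~65–68% (always family-wise significant at 17 subjects),
FEF ~56–59%, SEF/precentral at chance (never significant). They were fixed
before the acceptance assertions were frozen and are not adjusted per test.

# First-level model

High-pass filtering is a Gaussian-weighted running-line fit (σ = 50 s):
each time point subtracts the value of a local weighted straight-line fit,
and the series mean is restored; a pure line is removed exactly and block-
frequency signal retains >90% amplitude. The per-block (beta-series) design
has one HRF-convolved boxcar per block plus its temporal derivative, six
motion columns, and an intercept (36+36+6+1 = 79 columns); the
per-condition design has 6+6+6+1 = 19. Estimation is ordinary least squares
— prewhitening is deliberately omitted: mild AR(1) noise biases first-level
variance, not coefficients, and the group stage is a summary-statistics
model that does not consume first-level variances. Zero-filled motion
columns (the synthetic default — no motion is simulated) are dropped from
the fit with coefficient 0; a rank-deficiency error is reserved for
genuinely collinear columns, which are named. The univariate branch smooths
with a separable 5 mm FWHM Gaussian (edge-renormalized, so constants are
preserved).

# Decoding

Per ROI, the sample set is the per-block betas of small- and large-saccade
blocks (hemifields collapsed: 12 samples per class per run). Mean-centering
default is `both`: subtract each sample's spatial mean (image-wide signal),
then each voxel's within-run mean (session effects) — both motivations are
standard and no canonical order exists, so both are applied, run-wise and label-free (no leakage). The classifier is a linear
SVM, C = 1, solved by a deterministic SMO on the dual (maximal-violation
first index, second-order gain second index, tolerance 1e-6, fixed
tie-breaking) — no pre-installed SVM package exists in this stack, and a
from-scratch solver lets tests compare against an exhaustive KKT
enumeration oracle. Cross-validation is leave-one-run-out; with 5 runs each
fold trains on 96 samples. Feature selection ranks voxels by the
training-runs-only mean block beta (an all-saccades > rest localizer) and
takes the top k for k in 200, 300, …, min(900, ROI size), plus the full
size when below the cap; ties break by canonical voxel order.

# Group inference

Accuracies are compared to 50% with a one-sample t (df = n−1; zero variance
is flagged and reported as ±Inf by convention). Family-wise error across
the eight ROIs is controlled by sign-flip max-t permutation: each
permutation draws one sign per *subject*, shared across ROIs — preserving
the inter-ROI correlation that makes the max-statistic correction valid —
and records the maximum t. Monte-Carlo p-values use (1 + #{t_max ≥
t_obs})/(n_perm + 1), which cannot be zero; exhaustive mode (n ≤ 20
subjects) enumerates all 2^n patterns and reports the exact #{≥}/2^n.
Because reported p-values in this literature do not always say which
convention they follow, both are emitted. Voxel-wise group contrasts within an ROI use
the same machinery over voxels (one-sided, positive contrast), with
6-connected clustering of survivors.

# What a green test establishes — and what it does not

The generator emulates block timing, oculomotor kinematics, HRF dynamics,
AR(1) noise, session effects and between-subject heterogeneity. It does not
emulate head motion, physiological noise, anatomy, registration error, or
any true neural code — the injected patterns are Gaussian vectors. Green
acceptance tests therefore establish that the *pipeline* is correct and
calibrated (null accuracy at chance, family-wise error controlled,
permutation and QP solvers match independent oracles, planted effects
recovered where and only where injected), not that the biological claim is
re-confirmed: the original human recordings are unavailable, so no
empirical accuracy value is a reproduction target.

# Numerical and degenerate-input choices

* Sub-seeds for every stage derive from the master seed by exact-integer
  LCG mixing; all stages restore the caller's RNG state.
* SMO tolerance 1e-6 on the maximal KKT violation; bias from free support
  vectors, midpoint-of-bounds fallback.
* The 15–20° amplitude gap is `unclassified` and invalidates its block
  (the conservative reading of the class boundaries); amplitude exactly 6° is
  small (closed bound).
* Design-matrix convolution runs on a 0.1 s grid using one canonical
  boxcar response shifted per onset (exact for equal-duration blocks, and
  fast).
* t statistics under permutation exploit sign-invariance of squares, so
  the null is computed by matrix multiplication; the group-contrast null is
  chunked (2000 permutations at a time) to bound memory.
* Fewer than 2 subjects surviving exclusion falls back to all subjects
  with a warning rather than failing the group stage.

# Known limitations

* On-disk artifacts are TSV only (no NIfTI library exists in the target
  stack); volumes live in memory as arrays/matrices on the grid.
* Prewhitening and mixed-effects group variance weighting are simplified
  away (OLS + summary statistics), a documented divergence from the
  FSL-based original.
* The transition-balance guarantee (spread ≤ 1) is proven for designs
  whose remainder walk is shorter than the condition count — which includes
  the default 6×6 design — not for arbitrary repeats.
* `mixed_rule` other than `"mean"` and nonzero blink rates outside
  injected QC tests are unimplemented surface.
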