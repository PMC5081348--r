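# saccdecode

An R package implementing, end to end, a regional multivoxel pattern
analysis (MVPA) pipeline for saccadic eye movements: can the spatial
pattern of BOLD activity in the human oculomotor eye fields (frontal,
inferior precentral, supplementary, parietal) tell whether the subject was
executing **small (~4°) or large (~30°) saccades**?

Because no public recordings exist for this paradigm, the package ships a
first-class synthetic-data generator with known ground truth, so the whole
chain is runnable and statistically testable with no downloads:

1. **Design** — 36 four-second mini-blocks per run (6 conditions × 6
   repeats, balanced Eulerian-path ordering with transition spread ≤ 1),
   6–8 s jittered fixation, 8 s lead-in/out, TR 2 s.
2. **Eye traces** — 60 Hz gaze with main-sequence kinematics
   `V(A) = vmax(1 − e^{−A/a0})`, amplitude-proportional endpoint error,
   corrective glissades, optional injected bad behavior.
3. **Eye QC** — threshold-based saccade detection, amplitude classes
   (small 2–6°, medium 6–15°, large >20°), block validation against the
   schedule, and >50% exclusion rules for runs and subjects.
4. **ROI atlas** — eight connected masks of fixed sizes (SEF 564, parietal
   1043, FEF 900, Prec 700 voxels) grown inside literature-derived bounding boxes
   on a 2 mm MNI-like grid.
5. **BOLD simulation** — double-gamma HRF block responses carrying
   per-class multivoxel patterns in informative ROIs only, AR(1) noise,
   drift, session offsets, subject heterogeneity.
6. **GLM** — Gaussian running-line high-pass (σ = 50 s), per-block
   (beta-series, 79 columns) and per-condition (19 columns) OLS models,
   contrasts, 5 mm smoothing for the univariate branch.
7. **MVPA** — run-wise mean-centering, deterministic linear SVM (C = 1,
   own Rcpp SMO solver), leave-one-run-out cross-validation, localizer
   feature-selection curves (200…900 voxels).
8. **Inference** — one-sample t vs 50%, sign-flip **max-t** permutation
   across the 8 ROIs (10,000 permutations, family-wise α = 0.05, exhaustive
   enumeration for n ≤ 20), within-ROI voxelwise permutation contrasts,
   paired behavioral tests.

## Worked example

```r
library(saccdecode)
cfg <- pipeline_config(n_subjects = 17, do_eye_qc = FALSE, seed = 1)
report <- run_pipeline(cfg)   # ~40 s on one CPU
print(report)
```

Output from this exact call:

```
saccdecode run report (version 0.1.0)
subjects: 17 | retained: 17 
roi      mean_acc        t      p_fwe   sig
L-FEF        57.4     4.69     0.0016     *
R-FEF        58.5     4.39     0.0026     *
L-Prec       51.9     1.69     0.3122      
R-Prec       50.0     0.05     0.9874      
L-SEF        48.5    -1.08          1      
R-SEF        47.1    -1.95          1      
L-Par        67.6     8.39     0.0002     *
R-Par        68.2     8.69     0.0002     *
max-t critical value: 2.77 
```

Reading it: with the default calibrated ground truth (patterns injected in
parietal and FEF only), decoding accuracy in the parietal masks is ~68%
(chance 50%), FEF ~56%, and the supplementary/precentral masks — where no
pattern was injected — stay at chance; the permutation-corrected p-values
(`p_fwe`, 10,000 sign-flips, max-t over the 8 ROIs) flag exactly the
informative regions. `make_figures(report, "out")` draws the accuracy bar
chart and, when `do_feature_curve = TRUE`, accuracy-vs-ROI-size curves.

A CLI wraps the same stages
(`inst/cli/saccdecode <simulate|qc|all> --config FILE --out DIR [--seed N]`,
JSON config mirroring `pipeline_config()`).

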