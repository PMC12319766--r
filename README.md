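# mrfrelia

Quantitative T1 mapping with magnetic resonance fingerprinting (MRF), and the
scan–rescan reliability analysis that goes with it — implemented end-to-end on
synthetic data, so every stage of the pipeline can be exercised, stress-tested
and validated without access to scanner data.

## The problem

Quantitative T1 (and its rate R1 = 1/T1) indexes myelin content in white
matter and increases through childhood as tracts mature. MRF measures T1 in a
2-minute scan: an inversion-prepared pseudo-random flip-angle train produces a
distinctive signal evolution ("fingerprint") per tissue, acquired with heavily
undersampled k-space sampling, reconstructed in a low-dimensional temporal
subspace, and matched against a simulated dictionary. Whether such a fast
measurement is *reliable enough* for longitudinal pediatric studies — and how
scan duration and off-resonance (B0) correction affect that reliability — is a
pipeline-level question. This package implements the full pipeline and a
synthetic two-session pediatric cohort to study it:

* **Signal model** — extended-phase-graph (EPG) simulation of the
  inversion-prepared fingerprinting sequence; dictionary over a T1 × T2 grid
  (T1: 20–3000 ms at 20 ms steps plus a coarse 3200–5000 ms CSF tail); SVD
  temporal subspace Φ (K = 5 components capture ≥ 99% of dictionary energy).
* **Reconstruction** — solves
  `min_c ||P F S Φ c − y||² + λ · LLR(c)`
  (undersampling pattern P, Fourier transform F, coil sensitivities S) by
  accelerated proximal gradient with locally-low-rank (LLR) singular-value
  thresholding on spatial patches of the K coefficient maps; optional
  time-segmented conjugate-phase B0 correction models the per-sample
  off-resonance phase `exp(−2πi b0 t)` with L interpolated segments.
* **Motion-compensated combination** — two complementary 2-min acquisitions
  are merged in k-space (rotation of sample coordinates, phase ramp for
  translation) into a "4-min" reconstruction.
* **Template matching** — per-voxel normalized cross-correlation against the
  subspace-compressed dictionary yields T1/T2/PD maps; R1 = 1000 / T1.
* **Half-way registration** — sessions are resampled into an unbiased
  mid-space (both move half the distance), coefficient maps are registered
  *before* matching, and averaged maps give a higher-SNR template.
* **Reliability statistics** — voxelwise/ROI/tract Pearson r, R² about the
  identity line, two-point coefficient of variation
  (`CV = (|a−b|/√2) / mean · 100`), Bland–Altman summaries, and the mixed
  model `r ~ duration * B0 + age + (1 | participant)` (lme4).
* **Tractometry** — synthetic streamline bundles, AFQ-style iterative
  cleaning (drop streamlines > 3 sd from the core or > 4 sd longer, five
  rounds), 100-node profiles analyzed over the middle 80 nodes, and
  age–R1 correlations with Benjamini–Hochberg correction.
* **Digital phantom** — anatomy-like label geometry (WM, GM ring, asymmetric
  ventricles, deep-gray nuclei, five corpus-callosum segments whose T1 runs
  an inverted U front-to-back, tract-like bundles), a smooth B0 field with a
  high-inhomogeneity sinus-analog pocket, smooth coil maps, and a cohort of
  8–13-year-olds whose WM R1 rises linearly with age across two sessions 2–4
  months apart with rigid motion and thermal noise.

## Worked example

```r
library(mrfrelia)

protocol <- desk_protocol()                      # 16 groups x 60 TRs
dict  <- build_dictionary(dictionary_grid(), protocol)
basis <- compute_subspace(dict, k = 5)
basis
#> MRF subspace basis: K = 5 over 960 timepoints, 99.713% energy captured

ph     <- make_phantom(c(64, 64, 3), voxel_size_mm = 3, seed = 11)
coils  <- make_coil_sensitivities(c(64, 64, 3), n_coils = 4, seed = 3)
scheme <- make_sampling_scheme(c(64, 64), protocol, accel = 2, seed = 5)

truth <- project_phantom(ph, basis, protocol)
y     <- forward_model(truth, basis, coils, scheme, b0_map = ph$b0_map)
rec   <- reconstruct_subspace(y, basis, coils, scheme, recon_config())
maps  <- template_match(rec, compress_dictionary(dict, basis),
                        mask = ph$t1_map > 0)
maps
#> quantitative maps 64x64x3: 7932 matched voxels, T1 range 780-4400 ms

wm <- wm_mask(ph)
sqrt(mean((maps$t1_map[wm] - ph$t1_map[wm])^2))
#> [1] 27.8771
```

A noiseless, fully sampled run of the same pipeline puts ≥ 99% of
white-matter voxels on the dictionary grid point nearest their true T1
(half a 20 ms grid step). The undersampled reconstruction above stays within
~28 ms RMSE of the ground truth in white matter.

The full experiment — two sessions per subject, four reconstruction
pipelines (2-min / 4-min, B0 correction off/on), half-way registration,
matching, and all reliability statistics — is one call:

```r
report <- run_experiment(run_config(cohort = cohort_spec(n_subjects = 8)))
report$voxelwise      # per subject x pipeline: r, R2 about y = x, CV%
report$roi_table      # corpus-callosum segments, across-subject R2 / CV
report$tract_table    # tract-mean scan-rescan correlations
report$lmm$fixed      # duration / B0 / age fixed effects
report$age_table      # tract R1 vs age, FDR-corrected
```

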