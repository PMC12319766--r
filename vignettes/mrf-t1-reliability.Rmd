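---
title: "Quantitative T1 with MR fingerprinting: model, pipeline and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative T1 with MR fingerprinting: model, pipeline and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science implemented in `mrfrelia`: the signal
model, the reconstruction and matching chain, the reliability analysis, what
the synthetic-data generator does and does not emulate, and the numerical
choices behind each stage. Nothing here asserts an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. The signal model

### Sequence and EPG simulation

The acquisition is an inversion-prepared, gradient-spoiled fingerprinting
sequence: each acquisition group starts with an adiabatic inversion (15 ms
inversion time), plays a train of excitations with a varying flip-angle
schedule, and ends with a 1.2 s resting period for longitudinal recovery. At
scan scale a group holds 500 TRs and a scan has 16 groups; the desk-scale
default (`desk_protocol()`) keeps 16 groups of 60 TRs, preserving every
structural feature (inversion, ramped flips, rest) at roughly a tenth of the
simulation cost. All invariants hold at any size.

Signal evolutions are computed with the extended phase graph (EPG)
formalism: configuration states $(F^+_k, F^-_k, Z_k)$ over dephasing orders
$k$, advanced per TR by the RF mixing matrix, relaxation, and a unit gradient
shift. Thirty configuration orders are retained — enough that truncation is
invisible at the accuracy we verify. Because all excitations share one RF
phase axis, the recursion closes on a real-valued representation
($F^\pm = i f^\pm$ with $f^\pm$ real, $Z$ real), which is what makes
dictionary simulation fast in plain R; the physically irrelevant global
phase is dropped from returned fingerprints.

The simulator is validated against an independent isochromat Bloch oracle
(200 spins, ideal spoiling by uniform per-TR dephasing, pure 3×3 rotation
algebra): agreement is at machine precision on a 50-TR constant-flip train,
far inside the 1% bound we assert, and the zero-flip limit reproduces
$1 - 2e^{-t/T_1}$ exactly.

Choices the sequence literature leaves open, fixed here as configurable
defaults: TR 12 ms, TE 1.8 ms, a smooth half-sine-squared flip ramp between
5° and 75° per group (varying flips give joint T1/T2 sensitivity), and ideal
inversion efficiency.

### Dictionary and subspace

The dictionary covers T1 from 20 to 3000 ms in 20 ms steps plus a coarse
3200–5000 ms extension for CSF, crossed with a T2 axis (10–300 ms step 10,
plus 500–2000 ms step 100) restricted to physical pairs $T_2 \le T_1$ —
6166 atoms at the default grids, each normalized to unit energy. The
temporal subspace $\Phi$ holds the top $K$ right singular vectors of the
atom matrix; $K = 5$ captures 99.7% of squared singular-value energy on the
default dictionary, and matching decisions after compression agree with
full-space matching on essentially every phantom voxel (both recomputed in
the acceptance script). The worst per-atom projection residual at $K=5$ is
12% and sits entirely in ultra-short-T2 edge atoms (T2 = 10 ms); tissue-range
atoms stay below 10%.

## 2. Encoding and reconstruction

### Forward model

A k-space sample $s$ acquired in TR $t_s$ at grid frequency $q_s$ and
readout time $\tau_s$ is modeled as

$$ y_s = \sum_l w_l(\tau_s)\,\big[\,F\, D_l\, S\, (\Phi_{t_s} c)\,\big](q_s), \qquad D_l = e^{-2\pi i\, b_0 \tau_l}, $$

with coil maps $S$, unitary slice-wise 2D FFT $F$, and off-resonance phase
handled by time segmentation: $L$ segment centers $\tau_l$ with linear
interpolation weights $w_l$. When $L$ reaches the number of distinct sample
times the segments coincide with those times and the model is the exact
per-sample conjugate-phase operator — the identity the operator tests
assert. Without a B0 map there is one segment with unit weight.

Desk-scale sampling uses per-group variable-density random Cartesian masks
(fully sampled low-frequency disk, density-weighted periphery), the group's
samples spread cyclically over its TRs with a center-out 0–5 ms readout
time ramp. The reconstruction mathematics ($PFS\Phi$) is
trajectory-agnostic; spiral gridding fidelity is not what these experiments
probe. The two scans of a session draw complementary masks (the second scan
down-weights locations the first already covered).

### Solver

The objective is

$$ \min_c\; \lVert A c - y \rVert_2^2 + \lambda \cdot \mathrm{LLR}(c), $$

solved by FISTA-style accelerated proximal gradient. The normal operator
$A^{\mathsf H} A$ is applied through a precomputed k-space kernel
$T_{l_1 l_2, k_1 k_2}(q) = \sum_s w_{l_1} w_{l_2} \phi_{t_s k_1} \phi_{t_s k_2} \delta_{q_s}$,
so one application costs $L \times K$ FFT pairs per coil and slice
regardless of sample count; the objective is evaluated algebraically from
$A^{\mathsf H}A c$ and $A^{\mathsf H} y$, so the solver never forms forward
projections in the loop. The step size comes from a short power iteration;
because the conjugate-phase factors are unitary and barely move the operator
norm (we measured ratios within 0.1%), the bound is computed on the
phase-free operator with a wider 15% margin.

The LLR proximal step soft-thresholds the singular values of $p \times p$
spatial patches of the stacked $K$ coefficient maps ($p = 8$,
non-overlapping). By default the patch grid shifts randomly each iteration,
which suppresses blocking artifacts but makes the penalty — and hence the
reported objective — fluctuate at the sub-percent level; `llr_shift =
"fixed"` keeps one grid and then the objective is strictly non-increasing
(both behaviors are under test). Divergence (sustained growth beyond the
fluctuation band over five iterations) aborts with diagnostics. A
momentum-overshoot fallback takes a plain proximal step and restarts the
acceleration.

Defaults chosen where the field's literature prints none: $\lambda = 0.05
\cdot \lVert A^{\mathsf H} y \rVert_\infty$ (scale-free), patch 8, $L = 8$
segments, 30 iterations for a standalone solve and 20 inside the
four-pipeline experiment (the objective plateaus well before that at the
desk problem size, and all pipelines share the budget so comparisons stay
balanced).

### Motion-compensated combination

The "4-min" reconstruction merges the two complementary acquisitions in
k-space: sample coordinates of the second scan are rotated by the rigid
motion estimate and re-gridded to the nearest Cartesian location, and a
phase ramp applies the translation. The synthetic acquisition of a moved
object uses *the same* coordinate map in reverse (`forward_moved()`), so
compensation with the true transform is exact by construction — the honest
discretization of the fact that a rigidly moved object's k-space is the
rotated, phase-ramped k-space of the unmoved object. Nearest-grid rounding
of rotated coordinates is the desk-scale stand-in for trajectory rotation;
at the 64-point grid, rotations below ≈0.6° move no coordinate at all,
which bounds both the harm and the benefit of compensating them.

## 3. Matching and half-way registration

Template matching maximizes the magnitude of the complex inner product
between a voxel's coefficient vector and each unit-norm compressed atom
(phase-insensitive; global complex scaling of $c$ cannot change the argmax).
Ties resolve to the lowest T1; atoms are stored sorted by (T1, T2) to make
that deterministic. All-zero voxels are flagged (T1 = 0, correlation 0) and
propagate as missing through `r1_map()`.

Sessions are compared in an unbiased half-way space: the rigid transform
between sessions is estimated on the magnitude of the high-contrast third
coefficient map, split into two half-transforms via the matrix square root
in SE(2) (each session moves half the distance), and the *coefficient* maps
— not the matched T1 maps — are resampled before matching, which avoids
compounding partial-volume error through the nonlinear matching step.
Swapping the session order exchanges the two halves, so neither session is
privileged; the residual asymmetry of the full pipeline is measured (< 2%
relative RMS in interior white matter) rather than assumed.

The registration itself is an internal MSE optimizer: light in-plane
binomial presmoothing, a coarse grid search, then Nelder–Mead refinement.
Two numerical details matter. First, the metric grid sits half a voxel off
the lattice so that at the identity both images are interpolated
identically — without this, the kink in bilinear interpolation loss pins
the optimum to exact integer alignments and sub-voxel motion is never
found. Second, near-zero estimates snap to the exact identity so
registering an image to itself is a strict no-op. Recovery accuracy on
phantom maps is ~0.01 voxel / ~0.02° for known motions, comfortably inside
the 0.1 voxel / 0.2° contract.

## 4. The synthetic cohort: what it emulates, and what not

`make_phantom()` builds an anatomy-like 2D+slice head: elliptical brain with
a gray-matter ring, white-matter interior, left–right *asymmetric* lateral
ventricles, three deep-gray nuclei, five corpus-callosum segments ordered
anterior→posterior whose mean T1 follows an inverted U (interior maximum:
820, 862, 890, 868, 824 ms), and six tract-like core curves with distinct
small T1 offsets. The deliberate asymmetries are anatomically motivated and
also make small rotations identifiable: a purely elliptical phantom is
rotationally degenerate and no intensity-based registration could recover
session rotations from it.

Tissue values are literature-style configuration entries, not measurements:
WM 850/60 ms (T1/T2), GM 1400/80, CSF 4200/1500, proton densities 0.7–1.0.
T1 carries smooth within-class texture (sd 2.5%, hard-clamped at ±5%) — the
"individual anatomy" that reliability statistics correlate across sessions.
T2 is class-constant and sits on the dictionary grid, so the noiseless
recovery benchmark isolates T1 quantization; T2 accuracy is explicitly out
of scope (no B1 mapping in the modeled protocol). The B0 field is a smooth
low-amplitude background (5 Hz RMS) plus one 60 Hz Gaussian pocket at the
anterior brain boundary — the air-filled sinus analog; over a 5 ms readout
the pocket accrues ~1.9 rad of phase, enough to visibly blur the
uncorrected reconstruction there, while the background stays negligible.

`simulate_cohort()` draws subjects aged 8–13 whose WM R1 follows
$R_1 = 1.092 + 0.008 \cdot \mathrm{age} + u_i$ (1/s; slope per year,
between-subject sd $u_i \sim N(0, 0.015)$), sessions 2–4 months apart with
developmental drift along the same slope, inter-session rigid motion (sd 2°,
2 mm), small intra-session motion between the two 2-min scans (sd 0.2°,
0.5 mm), and complex k-space noise at 15% of the RMS sample magnitude.
Reasoning behind the values the source literature does not print:

* **Effect size.** The slope/SD pair makes the generative age–R1 correlation
  ≈ 0.6, detectable at $n = 40$ with FDR correction across tracts at
  essentially any seed — mirroring the fact that the real study's tract
  correlations were significant — without copying unprintable values.
* **Noise.** Chosen so thermal noise is the dominant session-to-session
  error source; only then does doubling the acquisition measurably improve
  reliability, which is the study's central duration effect. The resulting
  absolute voxelwise correlations (≈0.35–0.55) are *below* the in-vivo
  values, because the phantom's within-class texture is far smaller than
  real anatomical T1 variance at 1 mm; the criteria are therefore
  directional and property-based, not value-matching.
* **Intra-session rotation.** 0.2° sd — scaled so its edge displacement
  matches the translation sd relative to the desk voxel size. Larger
  sub-resolution rotations are unrecoverable by any registration at a
  64-point grid and would test grid resolution, not the combination
  machinery.
* **Session trajectories.** Each subject-session redraws its sampling-mask
  realization (default `session_trajectories = "redrawn"`): between sessions
  the head is repositioned, so the trajectory-relative sampling of the
  anatomy changes and undersampling residuals decorrelate, as in vivo. With
  identical masks the systematic aliasing is reproducible across sessions
  and *inflates* single-scan reliability — a desk-scale artifact we
  deliberately remove. The `"fixed"` mode exists so the fully degenerate
  cohort (no noise, no motion, no drift) is exactly repeatable, the
  textbook limit the tests assert.

What the generator does **not** emulate: cortical folding, diffusion
contrast and tractography (synthetic bundles stand in), B1+ inhomogeneity,
susceptibility physics behind the B0 pocket, through-plane rotation, scanner
drift, and physiological noise. Passing tests demonstrate that the
*pipeline machinery* behaves correctly and that directional effects (longer
scans help; B0 correction helps only near the pocket; age effects are
recoverable) emerge under controlled conditions — not that in-vivo effect
sizes are reproduced.

## 5. The experiment and its statistics

`run_experiment()` runs, per subject and session: two complementary
acquisitions (the second seen through the intra-session motion model), the
configured pipelines (2-min uses the first acquisition only; 4-min estimates
the intra-session transform from the two separate reconstructions and
combines in k-space; the B0 variants correct with $L=8$), half-way
registration of the sessions on the 4-min coefficient maps, resampling of
every pipeline's coefficients with the same halves, matching, and the three
reliability analyses:

* **Voxelwise** Pearson r and identity-line $R^2 = 1 - \sum(y-x)^2 /
  \sum(y-\bar y)^2$ over a one-voxel-eroded white-matter mask. The erosion
  excludes boundary voxels whose partial-volume content dominates at 3 mm
  voxels — the desk analog of the conservative white-matter masks used at
  1 mm; without it, boundary voxels contribute large session-correlated
  pseudo-signal that masks genuine differences between pipelines.
* **ROI**: the five CC segments, across-subject r / $R^2$ / two-point CV
  (sample convention, $sd = |a-b|/\sqrt 2$).
* **Tract**: bundles generated around the phantom's cores mapped into
  half-way space, cleaned, profiled at 100 nodes, middle 80 analyzed;
  across-subject tract-mean correlations with bootstrap 68% intervals, and
  age–R1 correlations with Benjamini–Hochberg correction.
* **Mixed model**: `r ~ duration * b0 + age + (1 | participant)` by REML
  (lme4), exactly the factorial pipeline comparison; singular fits are
  flagged, not fatal.

Problem sizes: the default experiment is 8 subjects at 64×64×3 (3 mm
voxels), 16×60 timepoints, 4 coils, acceleration 2 per scan — the full
four-pipeline run completes in roughly 13 minutes on one CPU, and the
two-pipeline duration comparison in about half that. Determinism: every
random stage draws from a stream derived from the master seed, so reruns
are byte-identical including CSV outputs.

## 6. Known limitations

* Matching is grid-valued (no interpolation between atoms): T1 precision is
  bounded by half the grid step, and near-midpoint voxels are intrinsically
  ambiguous — visible as the ~1% miss rate in the noiseless recovery
  benchmark.
* The MSE registration assumes the phantom's intensity asymmetries; on data
  without such structure, sub-degree rotations are unidentifiable (and at
  this grid size, also nearly inconsequential for k-space combination).
* The 2D+slice geometry restricts motion to in-plane rotation plus
  translation; full 3D rotation is out of scope at desk scale.
* T2 maps are produced but untested against accuracy targets (no B1 model).
* In-vivo reliability magnitudes are not reproduced, only their ordering
  and mechanisms; see §4.
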