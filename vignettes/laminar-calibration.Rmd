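---
title: "Laminar calibrated BOLD with RSFA normalization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar calibrated BOLD with RSFA normalization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamcal)
```

## The problem

Gradient-echo BOLD fMRI at submillimeter resolution can resolve signal
changes across cortical depth, but the BOLD response is biased toward
ascending and pial veins: activity originating in deep or middle cortical
layers is amplified toward the pial surface, and genuine laminar structure
(for example the double-peak response of primary motor cortex, with
separable input and output laminae) is hidden under a monotone venous
gradient.  Vascular space occupancy (VASO) imaging, which nulls blood
signal and therefore *loses* signal when cerebral blood volume (CBV)
rises, is far more spatially specific but has lower sensitivity.

Calibrated fMRI addresses the venous bias by dividing the BOLD response by
a purely vascular scaling factor, classically obtained from a hypercapnia
(CO~2~ breathing) challenge.  This package implements, end to end, the
laminar version of that analysis and its resting-state shortcut: using the
resting-state fluctuation amplitude (RSFA) — the temporal SD of the
band-passed resting signal — as the vascular scaling factor instead of a
gas challenge, and validating it against the hypercapnia amplitude
(tSD~hc~) and the Davis-model calibration factor *M*, lamina by lamina.

Because no in-vivo data ship with the package, a forward simulator with
known per-lamina ground truth stands in for the scanner.  It is a
first-class, tested module: every analysis stage is validated by parameter
recovery against it.

## The model

The Davis model writes the relative BOLD signal change for normalized
cerebral blood flow $f = \mathrm{CBF}/\mathrm{CBF}_0$ and normalized
oxidative metabolism $r = \mathrm{CMRO}_2/\mathrm{CMRO}_{2,0}$ as

$$\Delta S = M\,\bigl(1 - f^{\alpha_t-\beta}\, r^{\beta}\bigr),$$

with the Grubb exponent $\alpha_t = 0.38$ coupling total CBV to CBF
($\mathrm{CBV}_t \propto \mathrm{CBF}^{\alpha_t}$) and $\beta \approx 1$
at 7 T, where intravascular contributions are negligible.  $M$ is the
maximum possible BOLD signal change,

$$M = \kappa\,\mathrm{TE}\,\mathrm{CBV}_{v,0}\,[\mathrm{dHb}]_0^{\beta},$$

a baseline quantity proportional to echo time, baseline *venous* CBV and
baseline deoxyhemoglobin concentration.  Substituting Grubb's relationship
turns the flow dependency into a dependency on normalized total CBV
$v_t = \mathrm{CBV}_t/\mathrm{CBV}_{t,0}$ (the quantity VASO measures):

$$\Delta S = M\,\bigl(1 - v_t^{\,\alpha_v-\beta/\alpha_t}\, r^{\beta}\bigr),$$

with the venous Grubb exponent $\alpha_v = 0.2$.  Mild hypercapnia is
assumed isometabolic ($r = 1$), so paired laminar measurements of the
hypercapnic BOLD change $\Delta S_{hc}$ (from the not-nulled volumes) and
$v_t$ (from the BOLD-corrected nulled volumes) invert to

$$M = \frac{\Delta S_{hc}}{1 - v_t^{\,\alpha_v-\beta/\alpha_t}}.$$

`davis_forward_f()`, `davis_forward_v()` and `compute_M()` implement these
three equations; `compute_M()` is the exact analytic inverse of
`davis_forward_v()` at `r = 1` (checked to 1e-12 over a grid in the test
suite).

RSFA enters as a measurement-driven surrogate: if resting fluctuations and
evoked vascular responses share one local mechanism (the intrinsic
vascular sensitivity of each lamina), laminar RSFA, tSD~hc~ and *M* are
scaled versions of one another, and dividing a laminar BOLD response
profile by an RSFA profile removes the venous amplification just as gas
calibration would.

## Pipeline stages

1. **I/O** (`read_timeseries()`, `write_timeseries()`, `read_physio()`,
   profile TSV readers/writers): NIfTI-1 via RNifti; the TR lives in
   `pixdim`, the contrast label in the header description.
2. **Preprocessing**: `split_interleaved()` separates alternating
   blood-nulled/not-nulled volumes (nulled first by convention; a flag
   flips it); `bold_correct_vaso()` removes BOLD contamination from the
   nulled series by volume-wise division; `linear_detrend()` removes
   per-voxel drifts but re-adds the mean so percent changes keep their
   baseline; `bandpass()` realizes the 0.01–0.15 Hz (full), 0.01–0.1 Hz
   (low) and 0.1–0.15 Hz (high) bands; `retroicor()` regresses cardiac and
   respiratory phase harmonics (order 2) out of each contrast separately.
3. **Layering**: `upsample()` (bilinear for intensities, nearest for
   masks/labels), `grow_equivolume_laminae()` and `extract_profile()`.
4. **Fluctuation metrics**: `rsfa()`, `tsd_hc()`, `tsnr()` — per-voxel
   temporal SDs (band-passed, unfiltered, and mean/SD respectively).
5. **Calibration**: `block_percent_change()`, `vt_from_vaso()`,
   `compute_M()`.
6. **Statistics**: `glm_zstat()` (block-design GLM, Z via the exact
   t-to-normal transform), `define_roi()` (Z conjunction, largest
   component), `laminar_regression()` (unweighted OLS across laminae),
   `bland_altman()`, `normalize_profile()`, `task_residual_rsfa()`.
7. **Drivers**: `run_experiment_a()` (rest + hypercapnia → RSFA vs.
   tSD~hc~ vs. M regressions) and `run_experiment_b()` (rest + task →
   RSFA-normalized BOLD vs. VASO profiles), both driven by one
   `lamcal_config()` list.  The package's interface is these functions
   plus `scripts/acceptance.R`; no shell CLI is provided.

## Equivolume layering

Between the manually defined (here: synthetic) GM/WM and GM/CSF borders,
`grow_equivolume_laminae()` places lamina boundaries that preserve each
lamina's local *area* fraction under curvature rather than equal spacing.
For each GM pixel it computes distances $d_{wm}$, $d_{csf}$ to densely
resampled border polylines; the local curvature is estimated from the
ratio $\rho$ of border segment lengths at index-matched border points (for
concentric arcs, $\rho$ is exactly the ratio of the radii).  With
thickness $T = d_{wm}+d_{csf}$, signed curvature $a = (1-\rho)/\rho =
T/r_{w}$ and relative depth $x = d_{wm}/T$, the equivolume fraction is

$$v(x) = \frac{x\,(2 + a\,x)}{2 + a},$$

which reduces to the equidistant rule as $a \to 0$ and reproduces the
closed-form equal-area annulus boundaries
$r_k = \sqrt{\smash{((n-k)\,r_{wm}^2 + k\,r_{csf}^2)/n}}$ exactly.  Lamina
indices are `ceiling(v * n)` with ties breaking toward the WM side;
lamina 1 touches WM, lamina *n* the pial surface (plot axes can be
reversed).  On analytic annuli the recovered boundary radii agree with the
closed form to well under a pixel and lamina pixel counts are equal to
within 2% once rings are a few pixels wide; `make_ribbon()` provides these
oracle fixtures.  15 laminae are the default, 21 are supported for
higher-resolution protocols.  The laminae are *depth compartments*, not
histological layers.

## The synthetic session generator

`make_ground_truth()` fixes per-lamina physiology; `simulate_session()`
renders one interleaved acquisition at 0.824 s volume spacing (effective
per-contrast TR 1.648 s).  Defaults encode the emulated study:

| parameter | default | meaning |
|---|---|---|
| `n_laminae` | 15 | depth compartments in the ribbon |
| `pial_amplification` | 3 | pial/WM ratio of baseline venous CBV and CVR |
| `cvr_pial` | 0.2 | fractional CBV response of the pial lamina (v~t~ plateau 1.2) |
| `cbv_t0` | 0.055 ml/ml | baseline total CBV (gray matter) |
| `te_s` | 0.024 s | echo time entering *M* |
| `m_pial` | 0.1 | true *M* at the pial lamina (fixes κ·[dHb]₀) |
| `noise_sd` | 3 a.u. | thermal noise (baseline BOLD signal 100 → tSNR ≈ 33) |
| `rest_amp` | 1.0 | SD of spontaneous CBV fluctuations per unit CVR |
| `task_gain` | 0.6 | task CBV response per unit (neural × CVR) |
| `physio_amp` | 0.004 | cardiac (1.05 Hz) and respiratory (0.29 Hz) signal oscillation |
| paradigm | 2/3/3/3/4 min | air/gas/air/gas/air hypercapnia block design |

The forward model: each lamina's total CBV is
$\mathrm{CBV}_t(t) = \mathrm{CBV}_{t,0}\bigl(1 + \mathrm{cvr}\,u(t) +
\mathrm{cvr}\,\texttt{rest\_amp}\,w(t)\bigr)$, where $u(t)$ is the
challenge boxcar passed through a single-exponential vascular response
(τ = 30 s; a gamma-variate peaking at 5 s for tasks, scaled by
`task_gain × neural`), and $w(t)$ is **one** band-limited (0.01–0.15 Hz)
stochastic process shared by all laminae — evoked responses and
spontaneous fluctuations ride on the same local vascular sensitivity,
which is the hypothesis under test.  $w$ is soft-bounded at 2.5 SD
(tanh), since unbounded Gaussian excursions would push the Davis
nonlinearity into non-physical signal collapse.  BOLD follows the modified
Davis model with the lamina's true *M*; nulled volumes are
$\propto (1-\mathrm{CBV}_t)$ times the same BOLD modulation (which the
dynamic-division correction removes); tissue T1 differences are reduced to
fixed compartment scale factors (GM nulled/not-nulled 0.55, WM-like
background 0.75), giving the T1-weighted reference its contrast.

Two defaults deserve justification.  `rest_amp = 1.0` makes resting pial
BOLD fluctuations ≈ 5% — large, but it is what the in-vivo observation
implies: laminar RSFA profiles fall roughly twofold from pial surface to
WM, which at tSNR ≈ 30 requires the vascular RSFA component to dominate
the flat thermal floor, and it is the regime in which RSFA normalization
can work at all.  A side effect is that simulated pial tSNR (~16) drops
below the mid-cortical value (~33).  `task_gain = 0.6` keeps the
second-order Davis cross-term between task response and resting driver
small; larger gains measurably contaminate task-residual RSFA profiles.
The double-peak neural profile places Gaussian bumps (amplitude 0.2,
width 0.1 in depth fraction) at depths 0.35 and 0.8 — a deep output band
and an upper input band.

With `noise_sd = 0`, `rest_amp = 0` and `physio_amp = 0` the simulator is
fully deterministic given the seed, and the calibration module recovers
`m_true` per lamina as an analytic inverse.

## Numerical choices and degenerate inputs

* **Filters**: 4th-order Butterworth, forward–backward (zero phase); an
  ideal transform-domain brick-wall is available (`method = "spectral"`)
  and used for exact band-limiting of the resting driver.  Band edges at
  or above Nyquist are errors.  Variance partition across the low/high
  bands holds to ~10% with the realizable filter.
* **Block averaging**: steady states are block interiors minus the first
  60 s (`settle_s`) and the final two stored TRs (`edge_s`) — the
  division partner of a block's last nulled volumes lies across the
  transition.  With τ = 30 s transitions and linear detrending, block
  averaging leaves a systematic −1% to −2.6% bias in recovered *M*
  (baseline windows retain decay tails; detrending folds part of the
  response into the baseline level).  Recovery is exact only when
  plateaus are truly reached; the exactness tests therefore use fast
  transitions (τ = 5 s) without detrending, and the default path is
  validated under the noisy accuracy bounds instead.
* **M inversion**: `v_t = 1` yields NaN with a warning; negative *M* is
  reported, not dropped.  Per-lamina SEMs propagate through the inversion
  by the first-order delta method.
* **Z-statistics**: naive degrees of freedom (t − 2), no autocorrelation
  correction — adequate for white noise (the null tail at Z > 2.3 is
  calibrated to 0.0107 in the tests) and a known limitation for colored
  noise.  VASO series are fitted with a sign-inverted regressor; default
  thresholds 2.3 (BOLD) and 1.8 (VASO).
* **Bland–Altman** comparisons of differently scaled quantities (e.g. *M*
  vs. RSFA) z-score both profiles first (`standardize = TRUE`).
* **Regression across laminae** is unweighted OLS; per-lamina SEMs are
  carried in the profiles but not used as weights.
* **RETROICOR** runs after contrast splitting, per contrast, when
  enabled (`config$retroicor`); the cohort drivers default to off, since
  at these voxel sizes thermal noise dominates and the physiological
  oscillations alias outside the analysis bands.  Cardiac phase comes
  from pulse-peak detection (min peak distance 0.25 s), respiratory phase
  from the histogram-equalized amplitude-and-slope rule.
* **tSD~hc~** is computed on the unfiltered detrended series, transitions
  included; the initial baseline counts like any other block.

## Study conditions and problem sizes

`run_experiment_a()` simulates 9 subjects (15-min hypercapnia + 15-min
rest each); `run_experiment_b()` simulates 11 subjects (24-min task +
24-min rest, double-peak neural profile).  Per-subject ground truth gets
independent 5%-lognormal per-lamina jitter on CVR and baseline venous CBV
so between-subject spread is non-trivial.  The synthetic ribbon is a
quarter annulus (r~wm~ = 56 px, r~csf~ = 92 px on a 94×94 grid, ~280
pixels per lamina) — chosen so per-lamina averaging is comparable to an
upsampled in-vivo ROI; the profiles are extracted over the full ribbon,
which is the active region by construction.  These sizes are the
package's default study conditions; `lamcal_config()` scales any of them
(session durations down to ~5 min still hold three cycles of the lowest
analysis frequency).

Expected structure, all recomputed by the test suite and
`scripts/acceptance.R`: per-subject laminar regressions of tSD~hc~ on each
RSFA band are near-perfect and always positive; regressions of *M* on RSFA
are clearly positive but weaker (the *M* estimate divides two small noisy
contrasts); recovered *M* tracks the per-subject truth; in the double-peak
scenario the VASO profile shows two interior maxima, raw BOLD does not,
and RSFA-normalized BOLD reveals peak structure coinciding (within one
lamina) with the VASO peaks — most robustly the upper-layer peak, while
the deep peak reappears in only part of the simulated cohorts because the
thermal floor in per-voxel RSFA inflates the denominator at depth.
Normalizations using resting RSFA and task-residual RSFA agree to within
10% of the profile range.

## What the simulation does and does not show

Passing tests demonstrate that the implementation is faithful to the
models and recovers known ground truth under the stated forward model.
They do **not** demonstrate that RSFA normalization works on arbitrary
real data: the simulator has no motion, no distortion, a single 2D slice
of idealized geometry, thermal noise that is white and spatially
independent, a purely *local* linear venous amplification (no signal
drainage from deep laminae into superficial voxels, i.e. no laminar
point-spread function), and a resting driver that is perfectly shared
across depth — the strongest possible version of the common-mechanism
hypothesis.  Real cortices bend, veins drain tangentially, and RSFA
carries non-vascular components; the in-vivo correlations are accordingly
weaker than the simulated ones.

## Known limitations

* Block-mean calibration carries the few-percent transition bias described
  above; it is common-mode across laminae and barely affects profile
  shape or regressions.
* Strong spontaneous fluctuations add a positive Jensen-type bias to the
  recovered *M* of the most reactive laminae — block means of the convex
  Davis response overestimate the plateau by
  $O\bigl((\mathrm{cvr}\cdot\texttt{rest\_amp})^2\bigr)$, ≈ +9% at the
  pial lamina under the defaults; VASO, being linear in CBV, is immune.
* The Z conversion ignores temporal autocorrelation.
* The VASO-to-CBV conversion (`vt_from_vaso()`) assumes complete blood
  nulling and a known baseline CBV fraction (default 0.055 ml/ml); both
  enter *M* as scale factors.
* Only relative laminar shape of *M* is scientifically constrained; κ and
  [dHb]₀ are arbitrary positive constants fixed via `m_pial`.
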