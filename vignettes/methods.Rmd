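---
title: "Methods: laminar deficit indices and SSVEP frequency tagging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laminar deficit indices and SSVEP frequency tagging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminocular)
```

`laminocular` implements two complementary analysis arms for studying
monocular processing and binocular interactions in visual cortex — a
laminar (cortical-depth-resolved) BOLD fMRI arm and an EEG SSVEP
frequency-tagging arm — together with a seeded synthetic-data generator
that makes every stage testable by parameter recovery. This vignette
explains the models, the parameters that matter, the numerical choices,
and what the recovery tests do and do not establish.

## The two indices

Both arms quantify the same two effects:

* **Amblyopic deficit index (ADI)** — the proportional response loss of
  the amblyopic eye (AE) relative to the fellow eye (FE),
  $\mathrm{ADI} = (R_{FE} - R_{AE}) / R_{FE}$. Because it is a ratio, a
  pure feedforward gain change (for instance the depth-dependent venous
  amplitude bias of gradient-echo BOLD) cancels: if the deficit arises at
  the thalamic input and simply propagates, the ADI is flat across
  cortical depth, whereas depth-specific interactions (e.g. lateral
  inhibition between ocular dominance columns in the superficial layers)
  bend the laminar ADI profile.
* **Binocular suppression index (BSI)** — the fraction of one eye's
  monocular response suppressed under binocular viewing,
  $\mathrm{BSI} = 1 - R_{\mathrm{bino}} / R_{\mathrm{mono}}$, computed
  per eye.

## Laminar fMRI arm

### Equivolume depth

Cortical layers keep their relative *volume*, not their relative
thickness, as the cortex folds. The depth coordinate therefore models the
local cross-sectional area of a cortical column as varying linearly from
the pial neighbourhood area $A_p$ to the white-matter neighbourhood area
$A_w$ (1-ring barycentric vertex areas on a pair of corresponding
triangle meshes). The surface enclosing pial-side volume fraction
$\alpha$ sits at the Euclidean fraction $x$ solving

$$\int_0^x \left[(1-t)A_p + t A_w\right] dt \;=\; \alpha\,\frac{A_p+A_w}{2},$$

a quadratic with the closed-form root used by `equivolume_frac()`. The
estimator generates `n_surfaces` (default 11) intermediate surfaces at
equispaced $\alpha$, assigns each voxel centre to its nearest vertex
column, and interpolates depth linearly between the two nearest surfaces.
Eleven surfaces keep the piecewise-linear interpolation error of the
quadratic depth map below $2\times10^{-3}$ for a 2:1 area ratio; the
tests verify the closed form against numerical integration to $10^{-6}$.
Degenerate vertices ($A_p = A_w = 0$) are excluded from assignment, and a
voxel centre belongs to gray matter only if it projects strictly between
the surfaces (`tol = 0`) within `max_dist` (default: the median white
edge length) of a column.

Layer compartments are the exact equivolume tertiles (superficial
$d < 1/3$, middle, deep $d \ge 2/3$) rather than empirical voxel-count
tertiles, so the equal-volume definition holds independently of voxel
sampling density.

The test fixtures are parametric ribbons. The `wedge` is a curved gyrus
crown built from concentric half-cylindrical sheets: columns are exactly
radial, the per-vertex area ratio is exactly the radius ratio, and
cross-sectional area varies linearly with depth — the geometry the
equivolume model assumes — so compartment volumes can be checked against
exact thirds (the suite requires 1% of one third, on a 0.1 mm grid).

### GLM and vein exclusion

The block GLM regresses each voxel's raw time series on boxcar
regressors convolved with a canonical gamma-difference response
(`hrf_gamma`, peak 5 s, 10% undershoot), an intercept, and Legendre
drifts (order 3 by default). Betas are rescaled to percent signal change
against the *fitted baseline* (the model intercept) rather than the
voxel temporal mean: the temporal mean contains stimulus-evoked signal
and would bias the scaling by the design's duty cycle (about 1% here),
while the intercept is the drift-model's estimate of rest-state
intensity and makes noiseless recovery exact. The same kernel object is
shared by the simulator and the GLM, a deliberate self-consistency
choice: the recovery tests then isolate errors in the depth, masking,
and unmixing stages rather than kernel mismatch.

Large veins produce dark voxels in T2\*-weighted EPI and implausibly
large signal changes. A vertex is flagged when its column-mean EPI
intensity falls below 0.70 of the across-vertex average or its mean
response exceeds 10 percent signal change; the whole column is then
excluded at every depth, never partially, so vein exclusion cannot
reshape a laminar profile by removing only some depths.

### Inverted encoding model

Each voxel's response is modelled as a linear mixture of two monocular
channels, $Y = WC$. With monocular stimulation the channel state is
known ($C = [1\;0]^\top$ or $[0\;1]^\top$), so the non-negative mixing
weights $W$ are fit per voxel by Lawson–Hanson non-negative least
squares (negative monocular betas are clamped, not excluded — weak
voxels carry information about the opposing channel). The binocular
condition is then inverted by unconstrained OLS *pooled across the
voxels of each depth bin* — per-voxel inversion is impossible (one
observation, two unknowns) — giving $C_{\mathrm{bino}}$ and
$\mathrm{BSI} = 1 - C_{\mathrm{bino}}$ per eye per depth. No
regularisation is added: bins whose weight matrix is rank deficient are
reported as ill-posed rather than patched. The point of the inversion is
to undo the partial-volume dilution that makes naive binocular/monocular
ratios underestimate suppression in ocular-biased voxels; the noiseless
end-to-end test requires recovery of the planted BSI to $10^{-6}$ under
40% partial-volume mixing.

### Ocular-bias ROIs

Binocular deficits are measured in the vertices most biased toward each
eye: the top and bottom 10% of the surface AE−FE beta distribution
(pooled, not per hemisphere), ties broken by stable vertex order. A
split-half utility defines ROIs on odd runs to read out even runs and
vice versa, averaging the two, which removes selection bias when the
same noisy data would otherwise both select and quantify.

## EEG frequency-tagging arm

Dichoptic stimulation tags the two eyes at 7.2 and 8 Hz (assignment
counterbalanced), in a 2 spatial frequencies × 3 ocularities × 2
assignments = 12-condition grid. The analysis chain is:

1. **Band-pass 1–30 Hz** (amplitudes) or **6–9 Hz** (phase), as a
   windowed-sinc linear-phase FIR applied by FFT convolution with exact
   group-delay compensation — zero phase at all frequencies, passband
   within 1%, stopband beyond 40 dB. The default transition width is
   `min(1.5, lo, srate/2 - hi)` Hz; at 1000 Hz this keeps the filter
   edge shorter than the discarded trial onset (see below).
2. **Surface Laplacian**: mean of six central occipital electrodes minus
   mean of nine parietal/parieto-occipital surround electrodes; signals
   common to the whole montage cancel exactly.
3. **Trial averaging** over the last 5 s of each 6-s trial (amplitudes)
   or 1.25–5 s (phase). The discarded first interval avoids the
   stimulus-onset transient — in this implementation it also absorbs the
   filter's edge response. All trials are included; SSVEPs are robust to
   blink artifacts and no rejection is performed.
4. **Amplitude spectrum** normalised so a unit sinusoid on an exact bin
   reads 1.0. The 5-s window gives 0.2 Hz resolution, placing 7.2, 8,
   14.4, 16, and the intermodulation frequency 15.2 Hz on exact bins
   (asserted up front); the 3.75-s phase window spans 27 cycles of
   7.2 Hz and 30 cycles of 8 Hz.
5. **Harmonic summation**: the response to a tag is the amplitude at the
   fundamental plus the second harmonic, summed per tag assignment first
   and then averaged across the two assignments (the order follows the
   analysis convention; summation before averaging keeps each
   assignment's harmonics together).
6. **Indices**: ADI within viewing condition, BSI per eye; indices whose
   monocular amplitude does not exceed the local noise floor (mean of
   the 10 nearest non-signal bins) are flagged unreliable.
7. **Intermodulation**: the amplitude at $f_1 + f_2 = 15.2$ Hz, a
   response only a nonlinear combination of the two eyes' inputs can
   generate; its reduction indexes weakened binocular integration.
8. **Phase**: a least-squares fit of $a\cos 2\pi f t + b\sin 2\pi f t$
   over the integer-cycle window, with the cosine convention
   $\varphi = \mathrm{atan2}(-b, a)$ so a response delayed by $d$ has
   phase $-2\pi f d$. Only phase *differences* enter the results, which
   are convention-invariant. Per-eye delays are computed per tag
   frequency (AE and FE phases compared at the same frequency across
   the two assignments), converted to milliseconds, then averaged across
   the two frequencies — millisecond-domain averaging avoids comparing
   radians across different periods. The single-frequency fit is the
   default; fitting both tags jointly changes nothing on exact bins
   where the regressors are orthogonal.

## Group statistics

* **Outliers**: each subject's measurements form a point in
  $d$-dimensional space; points whose squared Mahalanobis distance
  exceeds the upper 1% tail of $\chi^2_d$ (the likelihood reading of the
  1% rule) are excluded from subsequent tests. The sample mean and
  ordinary covariance are used unless population parameters are
  supplied; the rule is affine-invariant.
* **Bootstrap CIs**: seeded percentile bootstrap of the mean.
* **Circular statistics**: the circular mean is the resultant direction;
  the one-sample delay test rejects when the null direction lies outside
  the Zar/Fisher confidence cone of the mean (the contract of the
  toolbox routine it mirrors: reject iff 0 outside the CI, at
  $\alpha = 0.05$ two-sided by default, since only p-values, not levels,
  are conventionally printed); the two-sample Watson–Williams test uses
  the concentration-corrected F statistic with Fisher's
  $\hat\kappa$ approximation and reports a validity flag (pooled
  resultant $\ge 0.45$, $n \ge 5$ per sample). These are hand-written
  because no circular-statistics package is declared as a dependency;
  both are verified against brute-force/transliterated oracles and
  Monte-Carlo type-I error checks.
* **Coupling**: Pearson correlation between the per-subject binocular
  ADI excess (binocular − monocular) and the BSI asymmetry (AE − FE),
  after outlier exclusion.

## The synthetic-data generator

The generator is first-class, tested code. It emulates:

* **fMRI**: 282-s runs (9 × 18-s stimulus + 10 × 12-s fixation blocks,
  pseudo-randomised and counterbalanced per seed; the within/across-run
  balancing constraint is exposed only through the seed), voxels on a
  regular grid inside a parametric ribbon, ocular mixing weights from a
  smoothed sinusoidal band pattern mimicking ocular dominance columns
  (band period 2 mm, partial-volume mixing strength configurable,
  integer band counts keep the two channels' means equal), a superficial
  depth gain (`1 + (1 - d)`), planted ADI/BSI laminar profiles, vein
  columns with 3× signal and 0.6× intensity, and AR(1) noise
  ($\rho = 0.3$) — the noise model is a design choice, as is the
  sinusoid-plus-harmonic reading of the on/off flicker below.
* **EEG**: 6-s trials at 1000 Hz on the 15-electrode montage with a
  fixed 5:1 central:surround projection (no head model), first and
  second harmonics per eye (defaults 2 and 1 µV for FE, scaled by
  1 − ADI for AE), binocular components scaled by $1-\mathrm{BSI}$ plus
  an intermodulation sinusoid (0.5 µV), planted AE delay 12.81 ms, and
  1/f + white Gaussian noise (3 µV, exponent 1, 30% white floor).
  Trials are separated by 2-s gaps so that filter transients at the
  recording level never reach the analysis windows; the paper-level
  defaults (20 trials per condition) are the generator's defaults, and
  smaller sizes used in tests are stated where used.

What the generator does **not** emulate — and hence what passing
recovery tests do not establish about real data: hemodynamic
nonlinearity and HRF variability, EPI distortion and motion,
draining-vein spatial correlation beyond a per-column gain,
non-sinusoidal steady-state waveforms, eye movements and blinks,
electrode impedance drift, volume conduction beyond the fixed
projection, and between-session variability. The tests establish that
the *estimators are correct under their own model assumptions* and
numerically stable at realistic SNR, not that the assumptions hold in
patients.

## Problem sizes and numerical choices

Recovery suites run at desk scale by design: meshes of 400–900 vertices,
0.1–0.5 mm voxel grids (about $2\,800$–$190\,000$ gray-matter voxels),
2–4 runs, 2–8 EEG trials per condition, and 5–10 synthetic subjects.
Group-level quantities reported by `scripts/acceptance.R` use 10
subjects with 6 trials per condition; headline subject counts of the
order of the original cohorts are not reproducible at desk scale, and
group effect sizes here describe the synthetic population. Ties in ROI
selection break by vertex index; empty depth bins are reported missing,
never zero; ill-posed IEM bins propagate as missing; off-grid analysis
frequencies are rejected with the nearest-bin offset named rather than
silently rounded.
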