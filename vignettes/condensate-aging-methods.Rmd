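---
title: "Methods: quantifying condensate aging with condaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying condensate aging with condaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condaging)
```

`condaging` implements the measurement stack used to characterize the
age-dependent liquid-to-solid transition of multi-component RNA–protein
condensates: intra-condensate RNA clustering from confocal images, interior
material state from passive bead nanorheology, molecular mobility from
FRAP, thermoresponsive phase behavior and percolation from temperature
ramps, and interfacial dynamics from droplet-fusion force relaxations.
This vignette documents the models, the parameters that matter, the
numerical conventions, and the boundaries of what the synthetic validation
does and does not establish.

## Video-particle-tracking nanorheology

### Model and conventions

Thermal motion of embedded tracer beads (radius *R* = 0.1 μm by default:
200 nm diameter fluorophore-labelled beads) reports on the surrounding
medium. Tracking is two-dimensional (epifluorescence/confocal movies), so
free diffusion follows MSD(τ) = 4Dτ and the Stokes–Einstein relation
D = k_B·T/(6πηR) converts the terminal slope to a viscosity. Temperature
defaults to 298 K (room-temperature experiments) and is configurable
everywhere it enters.

`compute_msd()` forms, per trajectory, the time-averaged MSD over all
start points, and ensemble-averages per lag as the **unweighted mean over
trajectories** (`"ensemble_of_time_averages"`). The alternative pair-count
weighting is available as `mode = "all_displacements"`. Lags are limited
to `max_lag_fraction = 0.25` of the trajectory length because the number
of independent displacement segments collapses at longer lags and the
estimator variance diverges.

Static localization error σ adds a lag-independent offset 4σ² to the MSD.
It is **not** subtracted by default; the terminal fit (`terminal_viscosity`)
is ordinary least squares of MSD against lag, whose intercept absorbs the
offset, so the extracted D is unbiased regardless. The terminal window
defaults to the last decade of available lags and is gated on the local
log–log slope lying in [0.8, 1.2]; outside that range the routine raises a
typed `no_terminal_viscosity` error rather than reporting a meaningless
viscosity — plateaued or arrested materials have no terminal viscosity by
definition.

### Material classification

`classify_material()` reduces the MSD shape to two log–log slopes
(`fit_loglog_slope`): α_short over the first decade of lags and α_long
over the last. The decision rule, with defaults α_fluid = 0.8 and
α_solid = 0.2:

| α_long            | α_short   | class                         |
|-------------------|-----------|-------------------------------|
| ≥ 0.8             | ≥ 0.8     | `newtonian`                   |
| ≥ 0.8             | < 0.8     | `viscoelastic_fluid`          |
| [0.2, 0.8)        | any       | `viscoelastic_fluid` (low confidence) |
| < 0.2             | —         | `kelvin_voigt_solid` if the plateau exceeds the static-error floor, else `arrested` |

The slope thresholds are this package's operational choice — visual MSD
shapes are the field's usual criterion — and are configurable through
`material_thresholds()`. The static-error floor is best estimated from the
shortest-lag MSD of arrested control beads (4σ² for localization noise σ)
and supplied via `static_floor_um2`; without it, a flat-profile heuristic
(plateau within `floor_mult` = 3× of the shortest-lag MSD) separates caged
from arrested beads, which is reliable only when the caging time is well
resolved by the frame interval. A Maxwell-like crossover whose terminal
regime is only partially reached lands in `viscoelastic_fluid` with the
low-confidence flag rather than being forced into a corner class.

### Localization and linking

`detect_particles()` finds strict 8-neighborhood maxima above a threshold
and refines them by an intensity-weighted centroid in a window of the
expected spot diameter, after subtracting the local window minimum; this
is adequate at the signal-to-noise of tracer movies and keeps the contract
simple (Gaussian PSF fitting would add precision the downstream statistics
do not need). Detections closer than half a diameter merge, keeping the
brighter. `link_trajectories()` performs greedy nearest-neighbor
assignment with global conflict resolution — all candidate pairs within
`max_disp` are sorted by squared displacement and accepted each-once — with
gap bridging up to `memory` frames. Crowded fields degrade into shorter
tracks (reported in the linking report) rather than mislinks across large
distances. `correct_drift()` subtracts the cumulative per-frame ensemble
median displacement; with a single particle this removes all motion and
warns.

## Spatial autocorrelation (SAC) imaging

`spatial_autocorrelation()` computes the mean-subtracted autocovariance of
the image restricted to the condensate mask, via zero-padded FFTs, and
divides lag-by-lag by the mask's own autocorrelation (the number of
in-mask pixel pairs at that lag). This mask normalization removes the edge
bias a finite condensate would otherwise imprint on the correlation decay.
The map is normalized to 1 at zero lag and radially averaged in one-pixel
annuli. A constant image has no defined correlation structure and raises
an error.

`cluster_size()` reports the lag at which the radial profile first falls
to 1/e, by linear interpolation between annuli. For a Gaussian intensity
cluster of width σ the autocovariance is exp(−r²/4σ²), so the measure
equals 2σ exactly. Conventions and degenerate cases:

- the 1/e search starts at a lag of one pixel, because uncorrelated
  (shot/readout) noise contributes a delta at zero lag only;
- the result is floored at one pixel and flagged `at_floor` when ≤ 1.5
  pixels — spatial fluctuations at the image resolution are a detection
  limit, not a measured size;
- profiles that stay above 1/e through half the field of view are
  censored (`censored = TRUE`, size `NA`) instead of reporting a size the
  window cannot support.

Because the size convention (1/e of the normalized autocovariance) is this
package's declared estimator, agreement with sizes obtained under other
conventions is expected only up to trends and the detection-floor
behavior, not digit-for-digit.

`pairwise_line_profile()` samples two co-registered channels along a line
(bilinear interpolation, averaged across a configurable width), normalizes
each profile by offsetting its minimum to 0 and dividing by its maximum,
and reports the Pearson correlation — negative values quantify the
core–shell anti-correlation between RNA clusters and the scaffold.
`cluster_fraction()` segments cluster pixels with a robust threshold
(median + k·MAD-σ, k = 3 by default) so the bright cluster tail cannot
inflate its own threshold, and reports background-subtracted cluster
intensity over background-subtracted condensate intensity; a homogeneous
condensate returns 0.

## FRAP

`normalize_frap()` applies the field-standard double normalization:
background subtraction, division of the bleached ROI by an unbleached
reference (correcting acquisition photobleaching), and rescaling so the
pre-bleach mean is 1. Without a reference channel it falls back to single
normalization and flags the output. `fit_frap()` fits the single
exponential I(t) = I₀ + A(1 − e^(−t/τ)) by bounded Levenberg–Marquardt,
with starts taken from the curve itself (post-bleach intercept, tail
plateau, 63% crossing). The mobile fraction is A/(1 − I₀) — the recovered
fraction of the bleached intensity — clipped into [0, 1] with a flag; the
half-time is τ·ln 2. Diffusion-model FRAP (bleach-spot geometry, D
extraction) is deliberately out of scope; with a single-exponential model,
recovery amplitudes and times are comparable across ages and channels,
which is what the aging analysis needs. Non-convergent fits return NaN
parameters with `converged = FALSE`, never silently.

## Temperature ramps and state diagrams

`detect_cloud_point()` defines the lower cloud-point temperature (LCPT) as
the first crossing of baseline mean + k·SD (k = 5), with the baseline
taken from the first 20% of the heating leg and the crossing refined by
linear interpolation. The baseline SD is floored at 10⁻³ of the signal
range so the statistic remains defined on noiseless traces. Two
consequences worth knowing: ramps should start comfortably (≥ ~10 °C)
below the expected transition so the baseline window is clean, and the
k·σ crossing sits slightly below the sigmoid midpoint, so the estimate
carries a small negative bias that shrinks as noise grows toward the
threshold — at signal-to-noise 10 the error stays well under 1 °C for
sharp (sub-degree) transitions.

`assess_reversibility()` compares the end-of-cooling signal (coolest 10%
of the cooling leg) with the heating baseline: hysteresis strictly greater
than `tol` (default 0.1 in units of the transition amplitude) is
irreversible; exactly `tol` is reversible (documented tie-break).
`classify_state_point()` maps a condition to `soluble` (no transition),
`reversible_ps`, or `percolated` (hysteresis, or clusters already present
at the start — supplied as the `pre_percolated` flag on the condition, not
inferred from the trace). `build_state_diagram()` orders points along the
Mg²⁺ axis and places the percolation boundary at the midpoint between the
highest non-percolated and lowest percolated concentration; a
non-monotone classification sequence is flagged but still assembled.

`fit_fusion_relaxation()` fits F(t) = F∞ + ΔF·e^(−t/τ) and normalizes τ
by the **arithmetic mean of the two droplet diameters** (ms/μm) — the
normalizing length is not standardized in the literature, so it is
declared here and used consistently. Fits with τ beyond a third of the
trace span, or with non-positive relaxation amplitude, are flagged
unreliable and carry no normalized value.

## The synthetic-data generator

Every analysis stage is validated by parameter recovery on synthetic data
with recorded ground truth, at the conditions the measurements are
designed for:

- **Trajectories** (`gen_trajectories`): Newtonian as Gaussian increments
  with per-axis variance 2D·dt; Kelvin–Voigt as an exactly discretized
  stationary Ornstein–Uhlenbeck process with per-axis SD equal to the
  confinement length (2D plateau 4·sd²); Maxwell-like as the sum of an
  independent confined term and a free-diffusion term at the terminal
  viscosity, which reproduces the sub-linear-then-linear MSD shape without
  committing to a specific constitutive model; arrested as constant
  positions. Localization noise is i.i.d. per frame; drift accumulates
  across frames. No hydrodynamic coupling between beads is modelled.
- **Images** (`gen_condensate_stack`): a uniform condensate disk plus
  Gaussian clusters whose width and brightness grow with sample age by a
  saturating-exponential `aging_law()`; an anti-correlated scaffold
  channel depleted under the clusters (clipped at 0); Gaussian PSF blur
  (sum-preserving FFT convolution); Poisson (default) or Gaussian noise.
  Pixels are 0-based with pixel-center physical coordinates; presets match
  common confocal samplings of 0.2196 and 0.09765 μm/pixel. Clusters
  narrower than half a pixel are flagged sub-resolution in the ground
  truth. No 3D PSF and no camera-specific noise calibration.
- **Curves**: FRAP recoveries with configurable mobile fraction, τ, bleach
  depth, reference photobleaching and background; heating/cooling ramps as
  logistic steps (width 0.25 °C — a sharp cloud point) with optional
  hysteresis; exponential force relaxations.

All generators are bit-deterministic given their seed.

Passing recovery tests on these inputs establishes that the estimators are
correct and unbiased under their own assumptions at realistic noise. It
does **not** establish robustness to what the generator deliberately omits:
aspherical or fractal clusters, spatially varying backgrounds, bead–bead
interactions, anomalous (non-OU) caging, multi-exponential FRAP, gradual
(broad) cloud-point transitions, or drift during ramps. Real-data use
should treat the flags (`at_floor`, `censored`, `low_confidence`,
`reliable`, `clipped`) as first-class results.

## The aging pipeline and study conditions

`run_aging_pipeline()` composes the stages over a simulated time course.
The `"wt"` scenario encodes the canonical aging progression: cluster width
growing toward σ = 0.45 μm (SAC size ≈ 0.9 μm) on a 1.5 h timescale,
interior viscosity stepping through 35.2 → 150 → 489 Pa·s before complete
arrest, and RNA FRAP mobility decaying while the scaffold stays mobile.
The `"mut"` control holds a cluster-free condensate at 35.2 Pa·s with
constant mobility. The tracking acquisition interval is scaled with the
expected viscosity (dt = 0.1·η seconds) so the per-lag displacement
signal-to-noise is constant across the stiffness range — the VPT analogue
of choosing an exposure for the sample. Per-age stage failures are
recorded in the report and do not abort the remaining ages; reports embed
the fully resolved configuration and package version.

Problem sizes used throughout the tests and the acceptance script — 100
beads × 300 frames for viscosity recovery, 50 seeds × 4 classes × 30
beads for classification, 128–192 px images, 50-seed ramp suites — are
desk-scale choices that keep each suite in seconds while leaving the
recovery statistics comfortably inside their tolerance bands.

## Numerical and design notes

- Exponential fits (FRAP, fusion) run bounded Levenberg–Marquardt on the
  residual function directly (`minpack.lm::nls.lm`); degenerate flat
  traces then surface as flagged non-identifiable fits instead of
  construction errors in a model-object wrapper.
- The SAC FFT path divides by the mask autocorrelation only where at least
  one pixel pair exists; other lags are undefined (NA) rather than zero.
- `cluster_fraction` uses median/MAD rather than mean/SD so segmentation
  is stable in the presence of the clusters being segmented.
- Image-level SNR (sd of signal over sd of noise) is the convention used
  when stating noise robustness for SAC; peak-amplitude SNR understates
  the information in sparse-cluster images.
- CSV writers emit doubles at 17 significant digits (exact round trip);
  TIFFs are 32-bit float with a fixed intensity scale of 65535, exact to
  single precision.
- The package exposes its functionality as an R API plus
  `run_aging_pipeline()`; a shell entry point is intentionally not
  shipped, as the intended users drive analyses from R scripts, and
  `scripts/acceptance.R` demonstrates the scripted path end to end.

## Known limitations

- No generalized Stokes–Einstein inversion to frequency-dependent moduli
  G*(ω); classification and terminal viscosity only.
- The linking stage is single-hypothesis; extreme densities or fast
  dynamics call for dedicated trackers.
- SAC assumes an isotropic correlation structure; strongly anisotropic
  clusters would need the full 2D map (which is returned) rather than the
  radial profile.
- Cloud-point detection presumes a monotone baseline-then-rise heating
  leg; multi-step transitions are outside the contract.
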