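# condaging

Quantitative analysis of the age-dependent liquid-to-solid transition of
RNA–protein condensates.

Biomolecular condensates formed by repeat-expansion RNAs (such as telomeric
TERRA, (UUAGGG)ₙ) together with scaffold proteins can *age*: RNA demixes
within the condensate into progressively larger clusters, the condensate
interior stiffens by orders of magnitude, RNA mobility drops, and
heat-induced phase separation becomes irreversible once the RNA network
percolates. `condaging` is an R toolbox for the measurements that quantify
this progression from fluorescence microscopy and micromanipulation data:

- **SAC imaging** — mask-aware spatial autocorrelation of confocal images,
  a 1/e correlation-length cluster size with a detection-floor flag,
  pairwise line-profile anti-correlation between channels, and the
  intensity-based fraction of signal residing in clusters.
- **VPT nanorheology** — particle localization, trajectory linking, drift
  correction, time-/ensemble-averaged MSD, viscoelastic classification
  (Newtonian / Maxwell-like fluid / Kelvin–Voigt solid / arrested), and
  terminal viscosity via Stokes–Einstein.
- **FRAP** — double normalization and single-exponential recovery fits
  (mobile fraction, τ, t₁/₂).
- **Phase kinetics** — cloud-point detection on heating ramps,
  reversibility classification on cooling, RNA state diagrams over Mg²⁺
  titrations with a percolation boundary, and droplet-fusion force
  relaxation times (ms/μm).
- **Synthetic data** — generators with known ground truth for every input
  (bead trajectories in four material regimes, core–shell condensate image
  stacks, FRAP curves, heating/cooling ramps, force relaxations), so each
  stage is validated by parameter recovery.

## The core relations

For a tracer bead of radius *R* in a 2D-tracked movie, free diffusion obeys

    MSD(τ) = 4Dτ,    D = k_B T / (6π η R)

so the terminal (long-lag) MSD slope yields the terminal viscosity η.
Localization noise adds a constant 4σ² offset, absorbed by the fit
intercept. The log–log MSD slope α distinguishes materials: α ≈ 1 at all
lags (Newtonian), α < 0.8 at short lags crossing to ≈ 1 (Maxwell-like
fluid), α ≈ 0 with a plateau above the noise floor (Kelvin–Voigt solid,
caged tracers), and MSD pinned at the noise floor (arrested).

For an image I restricted to a condensate mask W, the normalized spatial
autocovariance is computed by FFT with lag-wise mask normalization,

    G(d) = [ Σ δI(r) δI(r+d) W(r) W(r+d) ] / [ Σ W(r) W(r+d) ],  δI = I − ⟨I⟩_W

normalized to G(0) = 1 and radially averaged. The cluster size is the lag
where the radial profile first falls to 1/e (for a Gaussian cluster of
width σ this is exactly 2σ); sizes at ≤ 1.5 pixels are flagged as the
resolution floor.

FRAP recoveries are fit as I(t) = I₀ + A(1 − e^(−t/τ)) with mobile
fraction A/(1 − I₀); fusion force traces as F(t) = F∞ + ΔF·e^(−t/τ) with
the relaxation time normalized by the mean droplet diameter.

## Worked example

Nanorheology on simulated beads in a 35.2 Pa·s condensate:

```r
library(condaging)
model  <- material_model("newtonian", viscosity_Pa_s = 35.2)
beads  <- gen_trajectories(model, n_particles = 60, n_frames = 300,
                           dt_s = 3.5, loc_noise_sd_um = 0.005, seed = 42)
profile <- compute_msd(beads)
analyze_rheology(profile,
                 thresholds = material_thresholds(static_floor_um2 = 4 * 0.005^2))
#> Material classification: newtonian
#>   alpha short/long: 0.961 / 0.988
#>   terminal viscosity: 35.6 Pa.s (D = 6.13e-05 um^2/s)
```

The recovered viscosity (35.6 Pa·s) matches the simulated ground truth
(35.2 Pa·s) within sampling error, and both log–log slopes near 1 identify
a Newtonian liquid.

The end-to-end aging driver composes all stages over a simulated time
course:

```r
print(run_aging_pipeline(run_config("wt", seed = 5)))
#> Aging pipeline (wt scenario), 4 ages
#>   age_h cluster_size_um at_floor cluster_fraction pearson_r material_class
#> 1   0.5           0.220     TRUE          0.00288    -0.387      newtonian
#> 2   1.0           0.220     TRUE          0.01878    -0.782      newtonian
#> 3   1.5           0.422    FALSE          0.06274    -0.976      newtonian
#> 4   5.0           0.954    FALSE          0.24099    -0.973       arrested
#>   eta_Pa_s frap_mobile
#> 1     35.4       0.760
#> 2    136.2       0.639
#> 3    518.5       0.548
#> 4       NA       0.203
#> cluster-size trend tau = 0.91; line-profile r trend tau = -0.67
```

Read: cluster size starts at the resolution floor (0.22 μm at 0.2196
μm/pixel) and grows to ~0.95 μm; terminal viscosity rises an order of
magnitude before the final age is called arrested (no terminal regime);
the RNA/scaffold line-profile Pearson r becomes strongly negative
(core–shell anti-correlation); RNA mobility by FRAP falls. The `"mut"`
control scenario shows none of these trends.

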