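# flimcrowd

Fluorescence-lifetime sensing of macromolecular crowding: TCSPC decay
simulation and fitting, FLIM condensate phenotyping, time-resolved anisotropy,
FCS, lifetime-vs-FVO calibration, and protein-pocket volumetrics — in one R
package, with every simulator the generative inverse of its estimator.

## The problem

The fluorescence lifetime of monomeric fluorescent proteins such as mCherry
drops below its standard range (1.4–1.6 ns) only when the surroundings are
crowded by macromolecules above ~30% fractional volume occupancy (FVO);
salts and small viscogens leave it untouched. A calibrated boundary —
1.44 ns for mCherry — therefore turns fluorescence lifetime imaging (FLIM)
into a pixel-wise, concentration-independent density sensor: a pixel with
mean lifetime τ̄ < 1.44 ns reports local crowding at ≥30% FVO (the readout is
one-sided; longer lifetimes are "not resolved", not "dilute"). Applied to
biomolecular condensates this distinguishes a homogeneous liquid interior
(narrow pixel-lifetime histogram) from dense, heterogeneous sub-domain
organization (wide or bimodal histogram, means below the boundary).

The package is for microscopists and biophysicists who want to run this
analysis chain on TCSPC/FLIM-style data or validate it end to end on
synthetic data:

* **decays** — photon-level TCSPC simulation; bi-exponential reconvolution
  fits `I(t) = [a₁ e^(−t/τ₁) + a₂ e^(−t/τ₂)] ⊗ IRF` with Poisson-weighted
  least squares; mean lifetime τ̄ = Σaᵢτᵢ/Σaᵢ; χ²-surface confidence
  intervals; mono-exponential tail fits with photon gates (100 in-cell / 30
  in vitro);
* **images** — lifetime maps from photon-record streams (0 = no-estimate
  sentinel), per-condensate statistics against the 1.44 ns boundary,
  two-sided T/F population comparisons with star labels;
* **anisotropy** — r(t) = (I∥ − G·I⊥)/(I∥ + 2G·I⊥) with channel-shift
  estimation, 1–2 rotational components, the 0.4 photoselection cap, the
  Perrin relation r = r₀/(1 + τ/θ);
* **FCS** — multitau/direct correlators, two-component 3D diffusion fits
  `G(τ) = N⁻¹ Σ fᵢ (1+τ/τD,i)⁻¹ (1+τ/(s²τD,i))^(−1/2)` reporting the slow
  τD, bi-exponential photobleaching fits;
* **calibration** — FVO conversion, segmented-regression onset detection
  (~30% FVO), tryptophan-spectrum area/λmax and the sigmoid transition
  (midpoint 23.3% FVO);
* **pocket volumetrics** — contact-frequency pocket definition (>0.33% of
  snapshots, 3.5 Å any-atom cutoff), convex-hull Cα pocket volumes with SEM
  over replicas, Cα distance-difference maps, hydrogen bonds (3.5 Å / 150°),
  Shrake–Rupley SASA, first-quarter equilibration trimming.

## Worked example

Simulate a TCSPC decay of an mCherry-like fluorophore at the crowding
boundary and recover its lifetime:

```r
library(flimcrowd)

spec <- decay_sim_spec(component_lifetimes = 1.44, component_amplitudes = 1,
                       irf_fwhm = 0.1,        # 100 ps FWHM pulse
                       repetition_window = 50, # 20 MHz repetition
                       n_photons = 1e5, seed = 1)
h <- simulate_tcspc_decay(spec)
tail_fit_monoexponential(h, min_photons = 100)
#> [1] 1.445054
#> attr(,"amplitude") ...

irf <- gaussian_irf(0.1)
fit <- fit_convolved_biexponential(
  simulate_tcspc_decay(decay_sim_spec(c(0.8, 1.7), c(0.14, 0.86),
                                      n_photons = 1e6, seed = 5)), irf)
print(fit)
#> conv_biexp fit (chi2red 0.377): converged = TRUE
#>   tau1 = 0.8183 ns  (amplitude 0.267, photon fraction 0.148)
#>   tau2 = 1.7091 ns  (amplitude 0.733, photon fraction 0.852)
#>   mean lifetime (amplitude-weighted) = 1.4715 ns
classify_fvo_regime(fit$mean_lifetime, boundary = 1.44)
#> [1] "not_resolved"
```

The tail fit returns 1.445 ns (truth 1.44 ns); the bulk reconvolution fit
recovers both components and a mean lifetime of 1.472 ns, inside the standard
mCherry range, so the crowding readout is "not resolved" (below 30% FVO
cannot be distinguished from dilute).

A FLIM scene with a dense condensate:

```r
sc  <- simulate_flim_scene(flim_scene_spec(
  c(24, 24), list(list(center = c(12, 12), radius = 7, lifetime = 1.2)),
  background_lifetime = 1.5, photon_budget = 500, seed = 5))
img <- build_lifetime_image(sc$stream, c(24, 24), min_photons = 100)
condensate_statistics(img, sc$labels, boundary = 1.44)
#>   roi n_pixels mean_lifetime sd_lifetime fraction_below           class empty
#> 1   1      149      1.201531  0.06458022              1 above_30pct_FVO FALSE
```

The condensate's mean pixel lifetime (1.202 ns) sits below the boundary:
its interior is crowded at ≥30% FVO.

## Photon-record stream format

Columnar CSV, one row per detected photon:

```
frame,x,y,channel,microtime_ns
1,11,4,0,0.93
1,11,4,0,2.10
1,12,4,0,0.41
1,12,4,0,1.77
1,12,4,0,5.02
1,12,5,0,0.08
1,13,5,0,2.95
1,13,5,0,1.12
1,13,5,0,0.66
1,14,5,0,3.38
```

`x`/`y` are 0-based column/row pixel indices (row-major image, pixel
centers), `channel` is the polarization channel, `microtime_ns` the arrival
time within the repetition window.

## Command line

A thin CLI over the same functions ships in `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/flimcrowd-cli", package="flimcrowd"))')
$CLI fit-decay  --decay decay.csv --model conv_biexp --fwhm 0.1
$CLI fit-decay  --decay decay.csv --model tail_mono --min-photons 30
$CLI anisotropy --par par.csv --perp perp.csv --g 1 --shift auto
$CLI fcs        --traj traj.csv --components 2 --structure 5
$CLI calibrate  onset --table calibration.csv
$CLI calibrate  classify --lifetime 1.30 --boundary 1.44
```

## Package layout

* `R/` — simulators (`simulate_*`, `generate_*`), decay fitting
  (`fit_convolved_*`, `tail_fit_monoexponential`,
  `confidence_interval_mean_lifetime`), FLIM (`build_lifetime_image`,
  `condensate_statistics`, `compare_populations`), anisotropy, FCS,
  calibration, and trajectory geometry (`define_pocket`, `pocket_volume`,
  `sasa_shrake_rupley`, ...).
* `vignettes/lifetime-crowding-methods.Rmd` — the model, the numerical
  choices, and what the synthetic generators do and do not emulate.
* `tests/testthat/` — unit, property and end-to-end recovery suites.
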