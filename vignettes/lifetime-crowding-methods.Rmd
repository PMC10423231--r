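---
title: "Sensing macromolecular crowding with fluorescence lifetimes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensing macromolecular crowding with fluorescence lifetimes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimcrowd)
```

## The measurement idea

Monomeric fluorescent proteins such as mCherry show a reduction of their
fluorescence lifetime when the surrounding solution is crowded by
macromolecules above a threshold fractional volume occupancy (FVO) of roughly
30%, while salts and small viscogens leave the lifetime at its standard value
(1.4–1.6 ns for mCherry). The mechanistic picture is that external crowding
compresses the β-barrel enough to enlarge the rotational freedom of the
chromophore relative to the protein scaffold, opening a non-radiative
de-excitation channel. Because the lifetime is intensity- and
concentration-independent, a calibrated lifetime boundary (1.44 ns for mCherry
on the calibrating instrument) turns FLIM into a pixel-wise density sensor:
pixels whose lifetime falls below the boundary report local crowding at or
above ~30% FVO. The readout is one-sided by construction — lifetimes above
the boundary mean "not resolved", not "dilute" — and
`classify_fvo_regime()` implements exactly that convention.

This package implements the full analysis chain around that idea: TCSPC decay
simulation and fitting, FLIM image statistics, time-resolved and steady-state
anisotropy, FCS, the lifetime-vs-FVO calibration, and the trajectory
volumetrics used to support the mechanism. Every simulator is the generative
inverse of the matching estimator, so parameter recovery is testable end to
end without any external data.

## TCSPC decays: simulation and reconvolution fitting

`simulate_tcspc_decay()` draws photons at the event level: a decay component
(by photon weight), an exponential delay, Gaussian IRF jitter, and a wrap
modulo the repetition window. Defaults mirror a standard picosecond setup:
100 ps FWHM Gaussian IRF and a 50 ns window (20 MHz repetition). The window
wrap makes the simulator correct for lifetimes approaching the window even
though it is negligible at 1.5 ns.

`convolve_model_with_irf()` evaluates the model side. For a parametric
Gaussian IRF the convolution of each exponential component has a closed form
(the exponentially modified Gaussian); the curve is computed from its CDF so
bin values are exact bin averages, and the pulse-train wrap is summed
explicitly. For measured IRF histograms a discrete circular convolution is
used (`"fft"`, with an O(n²) `"direct"` twin retained as an oracle — the two
agree to 1e-9). The discrete path is first-order accurate in the bin width
near the pulse (the usual behavior of discrete reconvolution); the analytic
path is exact and is the default for Gaussian IRFs.

`fit_convolved_biexponential()` performs weighted least squares with
Levenberg–Marquardt. Weights start from the observed counts
(σ² = max(counts, 1)) and are then re-derived twice from the fitted model
(Pearson / iteratively reweighted least squares). The reweighting matters: with
observed-count weights, sparsely populated tail bins systematically drag
lifetimes down by ~1% at 2×10⁴ photons, which is visible against the
sub-percent statistical error and destroys confidence-interval coverage. With
model-based weights the estimator is unbiased to within simulation error and
the reduced χ² is calibrated (0.9–1.1 at 10⁶ photons on a fully populated
window). Components are reported sorted ascending; decay amplitudes
\(a_i\) and photon fractions \(a_i\tau_i/\sum a_j\tau_j\) are both returned.

The mean lifetime is amplitude-weighted by default,
\(\bar\tau = \sum a_i\tau_i / \sum a_i\), matching the convention of
calculating the mean from "component values and their amplitudes"; an
intensity-weighted variant \(\sum a_i\tau_i^2/\sum a_i\tau_i\) is available by
flag and is never smaller (Chebyshev's sum inequality, property-tested).

### Confidence intervals on the mean lifetime

`confidence_interval_mean_lifetime()` scans the χ² surface: per-parameter
profile grids plus a multivariate-normal candidate cloud shaped by the local
covariance, accepting parameter sets with
\(\chi^2 \le \chi^2_{min} + \max(\chi^2_{min}/(n-p), 1)\, p\, F_{p,n-p}(0.95)\)
and reporting the extreme mean lifetimes among accepted sets. Two numerical
choices are deliberate:

* the variance scale \(\chi^2_{min}/(n-p)\) is floored at 1. With Poisson
  weights the variances are known, and bins far in the empty tail of a 50 ns
  window contribute essentially no χ² mass; the raw F-ratio criterion would
  shrink the threshold several-fold and the interval with it. With the floor,
  the criterion coincides with the classical Δχ² = qchisq(0.95, p) rule
  whenever χ²red ≈ 1, and keeps the F-ratio inflation when the model misfits.
* the accepted region is the joint p-parameter region, so the projected
  interval for \(\bar\tau\) is conservative; measured coverage is ~97% at
  nominal 95% (200 repetitions in the test suite).

### Pixel-wise tail fits

FLIM pixels carry 30–1000 photons, far below the bulk regime, so
`tail_fit_monoexponential()` fits a single exponential to the histogram tail
starting `tail_start_offset` after the peak (default 0.2 ns = 2× the IRF FWHM,
a value the calibration does not pin down). The amplitude is profiled out
analytically and a one-dimensional search over the lifetime is run twice, the
second pass with Pearson weights from the first fit. Pixels below the photon
gate (100 in-cell, 30 in vitro) or with fewer than 3 nonzero tail bins return
a sentinel; in lifetime images the sentinel is exactly 0 ns and is excluded
from every downstream statistic.

## FLIM scenes and condensate statistics

`simulate_flim_scene()` emulates condensate images: disk-shaped regions on a
uniform background, each with a uniform lifetime or a two-subdomain split
(fraction of the disk at one value, the rest at another), Poisson photon
budgets per pixel, and photon micro-times drawn from the pixel's ground-truth
lifetime. Overlapping condensates resolve by "later entry wins". What the
generator does *not* emulate: irregular condensate shapes, spatial lifetime
gradients, detector afterpulsing, and scattering backgrounds — so passing
recovery tests demonstrate the correctness of the estimators under the stated
statistical model, not robustness to every feature of real images.

`condensate_statistics()` computes per-ROI means and standard deviations
strictly over gated pixels, the fraction of pixels below the boundary, and the
crowding class (mean below the boundary ⇒ above ~30% FVO). ROI masks are
externally supplied label images, mirroring manual ROI selection; an automatic
proposer is deliberately not part of any validated path. Population
comparisons use a two-sided Welch T-test (the safe default when only
"two-sided T-test" is specified; Student's by flag) and a two-sided
variance-ratio F-test with p = 2·min(P(F≤f), P(F≥f)), with the conventional
star mapping (n.s. / * / ** / ***).

## Anisotropy

Polarized decay pairs are combined as
\(r(t) = (I_\parallel - G I_\perp)/(I_\parallel + 2 G I_\perp)\) after
aligning the channels; the shift is estimated by cross-correlation with
parabolic sub-bin refinement. Bins with fewer than 25 denominator counts are
masked (keeps the relative error of r below ~20%). The G factor is always an
explicit input (1 for simulated data); rotational fits use
\(r(t) = r_0\sum w_i e^{-t/\theta_i}\) over a 10 ns window with one or two
components, the second accepted only on a >20% χ²red improvement — the
two-component signature is how enhanced chromophore mobility shows up above
the crowding threshold. The steady-state image path thresholds both
polarization channels (so condensate edges match across channels) and masks
any pixel above the theoretical cap of 0.4, which `limiting_anisotropy()`
derives from photoselection, \(r_0 = (3\cos^2\beta - 1)/5\). The Perrin
relation \(r = r_0/(1+\tau/\theta)\) quantifies why a shorter lifetime alone
would *raise* anisotropy, so the observed faster decay requires a fast
rotational mode.

## FCS

`simulate_fcs_trajectory()` runs Brownian emitters in a periodic box through a
3D Gaussian focus with optional excitation-driven irreversible bleaching.
The structure parameter defaults to s = w_z/w_xy = 5, a typical confocal
value declared rather than inferred. `autocorrelate()` offers the standard
multitau correlator (16 lags/octave, pairwise rebinning) and a direct
estimator; at unbinned lags the two are the same quantity and agree to
machine precision, while rebinned octaves are triangular-weighted averages by
construction (documented, tested at ~% level). The two-component 3D diffusion
model
\(G(\tau) = N^{-1}\sum_i f_i (1+\tau/\tau_{D,i})^{-1}(1+\tau/(s^2\tau_{D,i}))^{-1/2}\)
is fitted with a constant \(G_\infty\) offset (default on): finite traces
carry a negative correlogram bias at long lags that otherwise shortens fitted
diffusion times by ~15–20% at 10³ diffusion times per trace. Diffusion times
are bounded by the measured lag range, near-degenerate components are merged,
and the reported "slow" time is the slowest component carrying at least 5% of
the amplitude — fast components in cells often take non-physical values, so
components faster than 10 counting bins are flagged. Photobleaching is
fitted as \(A_1 e^{-k_1 t} + A_2 e^{-k_2 t} + c\) (fast-first); a valid FCS
readout requires both 1/k values to exceed the reported diffusion time, and
occupancy N from a bleached trace is not trustworthy (the bleach fit's
`decaying` flag is the warning sign).

## Calibration: onset and the tryptophan transition

`generate_calibration_table()` encodes the empirical shape of the
lifetime-vs-FVO curve — a plateau up to an onset near 30% FVO, then a linear
decline — and `detect_reduction_onset()` inverts it with a two-segment
changepoint fit, linear in the plateau and slope for each candidate
breakpoint, so only the breakpoint needs a grid search (0.1% FVO resolution,
observed grid points always included; exact on noiseless data). A flat-curve
F-test gate (p > 0.05, or a non-negative fitted slope) returns a no-onset
sentinel, and a residual-resampling bootstrap (200 draws by default) gives
the CI. The tryptophan-area transition is fitted with a four-parameter
logistic; the midpoint uncertainty comes from the covariance diagonal, the
fit accepts either sign of transition, and scaling the response rescales only
the plateaus (tested). FVO conversion from % w/v uses a partial specific
volume (0.84 mL/g typical for PEG, 1.0 for synthetic identity data) — the
original conversion constants are not published, so this stays an explicit
parameter.

## Trajectory volumetrics

The pocket pipeline works on generic coordinates (multi-frame XYZ with a
residue sidecar, or multi-model PDB via bio3d): the first quarter of each
trajectory is discarded as equilibration (`ceiling(fraction · n)` frames,
convention documented), residues contacting the target in more than 0.33% of
pooled post-equilibration snapshots (any-atom distance < 3.5 Å) form the
pocket, and the pocket volume is the convex-hull volume of the pocket Cα
atoms. With no qhull binding available in the environment, the hull is
computed by supporting-plane enumeration with planar-facet merging and
fan triangulation — O(n³) in points, exact for coplanar facets (a cube with
interior points is reproduced exactly), and validated against a Monte-Carlo
inside-hull oracle to <1%. Uncertainty is the SEM across replica
trajectories, each replica one observation. Hydrogen bonds use
donor–acceptor < 3.5 Å and a D–H···A angle ≥ 150° (boundary inclusive);
SASA is Shrake–Rupley with 960 golden-spiral points and standard van der
Waals radii. The toy barrel generator plants a chromophore stand-in at the
center of a residue shell whose radial expansion per state is the ground
truth; it is synthetic plumbing for validating the pipeline (contact
round-trips, volume dominance of expanded states), not a model of any real
protein.

## Problem sizes and seeds

All tests and the acceptance script run on a single CPU with explicitly
seeded generators. Typical sizes, chosen as the smallest that hold the
estimators to their stated tolerances: 10⁵–10⁶ photons for bulk decay fits,
50 repetitions for the boundary-lifetime recovery, 100 repetitions for the
sigmoid-midpoint and onset recoveries, 200 repetitions for the CI coverage
check, 12–30 s simulated traces for FCS recovery, and 20 condensates of
~200 gated pixels for the heterogeneity discrimination.

## Known limitations

* No global (multi-curve) decay fitting, phasor analysis, or >3 components.
* Anisotropy fits are not lifetime-associated; homoFRET is out of scope.
* FCS has no triplet/blinking term and no cross-correlation mode.
* The discrete reconvolution path is first-order in bin width near the pulse;
  use the analytic path for parametric IRFs.
* The hull algorithm is O(n³): intended for pockets of tens of residues, not
  thousand-point clouds.
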