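Package: flimcrowd
Title: Fluorescence-Lifetime Crowding Sensing: TCSPC, FLIM, Anisotropy, FCS
    and Pocket Volumetrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for fluorescence-lifetime-based sensing of macromolecular
    crowding. Simulates and fits time-correlated single photon counting (TCSPC)
    decays with instrument-response reconvolution, builds pixel-wise lifetime
    images from photon-record streams and extracts per-condensate density
    statistics, constructs and fits time-resolved fluorescence anisotropy
    decays (G factor, channel shift, Perrin relation), computes and fits
    fluorescence correlation spectroscopy (FCS) autocorrelation curves with a
    two-component 3D diffusion model plus bi-exponential photobleaching fits,
    manages lifetime-versus-fractional-volume-occupancy calibration curves
    (onset changepoint, sigmoid transition of tryptophan emission spectra), and
    analyzes protein trajectories (contact-frequency pocket definition,
    convex-hull pocket volumes, distance-difference maps, hydrogen bonds,
    solvent accessibility).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    bio3d,
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
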