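# Shared fixtures: all built in code at test time.

std_irf <- function() gaussian_irf(0.1)   # 100 ps FWHM pulse

# full-window uniform bin-center grid
window_grid <- function(window = 50, bin_width = 0.05) {
  seq(bin_width / 2, window - bin_width / 2, by = bin_width)
}

# noiseless decay histogram built from the analytic reconvolved model,
# scaled to a given total photon count
noiseless_decay <- function(lifetimes, amplitudes, irf, total = 1e6,
                            window = 50, bin_width = 0.05) {
  g <- window_grid(window, bin_width)
  mu <- convolve_model_with_irf(lifetimes, amplitudes, irf, g)
  decay_histogram(mu * total / sum(mu), bin_width)
}

# random rigid-body transform applied to an n x 3 coordinate matrix
random_rigid <- function(pts, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- rnorm(3, sd = 10)
  sweep(pts %*% q, 2, shift, "+")
}

# single-pseudo-atom-per-residue frame from a coordinate matrix
frame_from_coords <- function(xyz, element = "C", atom_name = "CA") {
  n <- nrow(xyz)
  structure(list(coords = xyz,
                 atoms = data.frame(residue_index = seq_len(n),
                                    residue_name = "GLY",
                                    atom_name = atom_name,
                                    element = element)),
            class = "md_frame")
}
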