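#' Simulate polarized decay pairs with rotational depolarization
#'
#' Generates parallel and perpendicular TCSPC histograms for a fluorophore of
#' lifetime `lifetime` whose anisotropy decays as
#' \eqn{r(t) = r_0 \sum_i w_i e^{-t/\theta_i}}:
#' \eqn{I_\parallel(t) \propto I(t)[1 + 2r(t)]} and
#' \eqn{I_\perp(t) \propto I(t)[1 - r(t)]/G}. Photons are allocated to the
#' channel/bin grid multinomially, so the total photon count is exact. This is
#' the generative inverse of [anisotropy_decay()] + [fit_anisotropy_decay()].
#'
#' @param r0 Limiting anisotropy; must not exceed the 0.4 theoretical limit.
#' @param rotational_components Data frame with columns `theta` (rotational
#'   correlation times, ns; `Inf` allowed for a frozen rotor) and `weight`
#'   (summing to 1).
#' @param lifetime Fluorescence lifetime, ns.
#' @param g_factor Simulated detection G factor.
#' @param n_photons Total photons across both channels.
#' @param seed Integer seed.
#' @param bin_width,window Histogram grid, ns.
#' @return List with elements `parallel` and `perpendicular`
#'   ([decay_histogram()]s) and `truth` (the generating r(t) on the grid).
#' @export
simulate_anisotropy_decays <- function(r0, rotational_components, lifetime,
                                       g_factor = 1, n_photons = 1e6, seed = 1,
                                       bin_width = 0.05, window = 50) {
  if (r0 > 0.4) stop("r0 exceeds theoretical limit 0.4")
  stop_field(r0 > 0, "r0", "must be positive")
  stopifnot(is.data.frame(rotational_components),
            all(c("theta", "weight") %in% names(rotational_components)))
  w <- rotational_components$weight
  th <- rotational_components$theta
  if (abs(sum(w) - 1) > 1e-8) stop("rotational component weights must sum to 1")
  stop_field(all(th > 0), "theta", "must be positive (Inf allowed)")
  stop_field(lifetime > 0, "lifetime", "must be positive")
  if (g_factor <= 0) stop("G factor must be positive")

  n_bins <- ceiling(window / bin_width)
  tc <- (seq_len(n_bins) - 0.5) * bin_width
  rt <- r0 * colSums(w * exp(-outer(1 / th, tc)))
  It <- exp(-tc / lifetime)
  lam_par <- It * (1 + 2 * rt)
  lam_perp <- It * (1 - rt) / g_factor
  probs <- c(lam_par, lam_perp)
  probs <- probs / sum(probs)
  with_seed(seed, {
    draw <- stats::rmultinom(1, size = n_photons, prob = probs)[, 1]
    list(parallel = decay_histogram(draw[seq_len(n_bins)], bin_width,
                                    channel = "parallel"),
         perpendicular = decay_histogram(draw[n_bins + seq_len(n_bins)],
                                         bin_width, channel = "perpendicular"),
         truth = list(time = tc, r = rt, r0 = r0, theta = th, weight = w,
                      lifetime = lifetime, g_factor = g_factor))
  })
}
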