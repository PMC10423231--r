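#' Specification for a simulated TCSPC decay
#'
#' Defaults mirror a typical picosecond pulsed-laser TCSPC setup: 100 ps FWHM
#' Gaussian IRF and a 20 MHz repetition rate (50 ns window).
#'
#' @param component_lifetimes Component lifetimes, ns (> 0).
#' @param component_amplitudes Non-negative photon weights, one per component:
#'   the probability that a photon is emitted by each component (i.e. the
#'   intensity fractions \eqn{a_i\tau_i} of the underlying decay law).
#' @param irf_fwhm Gaussian IRF full width at half maximum, ns. 0 = delta IRF.
#' @param irf_t0 Pulse position in the window, ns; defaults to `5 * irf_fwhm`.
#' @param repetition_window Laser repetition window, ns; must exceed the
#'   largest lifetime. 50 ns corresponds to 20 MHz.
#' @param n_photons Number of decay photons to draw (>= 1).
#' @param bin_width Histogram bin width, ns.
#' @param background_rate Expected uniform background counts per bin
#'   (Poisson), added on top of the `n_photons` decay photons.
#' @param seed Integer seed; all randomness in the simulator flows from it.
#' @return An object of class `decay_sim_spec`.
#' @export
decay_sim_spec <- function(component_lifetimes, component_amplitudes,
                           irf_fwhm = 0.1, repetition_window = 50,
                           n_photons = 1e5, bin_width = 0.05,
                           background_rate = 0, seed = 1,
                           irf_t0 = 5 * irf_fwhm) {
  stop_field(all(component_lifetimes > 0), "component_lifetimes",
             "must be positive")
  stop_field(length(component_amplitudes) == length(component_lifetimes) &&
               all(component_amplitudes >= 0) && sum(component_amplitudes) > 0,
             "component_amplitudes", "must be non-negative with positive sum")
  stop_field(irf_fwhm >= 0, "irf_fwhm", "must be non-negative")
  stop_field(repetition_window > max(component_lifetimes),
             "repetition_window", "must exceed the largest lifetime")
  stop_field(n_photons >= 1, "n_photons", "must be at least 1")
  stop_field(bin_width > 0 && bin_width < repetition_window, "bin_width",
             "must be positive and smaller than the window")
  stop_field(background_rate >= 0, "background_rate", "must be non-negative")
  structure(list(component_lifetimes = component_lifetimes,
                 component_amplitudes = component_amplitudes,
                 irf_fwhm = irf_fwhm, irf_t0 = irf_t0,
                 repetition_window = repetition_window,
                 n_photons = as.integer(n_photons), bin_width = bin_width,
                 background_rate = background_rate, seed = seed),
            class = "decay_sim_spec")
}

#' Simulate a TCSPC decay histogram
#'
#' Photon-level generative model: each photon picks a decay component by its
#' photon weight, draws an exponential delay, adds Gaussian IRF jitter
#' (centered on the pulse position) and is wrapped modulo the repetition
#' window, then binned. Optional uniform Poisson background counts are added.
#' This is the generative inverse of [fit_convolved_biexponential()].
#'
#' @param spec A [decay_sim_spec()].
#' @return A [decay_histogram()] covering one repetition window. The ground
#'   truth spec is attached as attribute `"spec"`.
#' @examples
#' h <- simulate_tcspc_decay(decay_sim_spec(1.5, 1, n_photons = 1e4, seed = 7))
#' @export
simulate_tcspc_decay <- function(spec) {
  stopifnot(inherits(spec, "decay_sim_spec"))
  with_seed(spec$seed, {
    k <- length(spec$component_lifetimes)
    comp <- if (k == 1L) rep(1L, spec$n_photons)
            else sample.int(k, spec$n_photons, replace = TRUE,
                            prob = spec$component_amplitudes)
    t <- stats::rexp(spec$n_photons, rate = 1 / spec$component_lifetimes[comp])
    if (spec$irf_fwhm > 0)
      t <- t + stats::rnorm(spec$n_photons, mean = spec$irf_t0,
                            sd = fwhm_to_sd(spec$irf_fwhm))
    else
      t <- t + spec$irf_t0
    t <- t %% spec$repetition_window
    n_bins <- ceiling(spec$repetition_window / spec$bin_width)
    counts <- tabulate(pmin(floor(t / spec$bin_width) + 1L, n_bins), n_bins)
    if (spec$background_rate > 0)
      counts <- counts + stats::rpois(n_bins, spec$background_rate)
    h <- decay_histogram(counts, spec$bin_width)
    attr(h, "spec") <- spec
    h
  })
}
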