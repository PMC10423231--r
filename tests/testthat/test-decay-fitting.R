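test_that("delta-IRF convolution returns the pure wrapped multi-exponential", {
  g <- window_grid(50, 0.05)
  got <- convolve_model_with_irf(c(0.8, 2.5), c(2, 1), gaussian_irf(0), g)
  # bin-averaged wrapped exponentials, computed independently
  edges <- seq(0, 50, by = 0.05)
  pure <- function(tau) {
    (exp(-edges[-length(edges)] / tau) - exp(-edges[-1] / tau)) *
      tau / (1 - exp(-50 / tau)) / 0.05
  }
  expect_equal(got, 2 * pure(0.8) + 1 * pure(2.5), tolerance = 1e-12)
})

test_that("Gaussian-IRF reconvolution equals the numeric convolution integral", {
  # oracle: brute-force double integral of exp(-u/tau) x Gaussian over a bin
  tau <- 1.3; fwhm <- 0.1; t0 <- 0.5; bw <- 0.05
  sdv <- fwhm / (2 * sqrt(2 * log(2)))
  dens <- function(t) vapply(t, function(tt)
    stats::integrate(function(s) dnorm(s, t0, sdv) * dexp(tt - s, 1 / tau),
                     lower = t0 - 10 * sdv, upper = min(tt, t0 + 10 * sdv),
                     rel.tol = 1e-10)$value,
    numeric(1))
  g <- window_grid(50, bw)
  got <- convolve_model_with_irf(tau, 1, gaussian_irf(fwhm, t0), g,
                                 method = "analytic")
  check_bins <- c(8, 10, 11, 13, 20, 60, 200)   # through the rise and tail
  for (k in check_bins) {
    oracle <- stats::integrate(dens, g[k] - bw / 2, g[k] + bw / 2,
                               rel.tol = 1e-9)$value * tau / bw
    expect_equal(got[k], oracle, tolerance = 1e-7)
  }
})

test_that("discrete reconvolution converges to the analytic curve as bins shrink", {
  err_at <- function(bw) {
    g <- window_grid(25, bw)
    a <- convolve_model_with_irf(c(0.5, 2), c(1, 1), gaussian_irf(0.1), g,
                                 method = "analytic")
    b <- convolve_model_with_irf(c(0.5, 2), c(1, 1), gaussian_irf(0.1), g,
                                 method = "fft")
    max(abs(a - b)) / max(a)
  }
  e1 <- err_at(0.01); e2 <- err_at(0.005)
  expect_lt(e2, 0.05)
  expect_lt(e2, 0.7 * e1)   # first-order in bin width near the pulse
})

test_that("FFT convolution equals the direct O(n^2) sum to 1e-9", {
  g <- window_grid(512 * 0.05, 0.05)
  a <- convolve_model_with_irf(c(0.5, 2), c(1, 1), gaussian_irf(0.1), g,
                               method = "fft")
  b <- convolve_model_with_irf(c(0.5, 2), c(1, 1), gaussian_irf(0.1), g,
                               method = "direct")
  expect_lt(max(abs(a - b)) / max(abs(b)), 1e-9)
})

test_that("total curve area is sum(a_i tau_i)/bin_width for a full window", {
  g <- window_grid(50, 0.05)   # window = 20 x max lifetime
  cv <- convolve_model_with_irf(c(0.5, 2.5), c(3, 1), gaussian_irf(0), g)
  expect_lt(abs(sum(cv) - (3 * 0.5 + 1 * 2.5) / 0.05) /
              ((3 * 0.5 + 1 * 2.5) / 0.05), 1e-6)
})

test_that("mean lifetime weightings follow their definitions", {
  expect_equal(mean_lifetime(1.7, 5), 1.7)
  expect_equal(mean_lifetime(c(1, 3), c(1, 1)), 2.0)
  expect_equal(mean_lifetime(c(1, 3), c(1, 1), "intensity"), 2.5)
  expect_error(mean_lifetime(c(1, 3), c(0, 0)), "amplitudes")
  # intensity-weighted >= amplitude-weighted (Chebyshev sum inequality)
  set.seed(7)
  for (i in 1:1000) {
    tau <- runif(3, 0.1, 10)
    a <- runif(3)
    expect_gte(mean_lifetime(tau, a, "intensity") + 1e-12,
               mean_lifetime(tau, a, "amplitude"))
  }
})

test_that("noiseless bi-exponential decays are recovered to 4 significant digits", {
  irf <- std_irf()
  h <- noiseless_decay(c(0.5, 2.0), c(1, 1), irf)
  fit <- fit_convolved_biexponential(h, irf)
  expect_true(fit$converged)
  expect_equal(fit$lifetimes, c(0.5, 2.0), tolerance = 1e-4)
  expect_equal(fit$amplitudes, c(0.5, 0.5), tolerance = 1e-4)
})

test_that("reduced chi-square is calibrated on Poisson realizations", {
  irf <- std_irf()
  ch <- vapply(1:4, function(s) {
    spec <- decay_sim_spec(c(0.5, 2), c(0.2, 0.8), n_photons = 1e6,
                           bin_width = 0.025, repetition_window = 12.5,
                           seed = s)
    fit_convolved_biexponential(simulate_tcspc_decay(spec), irf)$reduced_chi2
  }, numeric(1))
  expect_gt(mean(ch), 0.9)
  expect_lt(mean(ch), 1.1)
})

test_that("an mCherry-like decay fits back into the standard 1.4-1.6 ns range", {
  # amplitude-weighted mean 1.47 ns from two components
  irf <- std_irf()
  alpha <- c((1.7 - 1.47) / (1.7 - 0.8), 1 - (1.7 - 1.47) / (1.7 - 0.8))
  wts <- alpha * c(0.8, 1.7); wts <- wts / sum(wts)   # photon weights
  spec <- decay_sim_spec(c(0.8, 1.7), wts, n_photons = 1e6, seed = 5)
  fit <- fit_convolved_biexponential(simulate_tcspc_decay(spec), irf)
  expect_gt(fit$mean_lifetime, 1.4)
  expect_lt(fit$mean_lifetime, 1.6)
  expect_equal(fit$mean_lifetime, 1.47, tolerance = 0.02)
})

test_that("components are sorted ascending and refitting is idempotent", {
  irf <- std_irf()
  h <- noiseless_decay(c(0.5, 2.0), c(1, 1), irf, total = 1e6)
  fit <- fit_convolved_decay(h, irf, n_components = 2,
                             init = list(lifetimes = c(3, 0.4),
                                         photons = c(2e5, 8e5)))
  expect_true(all(diff(fit$lifetimes) > 0))
  refit <- fit_convolved_decay(h, irf, n_components = 2,
                               init = list(lifetimes = fit$lifetimes,
                                           photons = fit$photons_per_component))
  expect_lt(abs(refit$mean_lifetime - fit$mean_lifetime), 1e-6)
})

test_that("mean-lifetime bias stays below 1% at 1e5 photons across lifetimes", {
  irf <- std_irf()
  for (tau in c(0.5, 2, 4)) {
    est <- vapply(1:6, function(s) {
      h <- simulate_tcspc_decay(decay_sim_spec(tau, 1, n_photons = 1e5,
                                               seed = 400 + s))
      fit_convolved_decay(h, irf, n_components = 1)$mean_lifetime
    }, numeric(1))
    expect_lt(abs(mean(est) - tau) / tau, 0.01)
  }
})

test_that("tail fit gates on photon count and is exact on noiseless decays", {
  # 99 photons with the in-cell gate of 100 -> sentinel
  h99 <- decay_histogram(c(0, 30, 20, 14, 10, 8, 6, 5, 4, 2), 0.1)
  expect_true(is.na(tail_fit_monoexponential(h99, min_photons = 100)))
  expect_match(attr(tail_fit_monoexponential(h99, min_photons = 100), "reason"),
               "gate")
  # the same histogram passes the in vitro gate of 30
  expect_false(is.na(tail_fit_monoexponential(h99, min_photons = 30)))
  # fewer than 3 nonzero tail bins -> sentinel with reason
  h2 <- decay_histogram(c(0, 500, 200, 100, 0, 0), 0.1)
  s2 <- tail_fit_monoexponential(h2, min_photons = 30, tail_start_offset = 0.2)
  expect_true(is.na(s2))
  expect_match(attr(s2, "reason"), "tail bins")
  # noiseless 1.44 ns decay recovered exactly (solver tolerance)
  hN <- noiseless_decay(1.44, 1, gaussian_irf(0), total = 1e6)
  expect_equal(as.numeric(tail_fit_monoexponential(hN)), 1.44,
               tolerance = 1e-4)
})
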