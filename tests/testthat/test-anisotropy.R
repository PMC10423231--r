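test_that("photoselection gives the 0.4 theoretical cap for collinear dipoles", {
  expect_identical(limiting_anisotropy(0), 0.4)
  expect_equal(limiting_anisotropy(90), -0.2)
  expect_error(simulate_anisotropy_decays(0.45, data.frame(theta = 10, weight = 1),
                                          1.5), "theoretical limit")
})

test_that("channel shift is recovered at whole-bin and sub-bin offsets", {
  h <- noiseless_decay(2, 1, gaussian_irf(0.2, t0 = 2), total = 1e7,
                       window = 25, bin_width = 0.05)
  expect_equal(estimate_channel_shift(h, h), 0)
  shifted <- decay_histogram(c(rep(0, 3), h$counts[1:(length(h$counts) - 3)]),
                             0.05)
  expect_equal(estimate_channel_shift(h, shifted), 3 * 0.05, tolerance = 1e-9)
  # sub-bin: regenerate the smooth curve with t0 offset by 0.4 bins
  sub <- noiseless_decay(2, 1, gaussian_irf(0.2, t0 = 2 + 0.4 * 0.05),
                         total = 1e7, window = 25, bin_width = 0.05)
  expect_lt(abs(estimate_channel_shift(h, sub) - 0.4 * 0.05), 0.1 * 0.05)
  expect_error(estimate_channel_shift(h, decay_histogram(rep(0, 10), 0.05)),
               "empty")
})

test_that("anisotropy decay formula obeys its algebraic limits", {
  I <- decay_histogram(rep(1000, 100), 0.1)
  rd0 <- anisotropy_decay(I, I, G = 1)
  expect_true(all(rd0$r[rd0$valid] == 0))
  # I_perp = 0 -> formula limit r = 1, unphysical (> 0.4 cap) but well defined
  zero <- decay_histogram(rep(0, 100), 0.1)
  rd1 <- anisotropy_decay(I, zero, G = 1)
  expect_true(all(rd1$r == 1))
  expect_error(anisotropy_decay(I, I, G = 0), "G factor")
  # G-invariance: scaling perpendicular counts by c and G by 1/c is exact
  set.seed(5)
  perp <- decay_histogram(rpois(100, 600), 0.1)
  r_a <- anisotropy_decay(I, perp, G = 1.3)
  perp4 <- decay_histogram(perp$counts * 4, 0.1)
  r_b <- anisotropy_decay(I, perp4, G = 1.3 / 4)
  expect_equal(r_a$r, r_b$r, tolerance = 1e-12)
})

test_that("simulated depolarization round-trips through the anisotropy pipeline", {
  sim <- simulate_anisotropy_decays(0.38, data.frame(theta = 10, weight = 1),
                                    lifetime = 1.5, n_photons = 1e7, seed = 8)
  rd <- anisotropy_decay(sim$parallel, sim$perpendicular, G = 1)
  # r(0) ~ 0.38 and monotone decay over the 10 ns analysis window
  early <- rd$valid & rd$time < 0.3
  expect_equal(mean(rd$r[early]), 0.38, tolerance = 0.02)
  fit <- fit_anisotropy_decay(rd, n_components = 1)
  expect_equal(fit$r0, 0.38, tolerance = 0.02)
  expect_lt(abs(fit$components$theta - 10) / 10, 0.1)
  # theta -> Inf limit: the generating r(t) is constant at r0
  frozen <- simulate_anisotropy_decays(0.3, data.frame(theta = Inf, weight = 1),
                                       lifetime = 1.5, n_photons = 1e4, seed = 1)
  expect_true(all(frozen$truth$r == 0.3))
})

test_that("a flat anisotropy decay reports an infinite rotational time", {
  I <- round(1e5 * exp(-(1:200) * 0.05 / 1.5))
  par <- decay_histogram(round(I * (1 + 2 * 0.3)), 0.05)
  perp <- decay_histogram(round(I * (1 - 0.3)), 0.05)
  rd <- anisotropy_decay(par, perp, G = 1)
  fit <- fit_anisotropy_decay(rd)
  expect_equal(fit$n_components, 1L)
  expect_identical(fit$components$theta, Inf)
  expect_equal(fit$r0, 0.3, tolerance = 0.01)
})

test_that("a fast rotational mode is detected only when present", {
  slow <- simulate_anisotropy_decays(0.38, data.frame(theta = 20, weight = 1),
                                     lifetime = 1.5, n_photons = 1e7, seed = 12)
  both <- simulate_anisotropy_decays(0.38,
                                     data.frame(theta = c(20, 1),
                                                weight = c(0.7, 0.3)),
                                     lifetime = 1.5, n_photons = 1e7, seed = 12)
  f_slow <- fit_anisotropy_decay(anisotropy_decay(slow$parallel,
                                                  slow$perpendicular))
  f_both <- fit_anisotropy_decay(anisotropy_decay(both$parallel,
                                                  both$perpendicular))
  expect_equal(f_slow$n_components, 1L)
  expect_equal(f_both$n_components, 2L)
  expect_lt(min(f_both$components$theta), 3)
})

test_that("Perrin relation matches its closed form and limits", {
  expect_equal(perrin_anisotropy(0.35, 1e-9, 10), 0.35, tolerance = 1e-9)
  expect_equal(perrin_anisotropy(0.4, 12, 12), 0.2)
  expect_equal(perrin_anisotropy(0.4, 1.5, 15), 0.3636364, tolerance = 1e-7)
  expect_error(perrin_anisotropy(0.5, 1.5, 15), "r0")
})

test_that("anisotropy images threshold both channels and cap at 0.4", {
  par <- matrix(100, 4, 4); perp <- matrix(100, 4, 4)
  img <- steady_state_anisotropy_image(par, perp, G = 1)
  expect_true(all(img == 0))
  # pixel passing only one channel threshold is masked
  perp2 <- perp; perp2[2, 2] <- 5
  img2 <- steady_state_anisotropy_image(par, perp2, G = 1,
                                        intensity_thresholds = c(50, 50))
  expect_true(is.na(img2[2, 2]))
  expect_true(all(!is.na(img2[-6])))
  # a constructed pixel with r = 0.45 is filtered out
  par3 <- matrix(100, 2, 2); perp3 <- matrix(100, 2, 2)
  perp3[1, 1] <- 100 * (1 - 0.45) / (1 + 2 * 0.45)   # makes r exactly 0.45
  img3 <- steady_state_anisotropy_image(par3, perp3, G = 1)
  expect_true(is.na(img3[1, 1]))
  expect_error(steady_state_anisotropy_image(matrix(0, 2, 2), matrix(0, 3, 3)),
               "shape")
})

test_that("raising either intensity threshold never unmasks a pixel", {
  set.seed(14)
  par <- matrix(rpois(400, 80), 20, 20)
  perp <- matrix(rpois(400, 60), 20, 20)
  base <- is.na(steady_state_anisotropy_image(par, perp, G = 1,
                                              intensity_thresholds = c(60, 40)))
  for (thr in list(c(80, 40), c(60, 60), c(90, 70))) {
    up <- is.na(steady_state_anisotropy_image(par, perp, G = 1,
                                              intensity_thresholds = thr))
    expect_true(all(up[base]))   # masked stays masked
  }
})
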