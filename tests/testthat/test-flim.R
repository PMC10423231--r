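test_that("FLIM scenes conserve photons and empty budgets give empty streams", {
  spec <- flim_scene_spec(c(16, 16),
                          list(list(center = c(8, 8), radius = 5,
                                    lifetime = 1.2)),
                          photon_budget = 200, seed = 3)
  sc <- simulate_flim_scene(spec)
  expect_equal(nrow(sc$stream), sum(sc$counts))
  empty <- simulate_flim_scene(flim_scene_spec(c(8, 8), photon_budget = 0))
  expect_equal(nrow(empty$stream), 0)
  img <- build_lifetime_image(empty$stream, c(8, 8))
  expect_true(all(img$lifetime == 0))
  # determinism
  sc2 <- simulate_flim_scene(spec)
  expect_identical(sc$stream, sc2$stream)
  # overlap: later condensate wins
  ov <- flim_scene_spec(c(16, 16),
                        list(list(center = c(8, 8), radius = 5, lifetime = 1.2),
                             list(center = c(8, 8), radius = 3, lifetime = 0.9)),
                        photon_budget = 0)
  tr <- simulate_flim_scene(ov)$truth
  expect_equal(tr[8, 8], 0.9)
  expect_equal(tr[8, 12], 1.2)
})

test_that("the photon gate leaves sub-threshold pixels at the 0 sentinel", {
  set.seed(2)
  stream <- data.frame(frame = 1L, x = 0L, y = 0L, channel = 0L,
                       microtime_ns = rexp(99, 1 / 1.5))
  img <- build_lifetime_image(stream, c(2, 2), min_photons = 100)
  expect_equal(img$lifetime[1, 1], 0)
  expect_equal(img$counts[1, 1], 99L)
  img30 <- build_lifetime_image(stream, c(2, 2), min_photons = 30)
  expect_gt(img30$lifetime[1, 1], 0)
  expect_error(build_lifetime_image(data.frame(frame = 1, x = 5, y = 0,
                                               channel = 0, microtime_ns = 1),
                                    c(2, 2)), "outside")
})

test_that("a uniform scene is recovered pixel-wise within shot noise", {
  spec <- flim_scene_spec(c(14, 14), background_lifetime = 1.5,
                          photon_budget = 1000, seed = 6)
  sc <- simulate_flim_scene(spec)
  img <- build_lifetime_image(sc$stream, c(14, 14), min_photons = 100)
  v <- img$lifetime[img$lifetime > 0]
  expect_gt(length(v), 190)
  expect_equal(mean(v), 1.5, tolerance = 0.02)
  expect_lt(sd(v), 0.1)
})

test_that("condensate statistics respect the sentinel and the crowding boundary", {
  lt <- matrix(0, 10, 10)
  mask <- matrix(0L, 10, 10)
  lt[2:5, 2:5] <- 1.2;  mask[2:5, 2:5] <- 1L
  lt[7:9, 7:9] <- 1.5;  mask[7:9, 7:9] <- 2L
  mask[1, 1] <- 3L    # ROI entirely at the sentinel
  st <- condensate_statistics(lt, mask, boundary = 1.44)
  expect_equal(st$mean_lifetime[1], 1.2)
  expect_equal(st$sd_lifetime[1], 0)
  expect_equal(st$fraction_below[1], 1)
  expect_equal(st$class[1], "above_30pct_FVO")
  expect_equal(st$class[2], "below_30pct_FVO")
  expect_true(st$empty[3])
  # adding sentinel pixels to an ROI never changes its statistics
  mask2 <- mask; mask2[1, ] <- 1L   # extend ROI 1 over sentinel pixels
  st2 <- condensate_statistics(lt, mask2, boundary = 1.44)
  expect_equal(st2$mean_lifetime[1], st$mean_lifetime[1])
  expect_equal(st2$sd_lifetime[1], st$sd_lifetime[1])
  expect_equal(st2$n_pixels[1], st$n_pixels[1])
})

test_that("fraction-below-boundary extremes force the matching class", {
  set.seed(10)
  for (i in 1:25) {
    lo <- matrix(runif(64, 0.8, 1.43), 8, 8)   # all below the boundary
    hi <- matrix(runif(64, 1.45, 2.0), 8, 8)   # all above
    lo[sample(64, 10)] <- 0
    hi[sample(64, 10)] <- 0
    mask <- matrix(1L, 8, 8)
    st_lo <- condensate_statistics(lo, mask, boundary = 1.44)
    expect_equal(st_lo$fraction_below[1], 1)
    expect_equal(st_lo$class[1], "above_30pct_FVO")
    st_hi <- condensate_statistics(hi, mask, boundary = 1.44)
    expect_equal(st_hi$fraction_below[1], 0)
    expect_equal(st_hi$class[1], "below_30pct_FVO")
  }
})

test_that("pixel lifetime histograms count gated pixels and resolve subdomains", {
  lt <- matrix(0, 6, 6); lt[2:5, 2:5] <- 1.3
  h <- pixel_lifetime_histogram(lt, bin_width = 0.02)
  expect_equal(sum(h$counts), 16)
  expect_equal(sum(h$counts > 0), 1)
  # two-subdomain condensate: bimodal pixel histogram
  spec <- flim_scene_spec(c(21, 21),
                          list(list(center = c(11, 11), radius = 9,
                                    lifetime = list(values = c(1.1, 1.5),
                                                    fraction = 0.5))),
                          photon_budget = 800, seed = 4)
  sc <- simulate_flim_scene(spec)
  img <- build_lifetime_image(sc$stream, c(21, 21), min_photons = 100)
  hh <- pixel_lifetime_histogram(img, mask = sc$labels, bin_width = 0.05)
  expect_equal(sum(hh$counts), sum(img$lifetime > 0 & sc$labels > 0))
  # smooth lightly, then count local maxima
  y <- stats::filter(hh$counts, rep(1 / 3, 3))
  y[is.na(y)] <- 0
  peaks <- sum(diff(sign(diff(y))) == -2)
  expect_gte(peaks, 2)
})

test_that("population comparisons report calibrated p-values and stars", {
  a <- c(1.40, 1.45, 1.50, 1.42)
  cmp <- compare_populations(a, a)
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$t_p, 1)
  expect_equal(cmp$f_p, 1)
  expect_equal(cmp$t_stars, "n.s.")
  expect_equal(p_stars(0.005), "**")
  expect_equal(p_stars(0.2), "n.s.")
  expect_equal(p_stars(0.03), "*")
  expect_equal(p_stars(1e-5), "***")
  expect_error(compare_populations(1, c(1, 2)), "at least 2")
  # power: N(1.40, 0.05^2) vs N(1.50, 0.02^2), n = 30: both tests reject
  set.seed(77)
  hits_t <- 0; hits_f <- 0; n_rep <- 200
  for (i in seq_len(n_rep)) {
    cmp <- compare_populations(rnorm(30, 1.40, 0.05), rnorm(30, 1.50, 0.02))
    hits_t <- hits_t + (cmp$t_p < 0.05)
    hits_f <- hits_f + (cmp$f_p < 0.05)
  }
  expect_gt(hits_t / n_rep, 0.95)
  expect_gt(hits_f / n_rep, 0.95)
})

test_that("lifetime-intensity correlation hits its algebraic anchors", {
  img <- structure(list(lifetime = matrix(1:16 / 10, 4, 4),
                        counts = matrix(101:116, 4, 4), min_photons = 0),
                   class = "lifetime_image")
  expect_equal(lifetime_intensity_correlation(img), 1)
  img$counts <- matrix(116:101, 4, 4)
  expect_equal(lifetime_intensity_correlation(img), -1)
  # independent maps: |r| small at 1e4 pixels
  set.seed(8)
  img2 <- structure(list(lifetime = matrix(runif(1e4, 1, 2), 100, 100),
                         counts = matrix(rpois(1e4, 200), 100, 100),
                         min_photons = 0), class = "lifetime_image")
  expect_lt(abs(lifetime_intensity_correlation(img2)), 0.1)
  # constant input -> sentinel
  img3 <- structure(list(lifetime = matrix(1.5, 3, 3),
                         counts = matrix(100, 3, 3), min_photons = 0),
                    class = "lifetime_image")
  expect_true(is.na(lifetime_intensity_correlation(img3)))
})
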