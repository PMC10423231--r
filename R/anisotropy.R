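# Time-resolved and steady-state fluorescence anisotropy.

#' Limiting anisotropy from photoselection
#'
#' For one-photon excitation the fundamental anisotropy of a fluorophore whose
#' absorption and emission dipoles subtend an angle `beta` is
#' \eqn{r_0 = (3\cos^2\beta - 1)/5}; collinear dipoles (`beta = 0`) give the
#' theoretical maximum 0.4.
#'
#' @param beta_deg Angle between absorption and emission dipoles, degrees.
#' @return The limiting anisotropy.
#' @examples
#' limiting_anisotropy(0)    # 0.4
#' limiting_anisotropy(90)   # -0.2
#' @export
limiting_anisotropy <- function(beta_deg = 0) {
  (3 * cos(beta_deg * pi / 180)^2 - 1) / 5
}

#' Channel time shift between polarized detectors
#'
#' Estimates the arrival-time offset between the parallel and perpendicular
#' detection channels (different light path lengths) as the lag maximizing the
#' cross-correlation of the two histograms around their rising edges, refined
#' to sub-bin precision by parabolic interpolation.
#'
#' @param par,perp [decay_histogram()] objects on the same bin width.
#' @param max_shift_bins Search half-width in bins.
#' @return Shift in ns (positive = `perp` arrives later than `par`).
#' @export
estimate_channel_shift <- function(par, perp, max_shift_bins = 50L) {
  stopifnot(inherits(par, "decay_histogram"), inherits(perp, "decay_histogram"))
  if (abs(par$bin_width - perp$bin_width) > 1e-12)
    stop("histograms must share a bin width")
  if (par$total_photons == 0 || perp$total_photons == 0)
    stop("empty histogram")
  a <- par$counts / sum(par$counts)
  b <- perp$counts / sum(perp$counts)
  n <- min(length(a), length(b))
  a <- a[seq_len(n)]; b <- b[seq_len(n)]
  lags <- -max_shift_bins:max_shift_bins
  cc <- vapply(lags, function(L) {
    ia <- seq_len(n)
    ib <- ia + L
    ok <- ib >= 1 & ib <= n
    sum(a[ia[ok]] * b[ib[ok]])
  }, numeric(1))
  i <- which.max(cc)
  shift <- lags[i]
  # parabolic sub-bin refinement on the correlation peak
  if (i > 1 && i < length(lags)) {
    y1 <- cc[i - 1]; y2 <- cc[i]; y3 <- cc[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) shift <- shift + 0.5 * (y1 - y3) / den
  }
  shift * par$bin_width
}

#' Build a fluorescence anisotropy decay from polarized decay pairs
#'
#' \eqn{r(t) = (I_\parallel - G I_\perp) / (I_\parallel + 2 G I_\perp)} per
#' bin, after correcting the perpendicular decay with the G factor and
#' aligning the channels by `shift` (rounded to whole bins). Bins whose total
#' (denominator) counts fall below `min_denominator` are masked: at low counts
#' the anisotropy estimate is dominated by shot noise.
#'
#' @param par,perp Parallel and perpendicular [decay_histogram()]s.
#' @param G Detection-efficiency G factor (> 0); for simulated data 1.
#' @param shift Channel shift in ns (`perp` shifted by `-shift`), or `"auto"`
#'   to call [estimate_channel_shift()].
#' @param min_denominator Mask floor in counts per bin (default 25 keeps the
#'   relative error of r below roughly 20%).
#' @return An `anisotropy_decay` object: `time` (ns), `r`, `valid` mask,
#'   `g_factor`, `channel_shift`, `denominator` counts.
#' @export
anisotropy_decay <- function(par, perp, G = 1, shift = 0,
                             min_denominator = 25) {
  stopifnot(inherits(par, "decay_histogram"), inherits(perp, "decay_histogram"))
  if (G <= 0) stop("G factor must be positive")
  if (identical(shift, "auto")) shift <- estimate_channel_shift(par, perp)
  nb <- round(shift / par$bin_width)
  ip <- par$counts
  iq <- perp$counts
  if (nb > 0) iq <- c(iq[-seq_len(nb)], rep(0, nb))
  if (nb < 0) iq <- c(rep(0, -nb), iq[seq_len(length(iq) + nb)])
  n <- min(length(ip), length(iq))
  ip <- ip[seq_len(n)]; iq <- iq[seq_len(n)]
  den <- ip + 2 * G * iq
  r <- ifelse(den > 0, (ip - G * iq) / den, NA_real_)
  valid <- is.finite(r) & den >= min_denominator
  structure(list(time = bin_centers(par)[seq_len(n)], r = r, valid = valid,
                 g_factor = G, channel_shift = nb * par$bin_width,
                 denominator = den),
            class = "anisotropy_decay")
}

#' @export
print.anisotropy_decay <- function(x, ...) {
  cat(sprintf("anisotropy decay: %d bins, %d valid (G = %.3f, shift = %.4g ns)\n",
              length(x$r), sum(x$valid), x$g_factor, x$channel_shift))
  invisible(x)
}

#' Fit rotational components to an anisotropy decay
#'
#' Fits \eqn{r(t) = r_0 \sum_i w_i e^{-t/\theta_i}} with \eqn{\sum w_i = 1}
#' over the valid window, weighted by the per-bin denominator counts. With
#' `n_components = "auto"`, the two-component model is selected only when it
#' improves the reduced chi-square by more than `improvement` (default 20%);
#' a fast rotational mode on top of overall tumbling is the signature of
#' enhanced fluorophore mobility. A flat decay returns `theta = Inf`.
#'
#' @param rd An [anisotropy_decay()].
#' @param n_components 1, 2, or `"auto"`.
#' @param window Fit window after the first valid bin, ns (default 10 ns, the
#'   longest window that still shows the decay trend at practical noise).
#' @param improvement Required fractional chi-square improvement for the
#'   two-component model under `"auto"`.
#' @return A list: `r0`, data frame `components` (`theta`, `weight`),
#'   `reduced_chi2`, `n_components`.
#' @export
fit_anisotropy_decay <- function(rd, n_components = "auto", window = 10,
                                 improvement = 0.2) {
  stopifnot(inherits(rd, "anisotropy_decay"))
  sel <- rd$valid
  if (sum(sel) < 10) stop("need at least 10 valid bins")
  t0 <- min(rd$time[sel])
  sel <- sel & rd$time <= t0 + window
  t <- rd$time[sel] - t0
  r <- rd$r[sel]
  w <- rd$denominator[sel]
  w <- w / mean(w)

  chi2red <- function(pred, npar) sum(w * (r - pred)^2) / (length(r) - npar)

  # flat-decay degenerate case: no resolvable slope over the window
  slope_p <- tryCatch(
    summary(stats::lm(r ~ t, weights = w))$coefficients[2, 4],
    error = function(e) 1)
  if (stats::sd(r) < 1e-12 || slope_p > 0.5) {
    r0 <- stats::weighted.mean(r, w)
    return(list(r0 = r0,
                components = data.frame(theta = Inf, weight = 1),
                reduced_chi2 = chi2red(rep(r0, length(r)), 1),
                n_components = 1L))
  }

  fit_k <- function(k) {
    if (k == 1) {
      obj <- function(p) {
        pred <- p[1] * exp(-t / exp(p[2]))
        sum(w * (r - pred)^2)
      }
      starts <- list(c(max(r), log(max(t))), c(max(r), log(max(t) / 4)))
      best <- NULL
      for (s in starts) {
        o <- stats::optim(s, obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12))
        if (is.null(best) || o$value < best$value) best <- o
      }
      p <- best$par
      list(r0 = p[1], theta = exp(p[2]), weight = 1,
           chi2 = chi2red(p[1] * exp(-t / exp(p[2])), 2))
    } else {
      obj <- function(p) {
        wf <- stats::plogis(p[4])
        pred <- p[1] * ((1 - wf) * exp(-t / exp(p[2])) + wf * exp(-t / exp(p[3])))
        sum(w * (r - pred)^2)
      }
      s0 <- c(max(r), log(max(t)), log(max(t) / 20), 0)
      o <- stats::optim(s0, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
      p <- o$par
      wf <- stats::plogis(p[4])
      th <- exp(p[2:3]); wt <- c(1 - wf, wf)
      ord <- order(th)
      pred <- p[1] * (wt[1] * exp(-t / th[1]) + wt[2] * exp(-t / th[2]))
      list(r0 = p[1], theta = th[ord], weight = wt[ord],
           chi2 = chi2red(pred, 4))
    }
  }

  if (identical(n_components, "auto")) {
    f1 <- fit_k(1); f2 <- fit_k(2)
    use2 <- f2$chi2 < (1 - improvement) * f1$chi2
    f <- if (use2) f2 else f1
    k <- if (use2) 2L else 1L
  } else {
    k <- as.integer(n_components)
    stopifnot(k %in% 1:2)
    f <- fit_k(k)
  }
  list(r0 = f$r0, components = data.frame(theta = f$theta, weight = f$weight),
       reduced_chi2 = f$chi2, n_components = k)
}

#' Perrin relation for steady-state anisotropy
#'
#' \eqn{r = r_0 / (1 + \tau/\theta)}: for a single rotational mode, shorter
#' fluorescence lifetimes raise the steady-state anisotropy (less rotation
#' within the emission window).
#'
#' @param r0 Limiting anisotropy (0 < r0 <= 0.4).
#' @param tau Fluorescence lifetime, ns (> 0).
#' @param theta Rotational correlation time, ns (> 0).
#' @return Steady-state anisotropy.
#' @examples
#' perrin_anisotropy(0.4, 1.5, 15)
#' @export
perrin_anisotropy <- function(r0, tau, theta) {
  stop_field(r0 > 0 && r0 <= 0.4, "r0",
             "must be in (0, 0.4]; 0.4 is the theoretical limit")
  stop_field(tau >= 0, "tau", "must be non-negative")
  stop_field(theta > 0, "theta", "must be positive")
  r0 / (1 + tau / theta)
}

#' Steady-state anisotropy image from polarized intensity images
#'
#' Per-pixel \eqn{r = (I_\parallel - G I_\perp)/(I_\parallel + 2 G I_\perp)},
#' computed only on pixels passing the intensity threshold in *both*
#' channels (so condensate edges match across channels), and with any value
#' above the 0.4 theoretical cap masked out (edge pixels visible in one
#' channel only produce unphysical values). Masked pixels are `NA`.
#'
#' @param par_image,perp_image Numeric matrices (same shape) of polarized
#'   intensities.
#' @param G G factor (> 0).
#' @param intensity_thresholds Length-2 vector `c(parallel, perpendicular)`;
#'   a pixel must reach both.
#' @param cap Anisotropy cap; values strictly above it are masked.
#' @return Matrix of anisotropy values with `NA` sentinels.
#' @export
steady_state_anisotropy_image <- function(par_image, perp_image, G = 1,
                                          intensity_thresholds = c(0, 0),
                                          cap = 0.4) {
  if (!all(dim(par_image) == dim(perp_image)))
    stop("parallel and perpendicular images must have the same shape")
  if (G <= 0) stop("G factor must be positive")
  pass <- par_image >= intensity_thresholds[1] &
          perp_image >= intensity_thresholds[2]
  den <- par_image + 2 * G * perp_image
  r <- (par_image - G * perp_image) / den
  r[!pass | !is.finite(r) | den <= 0] <- NA_real_
  r[!is.na(r) & r > cap] <- NA_real_
  r
}
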