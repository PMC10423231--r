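# Fluorescence correlation spectroscopy: correlators and model fits.

# symmetric-normalization direct estimator at integer lag k
direct_g_at <- function(f, k) {
  n <- length(f)
  if (k >= n) return(NA_real_)
  a <- f[seq_len(n - k)]
  b <- f[(k + 1):n]
  mean(a * b) / (mean(a) * mean(b)) - 1
}

#' Intensity autocorrelation of a fluorescence trajectory
#'
#' \eqn{G(\tau) = \langle\delta F(t)\,\delta F(t+\tau)\rangle / \langle F\rangle^2}
#' with symmetric normalization (the means of the leading and trailing
#' segments are used), which makes the estimator exactly invariant to scaling
#' the counts. The `"multitau"` scheme computes 16 lags per octave with
#' pairwise rebinning of the signal between octaves, the standard
#' quasi-logarithmic correlator; at rebinned octaves the estimate is a
#' triangular-weighted average of nearby lags. The `"direct"` scheme evaluates
#' the estimator at arbitrary lags on the raw signal (O(N) per lag) and serves
#' as the oracle for the multitau scheme.
#'
#' @param traj An [intensity_trajectory()] with at least 1000 bins.
#' @param scheme `"multitau"` or `"direct"`.
#' @param lags Integer lags (in bins) for the direct scheme; default a
#'   quasi-logarithmic grid.
#' @param m Lags per octave for the multitau scheme.
#' @param max_lag_fraction Largest lag as a fraction of the trace length.
#' @return A `correlation_curve` object: `lag_s`, `G`, `lag_bins`,
#'   `raw_resolution` (TRUE where no rebinning was applied), `bin_time`,
#'   `scheme`, and `fit` (NULL until fitted).
#' @export
autocorrelate <- function(traj, scheme = c("multitau", "direct"), lags = NULL,
                          m = 16L, max_lag_fraction = 1 / 8) {
  stopifnot(inherits(traj, "intensity_trajectory"))
  scheme <- match.arg(scheme)
  f <- traj$counts
  n <- length(f)
  if (n < 1e3) stop("autocorrelation requires at least 1000 bins")
  if (mean(f) == 0) stop("zero-mean trajectory: autocorrelation undefined")
  max_lag <- floor(n * max_lag_fraction)

  if (scheme == "direct") {
    if (is.null(lags)) {
      lags <- unique(round(exp(seq(log(1), log(max_lag), length.out = 64))))
    }
    lags <- sort(unique(as.integer(lags)))
    lags <- lags[lags >= 1 & lags <= max_lag]
    G <- vapply(lags, function(k) direct_g_at(f, k), numeric(1))
    out <- list(lag_s = lags * traj$bin_time, G = G, lag_bins = lags,
                raw_resolution = rep(TRUE, length(lags)),
                bin_time = traj$bin_time, scheme = scheme, fit = NULL)
    return(structure(out, class = "correlation_curve"))
  }

  # multitau
  lag_bins <- numeric(0); G <- numeric(0); raw <- logical(0)
  sig <- f
  level <- 0L
  repeat {
    unit <- 2^level
    kk <- if (level == 0L) seq_len(m) else (m %/% 2 + 1L):m
    for (k in kk) {
      actual <- k * unit
      if (actual > max_lag || k >= length(sig)) next
      lag_bins <- c(lag_bins, actual)
      G <- c(G, direct_g_at(sig, k))
      raw <- c(raw, level == 0L)
    }
    if (length(sig) %/% 2 < 2L * m || (m * 2^(level + 1L)) > max_lag) break
    ns <- length(sig) %/% 2L
    sig <- (sig[2 * seq_len(ns) - 1L] + sig[2 * seq_len(ns)]) / 2
    level <- level + 1L
  }
  structure(list(lag_s = lag_bins * traj$bin_time, G = G, lag_bins = lag_bins,
                 raw_resolution = raw, bin_time = traj$bin_time,
                 scheme = scheme, fit = NULL),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("correlation curve (%s): %d lags, %.3g - %.3g s\n",
              x$scheme, length(x$lag_s), min(x$lag_s), max(x$lag_s)))
  if (!is.null(x$fit)) {
    ft <- x$fit
    cat(sprintf("  fit: N = %.3g, chi2red = %.3g%s\n", ft$N, ft$reduced_chi2,
                if (ft$converged) "" else " (FLAGGED: not converged)"))
    for (i in seq_len(nrow(ft$components)))
      cat(sprintf("   tau_D%d = %.4g s (fraction %.3f)%s\n", i,
                  ft$components$tau_D[i], ft$components$fraction[i],
                  if (ft$components$nonphysical[i]) " [non-physical: < 10 bins]" else ""))
    cat(sprintf("  reported slow tau_D = %.4g s\n", ft$slow_tau_D))
  }
  invisible(x)
}

#' Two-component 3D diffusion model for FCS
#'
#' \eqn{G(\tau) = \frac{1}{N}\sum_i f_i (1+\tau/\tau_{D,i})^{-1}
#' (1+\tau/(s^2\tau_{D,i}))^{-1/2}} with \eqn{\sum f_i = 1};
#' \eqn{G(0^+) = 1/N}.
#'
#' @param tau Lag times, s.
#' @param N Mean focal occupancy.
#' @param tau_D Diffusion times per species, s.
#' @param fractions Species fractions (same length, summing to 1).
#' @param s Structure parameter \eqn{w_z/w_{xy}}.
#' @return Model G values.
#' @export
fcs_diffusion_model <- function(tau, N, tau_D, fractions, s = 5) {
  stopifnot(length(tau_D) == length(fractions))
  g <- 0
  for (i in seq_along(tau_D))
    g <- g + fractions[i] / ((1 + tau / tau_D[i]) *
                               sqrt(1 + tau / (s^2 * tau_D[i])))
  g / N
}

#' Fit the two-component 3D diffusion model to a correlation curve
#'
#' Least-squares fit of [fcs_diffusion_model()] with components sorted by
#' diffusion time. The slow component is the reported diffusion time (fast
#' components in cells often take non-physical values); components faster
#' than 10 counting bins are flagged non-physical. For a single-species
#' curve the fractions collapse onto one component.
#'
#' @param curve A [autocorrelate()] result.
#' @param n_components 1 or 2.
#' @param structure Structure parameter (fixed unless `fit_structure`).
#' @param fit_structure Also fit the structure parameter.
#' @param fit_offset Fit a constant baseline \eqn{G_\infty} (default TRUE);
#'   it absorbs the negative correlogram bias of finite traces at long lags.
#' @param fit_range Optional `c(min_lag_s, max_lag_s)`.
#' @return The curve with its `fit` element filled: `N`, `components`
#'   (data frame `tau_D`, `fraction`, `nonphysical`), `slow_tau_D` (the
#'   slowest component carrying at least 5% of the amplitude), `offset`,
#'   `structure`, `reduced_chi2`, `converged`.
#' @export
fit_fcs_two_component <- function(curve, n_components = 2, structure = 5,
                                  fit_structure = FALSE, fit_offset = TRUE,
                                  fit_range = NULL) {
  stopifnot(inherits(curve, "correlation_curve"))
  sel <- is.finite(curve$G)
  if (!is.null(fit_range))
    sel <- sel & curve$lag_s >= fit_range[1] & curve$lag_s <= fit_range[2]
  tau <- curve$lag_s[sel]
  g <- curve$G[sel]
  if (length(tau) < 6) stop("too few lags to fit")
  k <- as.integer(n_components)
  stopifnot(k %in% 1:2)

  g0 <- max(mean(g[seq_len(min(3, length(g)))]), 1e-6)
  # lag at half amplitude as a tau_D guess
  td0 <- tau[which.min(abs(g - g0 / 2))]
  par0 <- if (k == 1) c(log(1 / g0), log(td0))
          else c(log(1 / g0), log(td0 / 5), log(td0 * 2), 0)
  i_td <- 1 + seq_len(k)
  if (fit_offset) par0 <- c(par0, 0)
  if (fit_structure) par0 <- c(par0, log(structure))

  unpack <- function(p) {
    out <- list(N = exp(p[1]), off = 0, s = structure)
    if (k == 1) { out$tds <- exp(p[2]); out$fr <- 1 }
    else { out$tds <- exp(p[2:3]); f1 <- stats::plogis(p[4])
           out$fr <- c(f1, 1 - f1) }
    j <- if (k == 1) 3 else 5
    if (fit_offset) { out$off <- p[j]; j <- j + 1 }
    if (fit_structure) out$s <- exp(p[j])
    out
  }
  resid_fun <- function(p) {
    u <- unpack(p)
    g - fcs_diffusion_model(tau, u$N, u$tds, u$fr, u$s) - u$off
  }
  # diffusion times are only identifiable inside the measured lag range
  lower <- rep(-Inf, length(par0)); upper <- rep(Inf, length(par0))
  lower[i_td] <- log(min(tau) / 10); upper[i_td] <- log(max(tau))
  fit <- minpack.lm::nls.lm(par0, lower = lower, upper = upper, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- fit$par
  u <- unpack(p)
  tds <- u$tds; fr <- u$fr
  ord <- order(tds)
  tds <- tds[ord]; fr <- fr[ord]
  # near-degenerate components are not identifiable: collapse them onto one
  if (length(tds) == 2 && tds[2] / tds[1] < 1.15) {
    tds <- sum(tds * fr)
    fr <- 1
  }
  npar <- length(p)
  chi2 <- sum(resid_fun(p)^2) / (length(tau) - npar)
  meaningful <- fr >= 0.05
  if (!any(meaningful)) meaningful <- fr == max(fr)
  curve$fit <- list(
    N = u$N,
    components = data.frame(tau_D = tds, fraction = fr,
                            nonphysical = tds < 10 * curve$bin_time),
    slow_tau_D = max(tds[meaningful]),
    offset = u$off,
    structure = u$s, reduced_chi2 = chi2,
    converged = fit$info %in% 1:4)
  curve
}

#' Bi-exponential photobleaching fit of an intensity trajectory
#'
#' Fits \eqn{F(t) = A_1 e^{-k_1 t} + A_2 e^{-k_2 t} + c} (components sorted
#' fast-first, \eqn{k_1 \ge k_2}) to the trajectory rebinned to at most
#' `max_points` points. In-focus dwell time sets bleaching probability, so
#' the fast component reports on slowly diffusing species and vice versa; a
#' valid FCS readout requires both bleaching timescales (1/k) to exceed the
#' diffusion times seen in the autocorrelation.
#'
#' @param traj An [intensity_trajectory()] with >= 100 bins.
#' @param max_points Rebin target for fitting.
#' @return A `bleach_fit` object: `amplitudes` (A1, A2), `rates` (k1 >= k2,
#'   1/s), `offset`, `reduced_chi2`, `decaying` (FALSE flags a non-decaying
#'   trajectory, where amplitudes collapse to ~0), `converged`.
#' @export
fit_photobleaching <- function(traj, max_points = 1000) {
  stopifnot(inherits(traj, "intensity_trajectory"))
  f <- traj$counts
  if (length(f) < 100) stop("photobleaching fit requires >= 100 bins")
  block <- max(1L, ceiling(length(f) / max_points))
  nb <- length(f) %/% block
  y <- colMeans(matrix(f[seq_len(nb * block)], block, nb))
  t <- (seq_len(nb) - 0.5) * block * traj$bin_time
  T_ <- max(t)
  head_m <- mean(y[seq_len(max(3, nb %/% 10))])
  tail_m <- mean(y[(nb - max(3, nb %/% 10) + 1):nb])
  drop <- max(head_m - tail_m, 0)
  par0 <- c(A1 = drop / 2, A2 = drop / 2, lk1 = log(5 / T_), lk2 = log(0.5 / T_),
            c = max(tail_m, 1e-9))
  resid_fun <- function(p)
    y - (p[1] * exp(-exp(p[3]) * t) + p[2] * exp(-exp(p[4]) * t) + p[5])
  fit <- minpack.lm::nls.lm(par0, fn = resid_fun,
                            lower = c(0, 0, log(1e-3 / T_), log(1e-3 / T_), 0),
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- fit$par
  A <- p[1:2]; kk <- exp(p[3:4]); off <- p[5]
  ord <- order(kk, decreasing = TRUE)
  A <- A[ord]; kk <- kk[ord]
  decaying <- sum(A) > 2 * stats::sd(y) / sqrt(nb)
  structure(list(amplitudes = unname(A), rates = unname(kk),
                 offset = unname(off),
                 reduced_chi2 = sum(resid_fun(p)^2) / (nb - 5),
                 decaying = decaying, converged = fit$info %in% 1:4),
            class = "bleach_fit")
}

#' @export
print.bleach_fit <- function(x, ...) {
  cat(sprintf("bi-exponential bleach fit%s:\n",
              if (x$decaying) "" else " (non-decaying trajectory)"))
  cat(sprintf("  A1 = %.4g, k1 = %.4g 1/s (fast); A2 = %.4g, k2 = %.4g 1/s; offset %.4g\n",
              x$amplitudes[1], x$rates[1], x$amplitudes[2], x$rates[2], x$offset))
  invisible(x)
}

#' Read / write correlation curves as CSV
#'
#' Columns `lag_s` and `G`.
#' @param curve A `correlation_curve`.
#' @param path File path.
#' @export
write_correlation_csv <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  utils::write.csv(data.frame(lag_s = curve$lag_s, G = curve$G), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_correlation_csv
#' @param bin_time Counting bin time of the originating trajectory, s.
#' @export
read_correlation_csv <- function(path, bin_time = NA_real_) {
  df <- utils::read.csv(path)
  stopifnot(all(c("lag_s", "G") %in% names(df)))
  structure(list(lag_s = df$lag_s, G = df$G,
                 lag_bins = if (is.na(bin_time)) rep(NA_real_, nrow(df))
                            else round(df$lag_s / bin_time),
                 raw_resolution = rep(NA, nrow(df)),
                 bin_time = bin_time, scheme = "file", fit = NULL),
            class = "correlation_curve")
}
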