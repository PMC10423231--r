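# Lifetime-vs-FVO calibration: crowder conversion, onset changepoint,
# tryptophan spectra and the sigmoid transition.

#' Convert crowder concentration to fractional volume occupancy
#'
#' FVO (%) = concentration (% w/v, i.e. g/100 mL) times the crowder's partial
#' specific volume (mL/g), clamped to \[0, 100\]. For PEG a partial specific
#' volume of ~0.84 mL/g is typical; 1.0 makes FVO numerically equal % w/v
#' (convenient for synthetic data).
#'
#' @param conc Concentration, % w/v (>= 0).
#' @param partial_specific_volume Crowder partial specific volume, mL/g.
#' @return FVO in percent.
#' @export
fvo_from_concentration <- function(conc, partial_specific_volume = 0.84) {
  stop_field(all(conc >= 0), "conc", "must be non-negative")
  stop_field(partial_specific_volume > 0, "partial_specific_volume",
             "must be positive")
  pmin(conc * partial_specific_volume, 100)
}

#' @rdname fvo_from_concentration
#' @param fvo FVO in percent.
#' @export
concentration_from_fvo <- function(fvo, partial_specific_volume = 0.84) {
  stop_field(all(fvo >= 0 & fvo <= 100), "fvo", "must be in [0, 100]")
  fvo / partial_specific_volume
}

#' Generate a synthetic lifetime-vs-FVO calibration table
#'
#' Emulates the empirical calibration shape: the mean lifetime sits at a
#' plateau up to an onset FVO, then declines linearly (fluorescence lifetime
#' reduction sets in only above ~30% FVO for mCherry). Gaussian noise is
#' added per point.
#'
#' @param onset_fvo Onset of the decline, % FVO.
#' @param plateau_lifetime Plateau lifetime, ns.
#' @param slope Decline slope above the onset, ns per % FVO (<= 0).
#' @param fvo_grid Sorted FVO values in \[0, 100\].
#' @param noise_sd Gaussian noise on the lifetimes, ns (>= 0).
#' @param seed Integer seed.
#' @param crowder Label stored with the table.
#' @return Data frame with columns `fvo` and `mean_lifetime` (attribute
#'   `"crowder"`).
#' @examples
#' generate_calibration_table(30, 1.45, -0.01, seq(0, 50, 5), 0, seed = 1)
#' @export
generate_calibration_table <- function(onset_fvo, plateau_lifetime, slope,
                                       fvo_grid, noise_sd = 0, seed = 1,
                                       crowder = "synthetic") {
  stop_field(!is.unsorted(fvo_grid) && all(fvo_grid >= 0 & fvo_grid <= 100),
             "fvo_grid", "must be sorted and within [0, 100]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  stop_field(slope <= 0, "slope", "must be <= 0 (a decline)")
  stop_field(plateau_lifetime > 0, "plateau_lifetime", "must be positive")
  lt <- plateau_lifetime + slope * pmax(fvo_grid - onset_fvo, 0)
  if (noise_sd > 0)
    lt <- with_seed(seed, lt + stats::rnorm(length(lt), sd = noise_sd))
  out <- data.frame(fvo = fvo_grid, mean_lifetime = lt)
  attr(out, "crowder") <- crowder
  out
}

#' Detect the lifetime-reduction onset in a calibration curve
#'
#' Two-segment (flat plateau + linear decline) least-squares changepoint fit:
#' for each candidate breakpoint the model `lifetime = c + s * max(fvo - b, 0)`
#' is linear in `(c, s)` and solved in closed form; the breakpoint minimizing
#' the residual sum of squares is the onset. If the segmented model does not
#' significantly improve on a flat fit (or the fitted slope is non-negative),
#' no onset is reported. An optional bootstrap (residual resampling) gives a
#' confidence interval.
#'
#' @param table Data frame with columns `fvo` and `mean_lifetime` (>= 5 points
#'   spanning the onset).
#' @param n_boot Bootstrap resamples for the CI (0 disables).
#' @param conf CI level.
#' @param grid_step Candidate-breakpoint resolution, % FVO (observed FVO
#'   values are always included as candidates).
#' @param seed Seed for the bootstrap.
#' @return List: `onset` (% FVO, or `NA` with `reason` when no onset),
#'   `ci` (`c(lo, hi)` or NULL), `plateau`, `slope`, `p_value` (F-test of the
#'   segmented model against a flat fit).
#' @export
detect_reduction_onset <- function(table, n_boot = 200, conf = 0.95,
                                   grid_step = 0.1, seed = 1) {
  stopifnot(all(c("fvo", "mean_lifetime") %in% names(table)))
  x <- table$fvo; y <- table$mean_lifetime
  if (length(x) < 5) stop("need at least 5 calibration points")

  fit_at <- function(b, xx, yy) {
    z <- pmax(xx - b, 0)
    if (all(z == 0)) {
      c_ <- mean(yy)
      return(list(sse = sum((yy - c_)^2), c = c_, s = 0))
    }
    X <- cbind(1, z)
    cf <- tryCatch(solve(crossprod(X), crossprod(X, yy)),
                   error = function(e) c(mean(yy), 0))
    res <- yy - X %*% cf
    list(sse = sum(res^2), c = cf[1], s = cf[2])
  }
  best_onset <- function(xx, yy) {
    cand <- sort(unique(c(xx[2:(length(xx) - 1)],
                          seq(xx[2], xx[length(xx) - 1], by = grid_step))))
    sse <- vapply(cand, function(b) fit_at(b, xx, yy)$sse, numeric(1))
    b <- cand[which.min(sse)]
    c(b = b, sse = min(sse))
  }

  bb <- best_onset(x, y)
  seg <- fit_at(bb["b"], x, y)
  flat_sse <- sum((y - mean(y))^2)
  n <- length(x)
  # F-test of the 3-parameter segmented model against the flat model
  dfree <- n - 3
  f_stat <- if (flat_sse - seg$sse <= 0) 0
            else if (seg$sse <= 0) Inf
            else ((flat_sse - seg$sse) / 2) / (seg$sse / dfree)
  p_val <- stats::pf(f_stat, 2, dfree, lower.tail = FALSE)
  scale_y <- max(abs(y), 1e-12)
  if (seg$s >= -1e-10 * scale_y || p_val > 0.05) {
    return(list(onset = NA_real_, ci = NULL, plateau = mean(y), slope = seg$s,
                p_value = p_val, reason = "no significant decline"))
  }

  ci <- NULL
  if (n_boot > 0) {
    fitted <- seg$c + seg$s * pmax(x - bb["b"], 0)
    res <- y - fitted
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      yb <- fitted + sample(res, n, replace = TRUE)
      best_onset(x, yb)["b"]
    }, numeric(1)))
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(boots, c(a, 1 - a)))
  }
  list(onset = unname(bb["b"]), ci = ci, plateau = seg$c, slope = seg$s,
       p_value = p_val)
}

#' Area and peak wavelength of an emission spectrum
#'
#' Trapezoidal area over the recorded range and the wavelength of maximal
#' intensity (after optional 3-point moving-average smoothing). Used for
#' tryptophan emission spectra, whose area drops sigmoidally with crowding.
#'
#' @param wavelength Strictly increasing wavelength grid, nm (>= 3 points).
#' @param intensity Non-negative intensities.
#' @param smooth Apply 3-point smoothing before locating the peak.
#' @return List: `area`, `lambda_max` (nm; `NA` for an all-zero spectrum).
#' @export
spectrum_area_and_lambda_max <- function(wavelength, intensity, smooth = FALSE) {
  stopifnot(length(wavelength) == length(intensity), length(wavelength) >= 3)
  stop_field(all(diff(wavelength) > 0), "wavelength", "must be strictly increasing")
  stop_field(all(intensity >= 0), "intensity", "must be non-negative")
  area <- sum(diff(wavelength) * (intensity[-1] + intensity[-length(intensity)]) / 2)
  if (all(intensity == 0)) return(list(area = 0, lambda_max = NA_real_))
  y <- intensity
  if (smooth) {
    y <- stats::filter(intensity, rep(1 / 3, 3), sides = 2)
    y[is.na(y)] <- intensity[is.na(y)]
    y <- as.numeric(y)
  }
  list(area = area, lambda_max = wavelength[which.max(y)])
}

#' Fit a sigmoid transition to area-vs-FVO data
#'
#' Least-squares fit of
#' \eqn{y = lower + (upper - lower) / (1 + e^{(x - midpoint)\,steepness})}
#' (decreasing in `x` for `steepness > 0`; either sign is accepted). The
#' midpoint uncertainty comes from the covariance diagonal.
#'
#' @param x FVO values, % (>= 5 points).
#' @param y Areas (or any monotone transition signal).
#' @return A `sigmoid_fit` object: `midpoint` (% FVO), `steepness` (1/%),
#'   `lower`, `upper`, `midpoint_se`, `converged`.
#' @export
fit_sigmoid_transition <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5) stop("need at least 5 points")
  decreasing <- stats::cor(x, y) < 0
  lo0 <- min(y); up0 <- max(y)
  mid0 <- stats::approx(y, x, xout = (lo0 + up0) / 2, ties = mean)$y
  if (is.na(mid0)) mid0 <- stats::median(x)
  k0 <- (if (decreasing) 1 else -1) * 4 / max(diff(range(x)), 1e-6)
  resid_fun <- function(p)
    y - (p[1] + (p[2] - p[1]) / (1 + exp((x - p[3]) * p[4])))
  fit <- minpack.lm::nls.lm(c(lo0, up0, mid0, k0), fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  p <- fit$par
  dof <- length(x) - 4
  sigma2 <- sum(resid_fun(p)^2) / max(dof, 1)
  covm <- tryCatch(sigma2 * solve(fit$hessian / 2), error = function(e)
    matrix(NA_real_, 4, 4))
  structure(list(midpoint = p[3], steepness = p[4],
                 lower = min(p[1], p[2]), upper = max(p[1], p[2]),
                 midpoint_se = sqrt(abs(covm[3, 3])),
                 reduced_chi2 = sigma2, converged = fit$info %in% 1:4),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("sigmoid transition fit%s: midpoint %.3f +/- %.3f %% FVO, plateaus [%.4g, %.4g]\n",
              if (x$converged) "" else " (FLAGGED)", x$midpoint,
              x$midpoint_se, x$lower, x$upper))
  invisible(x)
}

#' Classify the crowding regime from a mean lifetime
#'
#' One-sided readout: lifetimes strictly below the boundary report crowding
#' at or above the ~30% FVO threshold; lifetimes at or above it are "not
#' resolved" (the sensor only reports crowding above threshold, it cannot
#' certify dilution).
#'
#' @param mean_lifetime Mean lifetime, ns (> 0).
#' @param boundary Boundary lifetime, ns (1.44 for mCherry on the calibrating
#'   instrument).
#' @return `"crowded_ge_30pct"` or `"not_resolved"` (vectorized).
#' @examples
#' classify_fvo_regime(c(1.30, 1.44, 1.55))
#' @export
classify_fvo_regime <- function(mean_lifetime, boundary = 1.44) {
  stop_field(all(mean_lifetime > 0), "mean_lifetime", "must be positive")
  ifelse(mean_lifetime < boundary, "crowded_ge_30pct", "not_resolved")
}
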