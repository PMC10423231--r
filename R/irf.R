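#' Instrument response functions
#'
#' The instrument response function (IRF) is the measured system response to
#' an instantaneous emitter; recorded decays are the true decay law convolved
#' with it. Two representations are supported: a parametric Gaussian
#' (`gaussian_irf`), adequate for a ~100 ps FWHM pulsed laser, and a measured
#' histogram (`measured_irf`), normalized to unit area.
#'
#' @param fwhm Full width at half maximum in ns. `fwhm = 0` gives an ideal
#'   delta-function IRF.
#' @param t0 Pulse position within the repetition window, ns. Defaults to
#'   `5 * fwhm` so that essentially no response mass falls before time zero.
#' @return An object of class `instrument_response`.
#' @examples
#' gaussian_irf(0.1)             # 100 ps FWHM pulse
#' gaussian_irf(0)               # ideal delta IRF
#' @export
gaussian_irf <- function(fwhm, t0 = 5 * fwhm) {
  stop_field(is.numeric(fwhm) && length(fwhm) == 1L && fwhm >= 0,
             "fwhm", "must be a single non-negative number")
  stop_field(is.numeric(t0) && length(t0) == 1L && t0 >= 0,
             "t0", "must be a single non-negative number")
  structure(list(type = "gaussian", fwhm = fwhm, sd = fwhm_to_sd(fwhm), t0 = t0),
            class = "instrument_response")
}

#' @rdname gaussian_irf
#' @param h A [decay_histogram()] holding the measured IRF; it is normalized
#'   to unit area internally.
#' @export
measured_irf <- function(h) {
  stopifnot(inherits(h, "decay_histogram"))
  if (h$total_photons <= 0) stop("measured IRF has zero total counts")
  structure(list(type = "measured",
                 mass = h$counts / sum(h$counts),
                 bin_width = h$bin_width),
            class = "instrument_response")
}

#' @export
print.instrument_response <- function(x, ...) {
  if (x$type == "gaussian")
    cat(sprintf("Gaussian IRF: FWHM %.4g ns, t0 %.4g ns\n", x$fwhm, x$t0))
  else
    cat(sprintf("Measured IRF: %d bins x %.4g ns (unit area)\n",
                length(x$mass), x$bin_width))
  invisible(x)
}

# Unit-mass discrete IRF kernel on an n_bins x bin_width grid, wrapped on the
# repetition window.
irf_bin_mass <- function(irf, n_bins, bin_width) {
  stopifnot(inherits(irf, "instrument_response"))
  if (irf$type == "measured") {
    if (abs(irf$bin_width - bin_width) > 1e-9 * bin_width)
      stop("measured IRF bin width does not match the model grid")
    m <- irf$mass
    if (length(m) > n_bins) stop("measured IRF longer than the model grid")
    c(m, rep(0, n_bins - length(m)))
  } else {
    edges <- seq(0, n_bins * bin_width, by = bin_width)
    if (irf$sd == 0) {
      m <- numeric(n_bins)
      k <- (floor(irf$t0 / bin_width) %% n_bins) + 1L
      m[k] <- 1
      m
    } else {
      # Gaussian mass per bin, wrapped so the kernel is a distribution on the window
      window <- n_bins * bin_width
      m <- numeric(n_bins)
      for (j in -2:2) {
        lo <- stats::pnorm(edges[-length(edges)] + j * window, irf$t0, irf$sd)
        hi <- stats::pnorm(edges[-1] + j * window, irf$t0, irf$sd)
        m <- m + (hi - lo)
      }
      m / sum(m)
    }
  }
}
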