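# Pixel-wise lifetime images and condensate statistics.

#' Build a pixel-wise lifetime image from a photon-record stream
#'
#' Photons are accumulated per pixel across frames; each pixel with at least
#' `min_photons` photons gets a mono-exponential tail fit
#' ([tail_fit_monoexponential()]) of its micro-time histogram. Pixels below
#' the gate (or with degenerate fits) carry the 0 sentinel: a lifetime of
#' exactly 0 ns means "no estimate", never a measured value.
#'
#' @param stream Photon-record data frame (`frame`, `x`, `y`, `channel`,
#'   `microtime_ns`); `x`/`y` are 0-based column/row indices.
#' @param shape `c(rows, cols)` of the image.
#' @param min_photons Photon gate per pixel (100 for in-cell FLIM, 30 for
#'   in vitro maps).
#' @param frames Optional vector of frame numbers to accumulate (default all).
#' @param bin_width Micro-time histogram bin width, ns.
#' @param window Repetition window, ns (default: next bin above the largest
#'   micro-time).
#' @param tail_start_offset Passed to [tail_fit_monoexponential()].
#' @return A `lifetime_image` object: `lifetime` matrix (ns; 0 sentinel),
#'   `counts` matrix, `min_photons`.
#' @export
build_lifetime_image <- function(stream, shape, min_photons = 100,
                                 frames = NULL, bin_width = 0.1,
                                 window = NULL, tail_start_offset = 0.2) {
  stopifnot(length(shape) == 2L)
  nr <- shape[1]; nc <- shape[2]
  if (nrow(stream) > 0) {
    if (any(stream$x < 0 | stream$x >= nc | stream$y < 0 | stream$y >= nr))
      stop("stream contains pixels outside the image shape")
    if (!is.null(frames)) stream <- stream[stream$frame %in% frames, ]
  }
  lifetime <- matrix(0, nr, nc)
  counts <- matrix(0L, nr, nc)
  if (nrow(stream) == 0)
    return(structure(list(lifetime = lifetime, counts = counts,
                          min_photons = min_photons), class = "lifetime_image"))
  if (is.null(window)) window <- (floor(max(stream$microtime_ns) / bin_width) + 1) * bin_width
  n_bins <- ceiling(window / bin_width)
  pix <- stream$y + nr * stream$x + 1L   # column-major linear index
  tab <- tabulate(pix, nr * nc)
  counts[] <- tab
  gated <- which(tab >= max(min_photons, 1))
  mt_by_pix <- split(stream$microtime_ns, pix)
  for (p in gated) {
    mt <- mt_by_pix[[as.character(p)]]
    cts <- tabulate(pmin(floor(mt / bin_width) + 1L, n_bins), n_bins)
    h <- decay_histogram(cts, bin_width)
    tau <- tail_fit_monoexponential(h, min_photons = min_photons,
                                    tail_start_offset = tail_start_offset)
    if (!is.na(tau)) lifetime[p] <- as.numeric(tau)
  }
  structure(list(lifetime = lifetime, counts = counts,
                 min_photons = min_photons), class = "lifetime_image")
}

#' @export
print.lifetime_image <- function(x, ...) {
  g <- x$lifetime > 0
  cat(sprintf("lifetime image %d x %d: %d gated pixels (gate %d photons)",
              nrow(x$lifetime), ncol(x$lifetime), sum(g), x$min_photons))
  if (any(g)) cat(sprintf(", mean %.3f ns", mean(x$lifetime[g])))
  cat("\n")
  invisible(x)
}

#' Per-condensate lifetime statistics
#'
#' For each labeled region of interest: mean and standard deviation of the
#' pixel lifetimes, computed strictly over gated pixels (the 0 sentinel is
#' always excluded), the fraction of gated pixels below the crowding
#' boundary, and the crowding class: a condensate whose mean lifetime falls
#' below the boundary reports a local density above the ~30% FVO threshold.
#'
#' @param image A [build_lifetime_image()] result (or a bare matrix with the
#'   0 sentinel convention).
#' @param mask Integer label matrix, same shape; 0 = outside all ROIs.
#' @param boundary Crowding boundary in ns (1.44 ns for mCherry; instrument-
#'   and fluorophore-specific, so a parameter, not a constant).
#' @return Data frame, one row per ROI label: `roi`, `n_pixels`,
#'   `mean_lifetime`, `sd_lifetime`, `fraction_below`, `class`
#'   (`"above_30pct_FVO"` / `"below_30pct_FVO"`), `empty`.
#' @export
condensate_statistics <- function(image, mask, boundary = 1.44) {
  lt <- if (inherits(image, "lifetime_image")) image$lifetime else image
  if (!all(dim(lt) == dim(mask))) stop("mask shape must match image shape")
  labs <- sort(unique(mask[mask > 0]))
  out <- lapply(labs, function(L) {
    v <- lt[mask == L]
    v <- v[v > 0]
    if (length(v) == 0)
      return(data.frame(roi = L, n_pixels = 0L, mean_lifetime = NA_real_,
                        sd_lifetime = NA_real_, fraction_below = NA_real_,
                        class = NA_character_, empty = TRUE))
    m <- mean(v)
    data.frame(roi = L, n_pixels = length(v), mean_lifetime = m,
               sd_lifetime = if (length(v) > 1) stats::sd(v) else 0,
               fraction_below = mean(v < boundary),
               class = if (m < boundary) "above_30pct_FVO" else "below_30pct_FVO",
               empty = FALSE)
  })
  do.call(rbind, out)
}

#' Histogram of pixel lifetimes within a mask
#'
#' Counts gated (nonzero) pixels only; the histogram total therefore equals
#' the gated pixel count.
#'
#' @param image A `lifetime_image` or matrix.
#' @param mask Optional label matrix; pixels with `mask > 0` are used.
#' @param bin_width Histogram bin width, ns.
#' @return List: `breaks`, `mids`, `counts`.
#' @export
pixel_lifetime_histogram <- function(image, mask = NULL, bin_width = 0.02) {
  lt <- if (inherits(image, "lifetime_image")) image$lifetime else image
  v <- if (is.null(mask)) lt[lt > 0] else lt[mask > 0 & lt > 0]
  if (length(v) == 0) return(list(breaks = numeric(), mids = numeric(),
                                  counts = integer()))
  breaks <- seq(floor(min(v) / bin_width) * bin_width,
                (floor(max(v) / bin_width) + 1) * bin_width, by = bin_width)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, mids = h$mids, counts = h$counts)
}

#' Compare two condensate populations (means and variances)
#'
#' Two-sided T-test on the means (Welch by default) and two-sided
#' variance-ratio F-test, with the conventional star labels:
#' p > 0.05 "n.s.", 0.01 < p <= 0.05 "*", 0.001 < p <= 0.01 "**",
#' p <= 0.001 "***".
#'
#' @param means_a,means_b Numeric vectors (length >= 2) of per-condensate
#'   mean lifetimes, ns.
#' @param var_equal Use the pooled-variance Student T-test instead of Welch.
#' @return List: `t_p`, `f_p`, `t_stars`, `f_stars`, `t_statistic`,
#'   `f_statistic`.
#' @examples
#' compare_populations(rnorm(20, 1.4, 0.05), rnorm(20, 1.5, 0.02))
#' @export
compare_populations <- function(means_a, means_b, var_equal = FALSE) {
  if (length(means_a) < 2 || length(means_b) < 2)
    stop("each population needs at least 2 values")
  va <- stats::var(means_a); vb <- stats::var(means_b)
  if (va == 0 && vb == 0) {
    t_stat <- if (mean(means_a) == mean(means_b)) 0 else Inf
    t_p <- if (t_stat == 0) 1 else 0
  } else {
    tt <- stats::t.test(means_a, means_b, var.equal = var_equal)
    t_stat <- unname(tt$statistic); t_p <- tt$p.value
  }
  if (vb == 0 && va == 0) {
    f_stat <- 1; f_p <- 1
  } else if (vb == 0 || va == 0) {
    f_stat <- if (vb == 0) Inf else 0; f_p <- 0
  } else {
    f_stat <- va / vb
    df1 <- length(means_a) - 1L; df2 <- length(means_b) - 1L
    f_p <- 2 * min(stats::pf(f_stat, df1, df2),
                   stats::pf(f_stat, df1, df2, lower.tail = FALSE))
    f_p <- min(f_p, 1)
  }
  list(t_p = t_p, f_p = f_p,
       t_stars = p_stars(t_p), f_stars = p_stars(f_p),
       t_statistic = t_stat, f_statistic = f_stat)
}

#' @rdname compare_populations
#' @param p A p-value.
#' @export
p_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p > 0.05) "n.s." else if (p > 0.01) "*" else if (p > 0.001) "**" else "***"
}

#' Pixel-wise lifetime vs intensity correlation
#'
#' Pearson correlation between pixel lifetime and pixel photon count over
#' gated pixels. Lifetime-based density readout is (at most weakly) intensity
#' dependent, so this should sit near zero for a well-behaved image.
#'
#' @param image A `lifetime_image`.
#' @return Pearson r, or `NA` (with attribute `"reason"`) when fewer than 3
#'   gated pixels or a constant input make it undefined.
#' @export
lifetime_intensity_correlation <- function(image) {
  stopifnot(inherits(image, "lifetime_image"))
  g <- image$lifetime > 0
  if (sum(g) < 3) {
    out <- NA_real_; attr(out, "reason") <- "fewer than 3 gated pixels"; return(out)
  }
  x <- image$lifetime[g]; y <- image$counts[g]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- NA_real_; attr(out, "reason") <- "constant input"; return(out)
  }
  stats::cor(x, y)
}
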