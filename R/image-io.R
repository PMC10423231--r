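# TIFF / PNG image interfaces for lifetime maps and ROI label masks.

#' Write / read lifetime images as 32-bit float TIFF
#'
#' The lifetime map is written as a 32-bit float TIFF keeping the 0
#' no-estimate sentinel; the photon-count map (16-bit) goes to a second page.
#'
#' @param image A [build_lifetime_image()] result.
#' @param path Output TIFF path.
#' @param lifetime_scale Full-scale lifetime in ns: stored values are
#'   `lifetime / lifetime_scale` (the TIFF writer expects \[0, 1\] data);
#'   re-applied on read. 100 ns covers any fluorescence lifetime.
#' @param count_scale Divisor applied to counts so they fit 16-bit on write
#'   (re-applied on read).
#' @return `path`, invisibly; `read_lifetime_tiff` returns a
#'   `lifetime_image`.
#' @export
write_lifetime_tiff <- function(image, path, lifetime_scale = 100,
                                count_scale = 1) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("TIFF i/o requires the tiff package")
  stopifnot(inherits(image, "lifetime_image"))
  if (max(image$lifetime) > lifetime_scale)
    stop("lifetime values exceed lifetime_scale")
  counts16 <- pmin(image$counts / count_scale, 65535) / 65535
  tiff::writeTIFF(list(image$lifetime / lifetime_scale, counts16), path,
                  bits.per.sample = 32)
  invisible(path)
}

#' @rdname write_lifetime_tiff
#' @param min_photons Photon gate recorded with the returned image.
#' @export
read_lifetime_tiff <- function(path, min_photons = 100, lifetime_scale = 100,
                               count_scale = 1) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("TIFF i/o requires the tiff package")
  pages <- tiff::readTIFF(path, all = TRUE)
  lifetime <- pages[[1]] * lifetime_scale
  counts <- if (length(pages) > 1) round(pages[[2]] * 65535 * count_scale)
            else matrix(NA_real_, nrow(lifetime), ncol(lifetime))
  structure(list(lifetime = lifetime, counts = counts,
                 min_photons = min_photons), class = "lifetime_image")
}

#' Read an integer-label ROI mask from TIFF or PNG
#'
#' Gray values are mapped back to integer labels (0 = outside all ROIs).
#'
#' @param path TIFF or PNG path.
#' @param max_label Label corresponding to full intensity in normalized
#'   (0-1) images; defaults to 255 (8-bit convention).
#' @return Integer matrix of labels.
#' @export
read_roi_mask <- function(path, max_label = 255) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("PNG i/o requires the png package")
    png::readPNG(path)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("TIFF i/o requires the tiff package")
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img * max_label)), nrow(img), ncol(img))
}
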