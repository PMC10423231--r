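#' Specification for a simulated FLIM scene
#'
#' Describes a lifetime field: a uniform background plus disk-shaped
#' condensates, each with a uniform lifetime or a two-subdomain split, and a
#' Poisson photon budget per pixel. Condensates may overlap; the later entry
#' in `condensates` wins.
#'
#' @param image_shape `c(rows, cols)` in pixels.
#' @param condensates List of condensate descriptors, each a list with
#'   `center = c(row, col)` (1-based pixel coordinates), `radius` (pixels,
#'   > 0) and `lifetime`: either a single value (ns) or a list
#'   `list(values = c(ns, ns), fraction = f)` splitting the disk into two
#'   subdomains along the column axis, a fraction `f` of gated pixels taking
#'   `values[1]`.
#' @param background_lifetime Lifetime outside condensates, ns.
#' @param photon_budget Expected photons per pixel: a scalar or a matrix of
#'   `image_shape`.
#' @param n_frames Number of scan frames photons are spread over.
#' @param window Repetition window for photon micro-times, ns.
#' @param seed Integer seed.
#' @return An object of class `flim_scene_spec`.
#' @export
flim_scene_spec <- function(image_shape, condensates = list(),
                            background_lifetime = 1.5, photon_budget = 100,
                            n_frames = 1L, window = 50, seed = 1) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 1))
  stop_field(background_lifetime > 0, "background_lifetime", "must be positive")
  stop_field(all(photon_budget >= 0), "photon_budget", "must be non-negative")
  for (cd in condensates) {
    stop_field(cd$radius > 0, "radius", "must be positive")
    lt <- if (is.list(cd$lifetime)) cd$lifetime$values else cd$lifetime
    stop_field(all(lt > 0), "lifetime", "must be positive")
    stop_field(all(cd$center >= 1) && cd$center[1] <= image_shape[1] &&
                 cd$center[2] <= image_shape[2],
               "center", "must lie within the image")
  }
  structure(list(image_shape = as.integer(image_shape),
                 condensates = condensates,
                 background_lifetime = background_lifetime,
                 photon_budget = photon_budget, n_frames = as.integer(n_frames),
                 window = window, seed = seed),
            class = "flim_scene_spec")
}

# ground-truth lifetime map and condensate label mask for a scene spec
flim_scene_truth <- function(spec) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  lt <- matrix(spec$background_lifetime, nr, nc)
  labels <- matrix(0L, nr, nc)
  rows <- row(lt); cols <- col(lt)
  for (i in seq_along(spec$condensates)) {
    cd <- spec$condensates[[i]]
    inside <- (rows - cd$center[1])^2 + (cols - cd$center[2])^2 <= cd$radius^2
    labels[inside] <- i
    if (is.list(cd$lifetime)) {
      idx <- which(inside)
      # split along the column axis: the leftmost fraction takes values[1]
      ord <- idx[order(cols[idx], rows[idx])]
      n1 <- round(cd$lifetime$fraction * length(ord))
      lt[ord[seq_len(n1)]] <- cd$lifetime$values[1]
      lt[ord[setdiff(seq_along(ord), seq_len(n1))]] <- cd$lifetime$values[2]
    } else {
      lt[inside] <- cd$lifetime
    }
  }
  list(lifetime = lt, labels = labels)
}

#' Simulate a FLIM photon-record stream
#'
#' Per-pixel photon counts are Poisson with the scene's photon budget;
#' each photon's micro-time is an exponential draw at that pixel's
#' ground-truth lifetime, wrapped on the repetition window. Returns the
#' columnar photon-record stream consumed by [build_lifetime_image()]
#' together with the ground truth, for recovery tests.
#'
#' @param spec A [flim_scene_spec()].
#' @return List: `stream` (data frame with columns `frame`, `x` (column,
#'   0-based), `y` (row, 0-based), `channel`, `microtime_ns`), `truth`
#'   (ground-truth lifetime matrix), `labels` (condensate label matrix) and
#'   `counts` (realized per-pixel photon counts).
#' @export
simulate_flim_scene <- function(spec) {
  stopifnot(inherits(spec, "flim_scene_spec"))
  gt <- flim_scene_truth(spec)
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  budget <- if (is.matrix(spec$photon_budget)) spec$photon_budget
            else matrix(spec$photon_budget, nr, nc)
  stopifnot(all(dim(budget) == spec$image_shape))
  with_seed(spec$seed, {
    counts <- matrix(stats::rpois(nr * nc, budget), nr, nc)
    tot <- sum(counts)
    if (tot == 0) {
      stream <- data.frame(frame = integer(), x = integer(), y = integer(),
                           channel = integer(), microtime_ns = numeric())
    } else {
      pix <- rep.int(seq_len(nr * nc), as.vector(counts))
      yy <- (pix - 1L) %% nr          # row, 0-based
      xx <- (pix - 1L) %/% nr         # col, 0-based
      tau <- as.vector(gt$lifetime)[pix]
      mt <- stats::rexp(tot, rate = 1 / tau) %% spec$window
      fr <- if (spec$n_frames > 1L)
        sample.int(spec$n_frames, tot, replace = TRUE) else rep(1L, tot)
      stream <- data.frame(frame = fr, x = xx, y = yy,
                           channel = 0L, microtime_ns = mt)
    }
    list(stream = stream, truth = gt$lifetime, labels = gt$labels,
         counts = counts)
  })
}

#' Read / write photon-record streams as CSV
#'
#' Columns: `frame`, `x` (column, 0-based), `y` (row, 0-based), `channel`,
#' `microtime_ns`.
#'
#' @param stream Photon-record data frame.
#' @param path File path.
#' @export
write_photon_stream <- function(stream, path) {
  stopifnot(all(c("frame", "x", "y", "channel", "microtime_ns") %in% names(stream)))
  utils::write.csv(stream, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_photon_stream
#' @export
read_photon_stream <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("frame", "x", "y", "channel", "microtime_ns") %in% names(df)))
  df
}
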