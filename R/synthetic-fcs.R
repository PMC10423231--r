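#' Specification for a simulated FCS intensity trajectory
#'
#' Brownian point emitters in a periodic cubic box, observed through a 3D
#' Gaussian focus \eqn{W(r) = \exp(-2(x^2+y^2)/w_{xy}^2 - 2z^2/w_z^2)}.
#' Per-bin counts are Poisson with intensity \eqn{\sum_p B_p W(r_p) \Delta t}.
#' Optional irreversible photobleaching removes particles with per-bin hazard
#' \eqn{k_{bleach} W(r) \Delta t} (excitation-driven, so bleaching happens in
#' focus). The diffusion time of each species, \eqn{\tau_D = w_{xy}^2 / 4D},
#' is returned as ground truth.
#'
#' @param species Data frame with columns `D` (diffusion coefficients,
#'   um^2/s), `fraction` (non-negative, summing to 1) and `brightness`
#'   (counts/s in focus).
#' @param w_xy,w_z Lateral and axial 1/e^2 focus waists, um. The default
#'   structure parameter `w_z / w_xy` is 5, typical of a confocal spot.
#' @param box_size Periodic box edge, um; should be several waists.
#' @param duration Trajectory length, s (2 min is a typical in-cell
#'   acquisition).
#' @param bin_time Counting bin, s; `duration/bin_time` must give >= 1000 bins.
#' @param n_particles Total number of emitters in the box.
#' @param bleach_rate In-focus bleaching hazard, 1/s (0 disables).
#' @param seed Integer seed.
#' @return An object of class `fcs_sim_spec`.
#' @export
fcs_sim_spec <- function(species, w_xy = 0.25, w_z = 5 * w_xy, box_size = 2,
                         duration = 10, bin_time = 1e-4, n_particles = 10,
                         bleach_rate = 0, seed = 1) {
  stopifnot(is.data.frame(species),
            all(c("D", "fraction", "brightness") %in% names(species)))
  stop_field(all(species$fraction >= 0) && abs(sum(species$fraction) - 1) < 1e-8,
             "fraction", "must be non-negative and sum to 1")
  stop_field(all(species$D > 0), "D", "must be positive")
  stop_field(all(species$brightness >= 0), "brightness", "must be non-negative")
  if (bin_time <= 0) stop("bin_time must be positive")
  if (duration / bin_time < 1e3) stop("duration/bin_time must give >= 1000 bins")
  stop_field(box_size > 2 * w_xy, "box_size", "must exceed the focus")
  structure(list(species = species, w_xy = w_xy, w_z = w_z,
                 box_size = box_size, duration = duration, bin_time = bin_time,
                 n_particles = as.integer(n_particles),
                 bleach_rate = bleach_rate, seed = seed),
            class = "fcs_sim_spec")
}

#' Simulate an FCS intensity trajectory
#'
#' @param spec An [fcs_sim_spec()].
#' @return An `intensity_trajectory` object: `counts` per bin, `bin_time`,
#'   `duration`, plus `truth` (per-species `tau_D = w_xy^2/(4D)` in s and the
#'   spec itself).
#' @export
simulate_fcs_trajectory <- function(spec) {
  stopifnot(inherits(spec, "fcs_sim_spec"))
  n_bins <- round(spec$duration / spec$bin_time)
  dt <- spec$bin_time
  L <- spec$box_size
  with_seed(spec$seed, {
    ns <- nrow(spec$species)
    kind <- sample.int(ns, spec$n_particles, replace = TRUE,
                       prob = spec$species$fraction)
    D <- spec$species$D[kind]
    B <- spec$species$brightness[kind]
    lambda <- numeric(n_bins)
    alive_until <- rep.int(n_bins, spec$n_particles)
    # per particle: cumulative Brownian path, wrapped into [-L/2, L/2)
    for (p in seq_len(spec$n_particles)) {
      sdstep <- sqrt(2 * D[p] * dt)
      xyz <- matrix(stats::rnorm(3L * n_bins, sd = sdstep), n_bins, 3L)
      xyz[1, ] <- stats::runif(3, -L / 2, L / 2)
      xyz <- apply(xyz, 2, cumsum)
      xyz <- (xyz + L / 2) %% L - L / 2
      w <- exp(-2 * (xyz[, 1]^2 + xyz[, 2]^2) / spec$w_xy^2 -
                 2 * xyz[, 3]^2 / spec$w_z^2)
      if (spec$bleach_rate > 0) {
        hazard <- spec$bleach_rate * w * dt
        u <- stats::runif(n_bins)
        hit <- which(u < hazard)
        if (length(hit)) {
          alive_until[p] <- hit[1]
          if (hit[1] < n_bins) w[(hit[1] + 1L):n_bins] <- 0
        }
      }
      lambda <- lambda + B[p] * w
    }
    counts <- stats::rpois(n_bins, lambda * dt)
    structure(list(counts = counts, bin_time = dt,
                   duration = n_bins * dt,
                   truth = list(tau_D = spec$w_xy^2 / (4 * spec$species$D),
                                species = spec$species,
                                alive_until = alive_until, spec = spec)),
              class = "intensity_trajectory")
  })
}

#' Construct an intensity trajectory from counts
#'
#' @param counts Non-negative counts per bin.
#' @param bin_time Bin duration, s.
#' @export
intensity_trajectory <- function(counts, bin_time) {
  stop_field(all(counts >= 0), "counts", "must be non-negative")
  if (bin_time <= 0) stop("bin_time must be positive")
  structure(list(counts = as.numeric(counts), bin_time = bin_time,
                 duration = length(counts) * bin_time),
            class = "intensity_trajectory")
}

#' @export
print.intensity_trajectory <- function(x, ...) {
  cat(sprintf("intensity trajectory: %d bins x %.3g s (%.3g s total), mean %.3g counts/bin\n",
              length(x$counts), x$bin_time, x$duration, mean(x$counts)))
  invisible(x)
}

#' Read / write intensity trajectories as CSV
#'
#' Columns `time_s` (bin start) and `counts`.
#' @param traj An [intensity_trajectory()].
#' @param path File path.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "intensity_trajectory"))
  utils::write.csv(data.frame(
    time_s = (seq_along(traj$counts) - 1) * traj$bin_time,
    counts = traj$counts), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "counts") %in% names(df)))
  bt <- if (nrow(df) > 1) df$time_s[2] - df$time_s[1] else 1
  intensity_trajectory(df$counts, bt)
}
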