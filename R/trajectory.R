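# Trajectory containers, toy barrel generator and XYZ I/O.

#' Trajectory and ensemble containers
#'
#' A `trajectory` holds frames x atoms x 3 coordinates (Angstrom) plus atom
#' metadata; an `ensemble` is a list of replica trajectories sharing a
#' topology, the unit of uncertainty (SEM is computed across replicas).
#'
#' @param coords Numeric array `n_frames x n_atoms x 3`.
#' @param atoms Data frame with columns `residue_index`, `residue_name`,
#'   `atom_name`, `element` (one row per atom).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(coords, atoms) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  stopifnot(is.data.frame(atoms),
            all(c("residue_index", "residue_name", "atom_name", "element")
                %in% names(atoms)),
            nrow(atoms) == dim(coords)[2])
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  structure(list(coords = coords, atoms = atoms), class = "trajectory")
}

#' @rdname trajectory
#' @param ... Replica `trajectory` objects (or a single list of them).
#' @export
trajectory_ensemble <- function(...) {
  reps <- list(...)
  if (length(reps) == 1L && !inherits(reps[[1]], "trajectory"))
    reps <- reps[[1]]
  stopifnot(length(reps) >= 1L, all(vapply(reps, inherits, TRUE, "trajectory")))
  na <- vapply(reps, function(r) dim(r$coords)[2], integer(1))
  if (length(unique(na)) != 1L) stop("replicas must share an atom count")
  structure(reps, class = "ensemble")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames, %d atoms, %d residues\n",
              dim(x$coords)[1], dim(x$coords)[2],
              length(unique(x$atoms$residue_index))))
  invisible(x)
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble of %d replicas (%s frames each)\n", length(x),
              paste(vapply(x, function(r) dim(r$coords)[1], integer(1)),
                    collapse = "/")))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame of a trajectory
#'
#' @param traj A [trajectory()].
#' @param i Frame index.
#' @return A `frame` object: `coords` (n_atoms x 3 matrix) and `atoms`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(inherits(traj, "trajectory"), i >= 1, i <= n_frames(traj))
  structure(list(coords = traj$coords[i, , , drop = TRUE], atoms = traj$atoms),
            class = "md_frame")
}

#' Drop the equilibration period of a trajectory
#'
#' Removes the first `ceiling(fraction * n_frames)` frames (the first quarter
#' by default) from a trajectory or from every replica of an ensemble; only
#' the production tail enters analyses.
#'
#' @param x A [trajectory()] or [trajectory_ensemble()].
#' @param fraction Fraction to drop, in \[0, 1).
#' @return Same class as `x`.
#' @examples
#' # 100 frames -> 75 remain; 5 frames -> ceiling(1.25) = 2 dropped, 3 remain
#' @export
trim_equilibration <- function(x, fraction = 0.25) {
  stopifnot(fraction >= 0, fraction < 1)
  if (inherits(x, "ensemble"))
    return(trajectory_ensemble(lapply(x, trim_equilibration, fraction)))
  stopifnot(inherits(x, "trajectory"))
  drop_n <- ceiling(fraction * n_frames(x))
  keep <- seq_len(n_frames(x)) > drop_n
  if (!any(keep)) stop("trimming would leave no frames")
  trajectory(x$coords[keep, , , drop = FALSE], x$atoms)
}

#' Specification for a toy beta-barrel trajectory
#'
#' A stand-in for fluorescent-protein trajectories with a breathing
#' chromophore pocket: residues sit as single pseudo-atoms (named CA) on a
#' cylindrical barrel lattice, a central target residue (named CRO, index
#' `n_residues + 1`) plays the chromophore, and the designated pocket
#' residues sit on a small shell around it, displaced radially outward by a
#' per-state expansion offset plus thermal noise. Synthetic by construction;
#' used to validate the pocket pipeline, not to reproduce any real system.
#'
#' @param n_residues Number of barrel residues.
#' @param n_frames Number of frames (>= 4).
#' @param pocket_residue_indices Residue indices (subset of `1:n_residues`)
#'   forming the pocket.
#' @param pocket_expansion_per_state Radial offsets (Angstrom), one per state.
#' @param state_sequence Per-frame state labels (indices into the offsets).
#' @param thermal_noise_sd Gaussian coordinate noise, Angstrom.
#' @param pocket_radius Base radius of the pocket shell, Angstrom; the
#'   default 3.0 keeps pocket residues inside a 3.5 A contact cutoff of the
#'   target.
#' @param barrel_radius,barrel_rise Geometry of the outer barrel lattice.
#' @param seed Integer seed.
#' @return An object of class `toy_trajectory_spec`.
#' @export
toy_trajectory_spec <- function(n_residues, n_frames, pocket_residue_indices,
                                pocket_expansion_per_state = 0,
                                state_sequence = rep(1L, n_frames),
                                thermal_noise_sd = 0, seed = 1,
                                pocket_radius = 3.0, barrel_radius = 8.0,
                                barrel_rise = 1.5) {
  stop_field(all(pocket_residue_indices %in% seq_len(n_residues)),
             "pocket_residue_indices", "must be a subset of the residue indices")
  stop_field(n_frames >= 4, "n_frames", "must be at least 4")
  stop_field(length(state_sequence) == n_frames, "state_sequence",
             "must have one label per frame")
  stop_field(all(state_sequence %in% seq_along(pocket_expansion_per_state)),
             "state_sequence", "labels must index the expansion offsets")
  stop_field(thermal_noise_sd >= 0, "thermal_noise_sd", "must be non-negative")
  structure(list(n_residues = as.integer(n_residues),
                 n_frames = as.integer(n_frames),
                 pocket_residue_indices = as.integer(pocket_residue_indices),
                 pocket_expansion_per_state = pocket_expansion_per_state,
                 state_sequence = as.integer(state_sequence),
                 thermal_noise_sd = thermal_noise_sd, seed = seed,
                 pocket_radius = pocket_radius, barrel_radius = barrel_radius,
                 barrel_rise = barrel_rise),
            class = "toy_trajectory_spec")
}

# evenly spread directions on a sphere (golden spiral)
golden_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Generate a toy barrel trajectory with a breathing pocket
#'
#' @param spec A [toy_trajectory_spec()].
#' @return A [trajectory()]; the spec and the per-frame state sequence are
#'   attached as attribute `"spec"`. The target (chromophore stand-in) is the
#'   residue with index `n_residues + 1`.
#' @export
generate_toy_trajectory <- function(spec) {
  stopifnot(inherits(spec, "toy_trajectory_spec"))
  n <- spec$n_residues
  pocket <- spec$pocket_residue_indices
  barrel <- setdiff(seq_len(n), pocket)

  base <- matrix(0, n + 1L, 3L)
  # barrel lattice: helical placement on a cylinder
  ang <- 2 * pi * (seq_along(barrel) - 1) / max(length(barrel), 1) * 3.5
  base[barrel, ] <- cbind(spec$barrel_radius * cos(ang),
                          spec$barrel_radius * sin(ang),
                          (seq_along(barrel) - 1) * spec$barrel_rise -
                            (length(barrel) - 1) * spec$barrel_rise / 2)
  # pocket shell around the central target
  dirs <- golden_sphere(length(pocket))
  base[pocket, ] <- dirs * spec$pocket_radius
  # target at the origin
  base[n + 1L, ] <- 0

  atoms <- data.frame(
    residue_index = seq_len(n + 1L),
    residue_name = c(rep("GLY", n), "CRO"),
    atom_name = "CA",
    element = "C")

  coords <- array(0, c(spec$n_frames, n + 1L, 3L))
  with_seed(spec$seed, {
    for (f in seq_len(spec$n_frames)) {
      xyz <- base
      off <- spec$pocket_expansion_per_state[spec$state_sequence[f]]
      if (off != 0) xyz[pocket, ] <- xyz[pocket, ] + dirs * off
      if (spec$thermal_noise_sd > 0)
        xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = spec$thermal_noise_sd),
                            nrow(xyz), 3L)
      coords[f, , ] <- xyz
    }
  })
  out <- trajectory(coords, atoms)
  attr(out, "spec") <- spec
  out
}

#' Write / read multi-frame XYZ trajectories
#'
#' Standard XYZ: per frame an atom count line, a comment line, then
#' `element x y z` rows. Residue metadata goes to a sidecar CSV
#' (`residue_index`, `residue_name`, `atom_name`, `element`).
#'
#' @param traj A [trajectory()].
#' @param path XYZ file path.
#' @param sidecar Sidecar CSV path (default: `path` with `.csv` appended).
#' @export
write_xyz_trajectory <- function(traj, path, sidecar = paste0(path, ".csv")) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  na <- dim(traj$coords)[2]
  for (f in seq_len(n_frames(traj))) {
    writeLines(c(as.character(na), sprintf("frame %d", f)), con)
    xyz <- traj$coords[f, , , drop = TRUE]
    writeLines(sprintf("%s %.6f %.6f %.6f", traj$atoms$element,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  utils::write.csv(traj$atoms, sidecar, row.names = FALSE)
  invisible(path)
}

#' @rdname write_xyz_trajectory
#' @export
read_xyz_trajectory <- function(path, sidecar = paste0(path, ".csv")) {
  lines <- readLines(path)
  na <- as.integer(lines[1])
  per <- na + 2L
  nf <- length(lines) %/% per
  coords <- array(0, c(nf, na, 3L))
  for (f in seq_len(nf)) {
    block <- lines[((f - 1L) * per + 3L):((f - 1L) * per + 2L + na)]
    m <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    coords[f, , ] <- matrix(as.numeric(m[, 2:4]), na, 3L)
  }
  atoms <- utils::read.csv(sidecar)
  trajectory(coords, atoms)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Thin wrapper over `bio3d::read.pdb(..., multi = TRUE)`.
#'
#' @param path PDB file path.
#' @return A [trajectory()].
#' @export
read_pdb_trajectory <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB trajectories requires the bio3d package")
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  na <- ncol(xyz) / 3L
  coords <- array(0, c(nrow(xyz), na, 3L))
  for (f in seq_len(nrow(xyz)))
    coords[f, , ] <- matrix(xyz[f, ], na, 3L, byrow = TRUE)
  atoms <- data.frame(residue_index = pdb$atom$resno,
                      residue_name = pdb$atom$resid,
                      atom_name = pdb$atom$elety,
                      element = ifelse(is.na(pdb$atom$elesy) | pdb$atom$elesy == "",
                                       substr(pdb$atom$elety, 1, 1),
                                       pdb$atom$elesy))
  trajectory(coords, atoms)
}
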