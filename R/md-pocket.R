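# Contact-frequency pocket definition, convex-hull volumetrics and related
# trajectory geometry.

#' Volume of the 3D convex hull of a point set
#'
#' Exact hull volume by supporting-plane enumeration: every plane through
#' three points having all other points on one side is a hull facet plane;
#' coplanar facets are merged, triangulated with the planar convex hull
#' (`grDevices::chull`), and the volume is accumulated as signed tetrahedra
#' against the centroid. O(n^3) in the number of points, intended for the
#' tens-of-points pocket scale.
#'
#' @param pts Numeric matrix, n x 3.
#' @param tol Relative degeneracy tolerance.
#' @return Volume (cubic input units). Attribute `"degenerate"` flags
#'   rank-deficient inputs (volume 0); attribute `"planes"` holds the outward
#'   supporting planes as a matrix `[nx ny nz offset]` with inside meaning
#'   `x . n <= offset`, usable for point-in-hull tests.
#' @examples
#' convex_hull_volume(rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1)))  # 1/6
#' @export
convex_hull_volume <- function(pts, tol = 1e-9) {
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 3)
  degenerate <- function() {
    out <- 0
    attr(out, "degenerate") <- TRUE
    attr(out, "planes") <- matrix(numeric(0), 0, 4)
    out
  }
  n <- nrow(pts)
  if (n < 4) return(degenerate())
  scale <- max(apply(pts, 2, function(v) diff(range(v))), 1e-300)
  eps <- tol * scale
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))$d
  if (sv[3] < 1e-7 * scale) return(degenerate())

  cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
  combs <- utils::combn(n, 3)
  keys <- character(0)
  planes <- list()
  for (j in seq_len(ncol(combs))) {
    a <- pts[combs[1, j], ]; b <- pts[combs[2, j], ]; cc <- pts[combs[3, j], ]
    nrm <- cross3(b - a, cc - a)
    nl <- sqrt(sum(nrm^2))
    if (nl < eps * scale) next
    nrm <- nrm / nl
    d <- drop(pts %*% nrm) - sum(nrm * a)
    if (max(d) <= eps) {
      # all points on/below: nrm is already outward
    } else if (min(d) >= -eps) {
      nrm <- -nrm
    } else next
    off <- sum(nrm * a)
    key <- paste(round(c(nrm, off / scale) * 1e6), collapse = ",")
    if (key %in% keys) next
    keys <- c(keys, key)
    planes[[length(planes) + 1L]] <- c(nrm, off)
  }
  if (length(planes) < 4) return(degenerate())
  P <- do.call(rbind, planes)

  vol <- 0
  for (j in seq_len(nrow(P))) {
    nrm <- P[j, 1:3]; off <- P[j, 4]
    on_plane <- which(abs(drop(pts %*% nrm) - off) <= 2 * eps)
    if (length(on_plane) < 3) next
    # orthonormal in-plane basis
    u <- if (abs(nrm[1]) < 0.9) cross3(nrm, c(1, 0, 0)) else cross3(nrm, c(0, 1, 0))
    u <- u / sqrt(sum(u^2))
    v <- cross3(nrm, u)
    sub <- pts[on_plane, , drop = FALSE]
    xy <- cbind(drop(sub %*% u), drop(sub %*% v))
    hull2 <- grDevices::chull(xy)             # clockwise in (u, v)
    verts <- sub[hull2, , drop = FALSE]
    # orient the polygon so its normal matches the outward normal
    e1 <- verts[2, ] - verts[1, ]
    e2 <- verts[3, ] - verts[1, ]
    if (sum(cross3(e1, e2) * nrm) < 0) verts <- verts[rev(seq_len(nrow(verts))), ]
    for (kk in 2:(nrow(verts) - 1)) {
      m <- rbind(verts[1, ] - ctr, verts[kk, ] - ctr, verts[kk + 1, ] - ctr)
      vol <- vol + det(m) / 6
    }
  }
  out <- abs(vol)
  attr(out, "degenerate") <- FALSE
  attr(out, "planes") <- P
  out
}

# TRUE where points x (m x 3) lie inside/on the hull given its planes
points_in_hull <- function(x, planes, eps = 1e-9) {
  if (nrow(planes) == 0) return(rep(FALSE, nrow(x)))
  inside <- rep(TRUE, nrow(x))
  for (j in seq_len(nrow(planes))) {
    inside <- inside & (drop(x %*% planes[j, 1:3]) <= planes[j, 4] + eps)
    if (!any(inside)) break
  }
  inside
}

#' Residue-residue contacts within a frame
#'
#' Two residues are in contact when *any* of their atoms lie within the
#' distance cutoff (strictly). `method = "celllist"` bins atoms into
#' cutoff-sized cells and only examines neighboring cells; it must agree
#' exactly with the brute-force all-pairs path.
#'
#' @param frame A frame from [get_frame()].
#' @param selection_a,selection_b Residue index vectors (non-empty).
#' @param cutoff Distance cutoff, Angstrom.
#' @param method `"bruteforce"` or `"celllist"`.
#' @param heavy_only Ignore hydrogens (element "H").
#' @return Data frame of contacting pairs: `res_a`, `res_b`, `min_dist`.
#' @export
residue_contacts <- function(frame, selection_a, selection_b, cutoff = 3.5,
                             method = c("bruteforce", "celllist"),
                             heavy_only = FALSE) {
  stopifnot(inherits(frame, "md_frame"))
  method <- match.arg(method)
  stop_field(length(selection_a) > 0 && length(selection_b) > 0,
             "selection", "selections must be non-empty")
  stop_field(cutoff > 0, "cutoff", "must be positive")
  at <- frame$atoms
  keep <- if (heavy_only) at$element != "H" else rep(TRUE, nrow(at))
  ia <- which(at$residue_index %in% selection_a & keep)
  ib <- which(at$residue_index %in% selection_b & keep)
  if (length(ia) == 0 || length(ib) == 0)
    return(data.frame(res_a = integer(), res_b = integer(), min_dist = numeric()))
  A <- frame$coords[ia, , drop = FALSE]
  B <- frame$coords[ib, , drop = FALSE]

  pair_min <- new.env(parent = emptyenv())
  note <- function(ra, rb, d2) {
    key <- paste(ra, rb)
    cur <- pair_min[[key]]
    if (is.null(cur) || d2 < cur) pair_min[[key]] <- d2
  }

  if (method == "bruteforce") {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    if (nrow(hit))
      for (r in seq_len(nrow(hit)))
        note(at$residue_index[ia[hit[r, 1]]], at$residue_index[ib[hit[r, 2]]],
             d2[hit[r, 1], hit[r, 2]])
  } else {
    all_idx <- c(ia, ib)
    origin <- apply(frame$coords[all_idx, , drop = FALSE], 2, min)
    cellA <- floor(sweep(A, 2, origin) / cutoff)
    cellB <- floor(sweep(B, 2, origin) / cutoff)
    keyB <- paste(cellB[, 1], cellB[, 2], cellB[, 3])
    buckets <- split(seq_len(nrow(B)), keyB)
    shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    for (i in seq_len(nrow(A))) {
      for (s in seq_len(nrow(shifts))) {
        key <- paste(cellA[i, 1] + shifts[s, 1], cellA[i, 2] + shifts[s, 2],
                     cellA[i, 3] + shifts[s, 3])
        js <- buckets[[key]]
        if (is.null(js)) next
        d2 <- colSums((t(B[js, , drop = FALSE]) - A[i, ])^2)
        ok <- which(d2 < cutoff^2)
        for (o in ok)
          note(at$residue_index[ia[i]], at$residue_index[ib[js[o]]], d2[o])
      }
    }
  }
  keys <- ls(pair_min)
  if (length(keys) == 0)
    return(data.frame(res_a = integer(), res_b = integer(), min_dist = numeric()))
  parts <- do.call(rbind, strsplit(keys, " "))
  out <- data.frame(res_a = as.integer(parts[, 1]),
                    res_b = as.integer(parts[, 2]),
                    min_dist = sqrt(vapply(keys, function(k) pair_min[[k]],
                                           numeric(1))))
  out <- out[order(out$res_a, out$res_b), ]
  rownames(out) <- NULL
  out
}

#' Define a fluorophore pocket from contact frequencies
#'
#' A residue belongs to the pocket when it contacts the target in more than
#' `freq_threshold` of all post-equilibration snapshots (pooled over replicas
#' by default; the published convention). The default threshold is 0.33%
#' of snapshots with a 3.5 Angstrom any-atom cutoff.
#'
#' @param ensemble A [trajectory_ensemble()] (already trimmed of
#'   equilibration frames).
#' @param target Target residue index (e.g. the chromophore residue).
#' @param cutoff Contact cutoff, Angstrom.
#' @param freq_threshold Contact-frequency threshold (fraction of snapshots;
#'   strict ">").
#' @param heavy_only Ignore hydrogens in the contact criterion.
#' @param per_replica Require the frequency rule in every replica separately
#'   instead of pooling snapshots.
#' @return A `pocket_definition`: `target`, `residues` (sorted indices),
#'   `cutoff`, `freq_threshold`, `frequencies` (named vector over candidate
#'   residues).
#' @export
define_pocket <- function(ensemble, target, cutoff = 3.5,
                          freq_threshold = 0.0033, heavy_only = FALSE,
                          per_replica = FALSE) {
  if (inherits(ensemble, "trajectory")) ensemble <- trajectory_ensemble(list(ensemble))
  stopifnot(inherits(ensemble, "ensemble"))
  all_res <- sort(unique(ensemble[[1]]$atoms$residue_index))
  if (!target %in% all_res) stop("target residue ", target, " not present")
  others <- setdiff(all_res, target)
  tally <- function(traj) {
    cnt <- stats::setNames(numeric(length(others)), others)
    for (f in seq_len(n_frames(traj))) {
      hits <- residue_contacts(get_frame(traj, f), others, target,
                               cutoff = cutoff, heavy_only = heavy_only)
      if (nrow(hits)) cnt[as.character(hits$res_a)] <-
          cnt[as.character(hits$res_a)] + 1
    }
    list(cnt = cnt, nf = n_frames(traj))
  }
  per <- lapply(ensemble, tally)
  if (per_replica) {
    keep_each <- vapply(per, function(p) p$cnt / p$nf > freq_threshold,
                        logical(length(others)))
    keep <- if (is.matrix(keep_each)) apply(keep_each, 1, all) else keep_each
    freq <- rowMeans(vapply(per, function(p) p$cnt / p$nf,
                            numeric(length(others))))
  } else {
    tot <- Reduce(`+`, lapply(per, `[[`, "cnt"))
    nf <- sum(vapply(per, `[[`, numeric(1), "nf"))
    freq <- tot / nf
    keep <- freq > freq_threshold
  }
  structure(list(target = target, residues = others[keep], cutoff = cutoff,
                 freq_threshold = freq_threshold, frequencies = freq),
            class = "pocket_definition")
}

#' @export
print.pocket_definition <- function(x, ...) {
  cat(sprintf("pocket of target residue %d: %d residues (cutoff %.2f A, freq > %.4g)\n",
              x$target, length(x$residues), x$cutoff, x$freq_threshold))
  invisible(x)
}

#' Convex-hull pocket volume of one frame
#'
#' The pocket volume is the convex-hull volume of the C-alpha atoms of the
#' pocket residues.
#'
#' @param frame A frame from [get_frame()].
#' @param pocket A [define_pocket()] result or a vector of residue indices.
#' @return Volume in cubic Angstrom (0 with attribute `"degenerate"` for
#'   rank-deficient point sets).
#' @export
pocket_volume <- function(frame, pocket) {
  stopifnot(inherits(frame, "md_frame"))
  res <- if (inherits(pocket, "pocket_definition")) pocket$residues else pocket
  idx <- which(frame$atoms$residue_index %in% res & frame$atoms$atom_name == "CA")
  convex_hull_volume(frame$coords[idx, , drop = FALSE])
}

#' Pocket volume distribution over an ensemble
#'
#' Per-frame convex-hull volumes per replica; the grand mean is the mean of
#' per-replica means and the uncertainty is the standard error of the mean
#' treating each replica trajectory as one independent observation.
#'
#' @param ensemble A [trajectory_ensemble()] (trimmed).
#' @param pocket A [define_pocket()] result or residue indices.
#' @return A `pocket_volume_distribution`: `volumes` (list per replica),
#'   `replica_means`, `grand_mean`, `sem` (`NA` for a single replica).
#' @export
pocket_volume_distribution <- function(ensemble, pocket) {
  if (inherits(ensemble, "trajectory")) ensemble <- trajectory_ensemble(list(ensemble))
  stopifnot(inherits(ensemble, "ensemble"))
  vols <- lapply(ensemble, function(traj)
    vapply(seq_len(n_frames(traj)),
           function(f) as.numeric(pocket_volume(get_frame(traj, f), pocket)),
           numeric(1)))
  rm_ <- vapply(vols, mean, numeric(1))
  structure(list(volumes = vols, replica_means = rm_,
                 grand_mean = mean(rm_),
                 sem = if (length(rm_) >= 2) stats::sd(rm_) / sqrt(length(rm_))
                       else NA_real_),
            class = "pocket_volume_distribution")
}

#' @export
print.pocket_volume_distribution <- function(x, ...) {
  cat(sprintf("pocket volume: %.2f A^3 (SEM %s over %d replicas)\n",
              x$grand_mean,
              if (is.na(x$sem)) "n/a" else sprintf("%.2f", x$sem),
              length(x$replica_means)))
  invisible(x)
}

#' Difference map of mean C-alpha distances between two ensembles
#'
#' \eqn{D[i,j] = \langle d_{ij}\rangle_A - \langle d_{ij}\rangle_B} over the
#' requested residues; positive entries mean larger separations in ensemble A.
#' Symmetric with a zero diagonal; `map(A, B) = -map(B, A)`.
#'
#' @param ensemble_a,ensemble_b Ensembles (or trajectories) resolving the
#'   same residues.
#' @param residues Residue indices to include.
#' @return Square matrix (Angstrom) with residue indices as dimnames.
#' @export
distance_difference_map <- function(ensemble_a, ensemble_b, residues) {
  mean_dist <- function(x) {
    if (inherits(x, "trajectory")) x <- trajectory_ensemble(list(x))
    acc <- NULL; nf <- 0
    for (traj in x) {
      idx <- vapply(residues, function(r) {
        w <- which(traj$atoms$residue_index == r & traj$atoms$atom_name == "CA")
        if (length(w) != 1L) stop("residue ", r, " has no unique CA atom")
        w
      }, integer(1))
      for (f in seq_len(n_frames(traj))) {
        d <- as.matrix(stats::dist(traj$coords[f, idx, , drop = TRUE]))
        acc <- if (is.null(acc)) d else acc + d
        nf <- nf + 1
      }
    }
    acc / nf
  }
  out <- mean_dist(ensemble_a) - mean_dist(ensemble_b)
  dimnames(out) <- list(residues, residues)
  out
}

#' Count hydrogen bonds in a frame
#'
#' A bond is counted when the donor-acceptor distance is below `dist_cutoff`
#' and the donor-hydrogen-acceptor angle (at the hydrogen) is at least
#' `angle_cutoff` degrees.
#'
#' @param frame A frame from [get_frame()].
#' @param donors,hydrogens Parallel atom-index vectors giving each
#'   covalent D-H pair.
#' @param acceptors Acceptor atom indices.
#' @param dist_cutoff Donor-acceptor cutoff, Angstrom.
#' @param angle_cutoff D-H...A angle cutoff, degrees (boundary inclusive).
#' @return Integer count; attribute `"bonds"` lists them.
#' @export
count_hydrogen_bonds <- function(frame, donors, hydrogens, acceptors,
                                 dist_cutoff = 3.5, angle_cutoff = 150) {
  stopifnot(inherits(frame, "md_frame"))
  if (length(donors) != length(hydrogens))
    stop("every hydrogen must be paired with its covalent donor")
  bonds <- list()
  for (i in seq_along(donors)) {
    D <- frame$coords[donors[i], ]
    H <- frame$coords[hydrogens[i], ]
    for (a in setdiff(acceptors, donors[i])) {
      A <- frame$coords[a, ]
      if (sqrt(sum((D - A)^2)) >= dist_cutoff) next
      v1 <- D - H; v2 <- A - H
      ang <- acos(pmin(pmax(sum(v1 * v2) /
                              (sqrt(sum(v1^2)) * sqrt(sum(v2^2))), -1), 1)) * 180 / pi
      if (ang >= angle_cutoff)
        bonds[[length(bonds) + 1L]] <- data.frame(donor = donors[i],
                                                  hydrogen = hydrogens[i],
                                                  acceptor = a, angle = ang)
    }
  }
  out <- length(bonds)
  attr(out, "bonds") <- if (out) do.call(rbind, bonds) else NULL
  out
}

# van der Waals radii (Angstrom) by element
vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

#' Shrake-Rupley solvent-accessible surface area
#'
#' Sphere-point accessibility: each atom is inflated by the probe radius and
#' covered with `n_points` evenly distributed test points; points falling
#' inside any neighboring inflated sphere are buried. Per-atom areas are
#' summed per residue.
#'
#' @param frame A frame from [get_frame()].
#' @param radii Named vector of van der Waals radii per element; defaults to
#'   a standard set (H, C, N, O, S, P).
#' @param probe Probe radius, Angstrom (water: 1.4).
#' @param n_points Test points per atom.
#' @return Named numeric vector: SASA (square Angstrom) per residue index.
#'   Attribute `"per_atom"` carries the per-atom values.
#' @export
sasa_shrake_rupley <- function(frame, radii = NULL, probe = 1.4,
                               n_points = 960) {
  stopifnot(inherits(frame, "md_frame"))
  if (is.null(radii)) radii <- vdw_radii
  el <- frame$atoms$element
  unknown <- setdiff(unique(el), names(radii))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  r <- radii[el] + probe
  xyz <- frame$coords
  n <- nrow(xyz)
  dirs <- golden_sphere(n_points)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (r + r[i])^2 & seq_len(n) != i)
    pts <- sweep(dirs * r[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      acc <- acc & (colSums((t(pts) - xyz[j, ])^2) >= r[j]^2)
      if (!any(acc)) break
    }
    per_atom[i] <- 4 * pi * r[i]^2 * mean(acc)
  }
  out <- tapply(per_atom, frame$atoms$residue_index, sum)
  out <- stats::setNames(as.numeric(out), names(out))
  attr(out, "per_atom") <- per_atom
  out
}
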