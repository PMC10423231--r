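make_traj <- function(coord_list, atoms) {
  coords <- array(0, c(length(coord_list), nrow(atoms), 3))
  for (f in seq_along(coord_list)) coords[f, , ] <- coord_list[[f]]
  trajectory(coords, atoms)
}

test_that("equilibration trimming drops the leading ceiling(fraction n) frames", {
  at <- data.frame(residue_index = 1, residue_name = "GLY",
                   atom_name = "CA", element = "C")
  tr100 <- make_traj(lapply(1:100, function(i) matrix(c(i, 0, 0), 1, 3)), at)
  expect_equal(dim(trim_equilibration(tr100, 0.25)$coords)[1], 75)
  expect_equal(trim_equilibration(tr100, 0.25)$coords[1, 1, 1], 26)
  expect_equal(dim(trim_equilibration(tr100, 0)$coords)[1], 100)
  tr5 <- make_traj(lapply(1:5, function(i) matrix(c(i, 0, 0), 1, 3)), at)
  expect_equal(dim(trim_equilibration(tr5, 0.25)$coords)[1], 3)  # ceiling(1.25) dropped
})

test_that("the any-atom contact criterion applies the 3.5 A cutoff strictly", {
  at <- data.frame(residue_index = c(1, 2), residue_name = "GLY",
                   atom_name = "CA", element = "C")
  near <- frame_from_coords(rbind(c(0, 0, 0), c(3.4, 0, 0)))
  far <- frame_from_coords(rbind(c(0, 0, 0), c(3.6, 0, 0)))
  expect_equal(nrow(residue_contacts(near, 1, 2)), 1)
  expect_equal(nrow(residue_contacts(far, 1, 2)), 0)
})

test_that("contacts are invariant under rigid transforms and match the cell list", {
  set.seed(15)
  xyz <- matrix(rnorm(500 * 3, sd = 8), 500, 3)
  fr <- frame_from_coords(xyz)
  bf <- residue_contacts(fr, 1:250, 251:500, method = "bruteforce")
  cl <- residue_contacts(fr, 1:250, 251:500, method = "celllist")
  expect_equal(bf, cl)
  fr2 <- frame_from_coords(random_rigid(xyz, seed = 2))
  bf2 <- residue_contacts(fr2, 1:250, 251:500)
  expect_equal(bf[c("res_a", "res_b")], bf2[c("res_a", "res_b")])
  expect_equal(bf$min_dist, bf2$min_dist, tolerance = 1e-9)
})

test_that("pocket membership follows the contact-frequency rule strictly", {
  # residue 1 fixed in contact; residue 2 in contact in exactly 1/1000 frames
  at <- data.frame(residue_index = 1:3, residue_name = c("GLY", "GLY", "CRO"),
                   atom_name = "CA", element = "C")
  frames <- lapply(1:1000, function(f) {
    rbind(c(2, 0, 0),
          if (f == 1) c(0, 2, 0) else c(0, 50, 0),
          c(0, 0, 0))
  })
  tr <- make_traj(frames, at)
  pk <- define_pocket(trajectory_ensemble(list(tr)), target = 3)
  expect_true(1 %in% pk$residues)     # 100% > 0.33%
  expect_false(2 %in% pk$residues)    # 0.1% fails the > 0.33% rule
  expect_equal(unname(pk$frequencies["2"]), 0.001)
  expect_error(define_pocket(trajectory_ensemble(list(tr)), target = 99),
               "not present")
})

test_that("convex hull volume matches analytic solids and hull properties", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(as.numeric(convex_hull_volume(tet)), 1 / 6, tolerance = 1e-12)
  cube <- as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2)))
  expect_equal(as.numeric(convex_hull_volume(cube)), 8, tolerance = 1e-12)
  # interior points never change the hull
  expect_equal(as.numeric(convex_hull_volume(rbind(cube, c(1, 1, 1),
                                                   c(0.3, 1.7, 0.2)))),
               8, tolerance = 1e-12)
  # adding an exterior point never decreases the volume
  expect_gt(as.numeric(convex_hull_volume(rbind(cube, c(4, 1, 1)))), 8)
  # rank-deficient input: volume 0 with the degeneracy flag
  flat <- cbind(matrix(rnorm(20), 10, 2), 0)
  v <- convex_hull_volume(flat)
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "degenerate"))
  # rigid-transform invariance
  set.seed(4)
  pts <- matrix(rnorm(60), 20, 3)
  expect_equal(as.numeric(convex_hull_volume(random_rigid(pts, 3))),
               as.numeric(convex_hull_volume(pts)), tolerance = 1e-9)
})

test_that("hull volume agrees with a Monte-Carlo inside-hull oracle", {
  set.seed(23)
  pts <- matrix(rnorm(150), 50, 3)
  v <- convex_hull_volume(pts)
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  m <- 2e5
  samp <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]),
                runif(m, lo[3], hi[3]))
  inside <- flimcrowd:::points_in_hull(samp, attr(v, "planes"))
  mc <- mean(inside) * prod(hi - lo)
  se <- sd(inside) * prod(hi - lo) / sqrt(m)
  expect_lt(abs(mc - as.numeric(v)), max(0.01 * as.numeric(v), 4 * se))
})

test_that("pocket volume distributions aggregate per replica with SEM", {
  spec1 <- toy_trajectory_spec(16, 12, c(2, 5, 8, 11, 14), seed = 1,
                               thermal_noise_sd = 0.05)
  reps <- lapply(1:3, function(s) {
    sp <- spec1; sp$seed <- s; generate_toy_trajectory(sp)
  })
  ens <- trajectory_ensemble(reps)
  pvd <- pocket_volume_distribution(ens, c(2, 5, 8, 11, 14))
  expect_equal(pvd$grand_mean, mean(pvd$replica_means))
  expect_equal(pvd$sem, sd(pvd$replica_means) / sqrt(3))
  # identical replicas -> SEM exactly 0
  same <- trajectory_ensemble(list(reps[[1]], reps[[1]]))
  expect_equal(pocket_volume_distribution(same, c(2, 5, 8, 11, 14))$sem, 0)
  # single replica -> SEM sentinel
  expect_true(is.na(pocket_volume_distribution(
    trajectory_ensemble(list(reps[[1]])), c(2, 5, 8, 11, 14))$sem))
})

test_that("expanded-state ensembles dominate compact ones in pocket volume", {
  pocket <- c(2, 5, 8, 11, 14)
  mk <- function(state, seed) {
    generate_toy_trajectory(toy_trajectory_spec(
      16, 20, pocket, pocket_expansion_per_state = c(0, 1),
      state_sequence = rep(state, 20), thermal_noise_sd = 0.08, seed = seed))
  }
  compact <- trajectory_ensemble(lapply(1:3, function(s) mk(1L, s)))
  expanded <- trajectory_ensemble(lapply(1:3, function(s) mk(2L, 10 + s)))
  vc <- pocket_volume_distribution(compact, pocket)
  ve <- pocket_volume_distribution(expanded, pocket)
  expect_gt(ve$grand_mean, vc$grand_mean)
  # distribution shift: even the smallest expanded frame beats the compact median
  expect_gt(min(unlist(ve$volumes)), median(unlist(vc$volumes)))
})

test_that("distance-difference maps are antisymmetric and sign expansion", {
  pocket <- c(2, 5, 8, 11, 14)
  a <- generate_toy_trajectory(toy_trajectory_spec(
    16, 8, pocket, pocket_expansion_per_state = 1,
    state_sequence = rep(1L, 8), seed = 1))
  b <- generate_toy_trajectory(toy_trajectory_spec(
    16, 8, pocket, pocket_expansion_per_state = 0,
    state_sequence = rep(1L, 8), seed = 1))
  same <- distance_difference_map(a, a, pocket)
  expect_true(all(same == 0))
  d_ab <- distance_difference_map(a, b, pocket)
  expect_equal(d_ab, -distance_difference_map(b, a, pocket))
  expect_true(all(diag(d_ab) == 0))
  offdiag <- d_ab[upper.tri(d_ab)]
  expect_true(all(offdiag > 0))   # uniform radial expansion separates all pairs
  expect_equal(d_ab, t(d_ab))
})

test_that("hydrogen bonds require both the distance and the angle cutoff", {
  at <- data.frame(residue_index = 1:3, residue_name = "X",
                   atom_name = c("N", "H", "O"), element = c("N", "H", "O"))
  mk <- function(acceptor) structure(list(
    coords = rbind(c(0, 0, 0), c(1, 0, 0), acceptor), atoms = at),
    class = "md_frame")
  # linear geometry at 2.9 A donor-acceptor: counted
  expect_equal(as.numeric(count_hydrogen_bonds(mk(c(2.9, 0, 0)), 1, 2, 3)), 1)
  # 3.6 A at 180 degrees: distance fails
  expect_equal(as.numeric(count_hydrogen_bonds(mk(c(3.6, 0, 0)), 1, 2, 3)), 0)
  # 2.9 A donor-acceptor but D-H...A angle of 120 degrees: angle fails
  ang <- 120 * pi / 180
  acc <- c(1, 0, 0) + 2.2 * c(cos(pi - ang), sin(pi - ang), 0)
  d_da <- sqrt(sum(acc^2))
  expect_lt(d_da, 3.5)
  expect_equal(as.numeric(count_hydrogen_bonds(mk(acc), 1, 2, 3)), 0)
  expect_error(count_hydrogen_bonds(mk(c(2.9, 0, 0)), 1, c(2, 3), 3), "paired")
})

test_that("Shrake-Rupley areas match analytic sphere geometry", {
  # isolated atom: 4 pi (r + probe)^2 within point-discretization error
  lone <- frame_from_coords(matrix(0, 1, 3))
  a <- sasa_shrake_rupley(lone)
  expect_lt(abs(a[["1"]] - 4 * pi * (1.7 + 1.4)^2) / (4 * pi * 3.1^2), 0.01)
  # fully buried atom: enclose in a tight shell of 26 neighbors
  shell <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) * 2.2
  fr <- frame_from_coords(rbind(c(0, 0, 0), shell[rowSums(shell^2) > 0, ]))
  buried <- sasa_shrake_rupley(fr)
  expect_lt(attr(buried, "per_atom")[1], 1)
  # two overlapping spheres vs the analytic spherical-cap formula
  d <- 3.0; R <- 1.7 + 1.4
  two <- frame_from_coords(rbind(c(0, 0, 0), c(d, 0, 0)))
  out <- sasa_shrake_rupley(two)
  h <- R - d / 2                      # equal radii: cap height on each sphere
  analytic <- 4 * pi * R^2 - 2 * pi * R * h
  expect_lt(abs(attr(out, "per_atom")[1] - analytic) / analytic, 0.02)
  expect_error(sasa_shrake_rupley(frame_from_coords(matrix(0, 1, 3),
                                                    element = "Xx")), "Xx")
})
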