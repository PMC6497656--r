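toy_traj <- function(n_res = 12, n_frames = 5, sigma = 0, seed = 1, ...) {
  s <- make_toy_structure(n_res, seed = seed)
  make_trajectory(s, n_frames = n_frames, noise_sigma = sigma, seed = seed, ...)
}

test_that("Kabsch superposition recovers exact rigid transforms", {
  set.seed(1)
  ref <- matrix(rnorm(30), 10, 3)
  fit0 <- kabsch_superpose(ref, ref)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit0$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)

  mob <- random_rigid(ref, seed = 2)
  fit <- kabsch_superpose(ref, mob)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_equal(fit$fitted, sweep(mob %*% t(fit$rotation), 2,
                                 fit$translation, "+"), tolerance = 1e-10)
})

test_that("Kabsch rejects degenerate inputs", {
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))   # perfectly collinear
  expect_error(kabsch_superpose(line, line + 1), "collinear")
  set.seed(3)
  ref <- matrix(rnorm(30), 10, 3)
  expect_error(kabsch_superpose(ref, ref, weights = rep(-1, 10)), "weights")
})

test_that("post-fit RMSD matches a numeric-minimization oracle on noisy pairs", {
  set.seed(7)
  for (r in 1:8) {
    ref <- matrix(rnorm(30, sd = 3), 10, 3)
    mob <- random_rigid(ref, seed = r) + matrix(rnorm(30, sd = 0.4), 10, 3)
    pre <- sqrt(mean(rowSums((mob - ref)^2)))
    fit <- kabsch_superpose(ref, mob)
    expect_lte(fit$rmsd, pre + 1e-12)
    expect_equal(fit$rmsd, rmsd_optim_oracle(ref, mob), tolerance = 1e-8)
  }
})

test_that("RMSD series is zero for static or rigidly moving trajectories", {
  tr <- toy_traj(sigma = 0, n_frames = 6)      # pure rigid motion
  r <- rmsd_series(tr, "backbone")
  expect_equal(r, rep(0, 6), tolerance = 1e-8)
  expect_equal(rmsd_series(tr, "calpha"), rep(0, 6), tolerance = 1e-8)
  expect_error(rmsd_series(tr, "backbone", reference_frame = 9),
               "out of range")
  expect_true(all(rmsd_series(toy_traj(sigma = 0.4, n_frames = 4)) >= 0))
})

test_that("two-atom displacement gives the closed-form RMSD after fitting", {
  # 3 atoms forming a triangle; one atom displaced in frame 2. The optimal
  # superposition is found numerically and must match kabsch exactly.
  s <- make_toy_structure(3, seed = 1, sequence = "GGG")
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  idx <- which(s$atoms$atom_name == "CA")
  f2 <- xyz; f2[idx[1], ] <- f2[idx[1], ] + c(1, 0, 0)
  tr <- new_trajectory(s, list(xyz, f2))
  got <- rmsd_series(tr, idx)[2]
  expect_equal(got * 10, rmsd_optim_oracle(xyz[idx, ], f2[idx, ]),
               tolerance = 1e-8)
})

test_that("radius of gyration matches closed forms and the direct formula", {
  # two equal-mass points 2 Angstrom apart: each 1 A from the COM -> 0.1 nm
  atoms <- data.frame(serial = 1:3, atom_name = c("CA", "CA", "CA"),
                      element = "C", chain_id = "A", res_name = "GLY",
                      res_seq = 1:3, ins = "", x = c(0, 2, 0), y = 0, z = 0,
                      occ = 1, is_hetero = FALSE, stringsAsFactors = FALSE)
  s <- pocketcons:::new_structure(atoms)
  tr <- new_trajectory(s, list(as.matrix(atoms[, c("x", "y", "z")])))
  expect_equal(rg_series(tr, selection = 1:2), 0.1)
  # all atoms coincident -> 0
  tr0 <- new_trajectory(s, list(matrix(5, 3, 3)))
  expect_equal(rg_series(tr0, selection = 1:3), 0)
  # regular hexagon of circumradius R: every vertex at distance R from the
  # centroid, so unweighted Rg = R
  R <- 4.2
  th <- 2 * pi * (0:5) / 6
  hexa <- data.frame(serial = 1:6, atom_name = "CA", element = "C",
                     chain_id = "A", res_name = "GLY", res_seq = 1:6,
                     ins = "", x = R * cos(th), y = R * sin(th), z = 0,
                     occ = 1, is_hetero = FALSE, stringsAsFactors = FALSE)
  sh <- pocketcons:::new_structure(hexa)
  trh <- new_trajectory(sh, list(as.matrix(hexa[, c("x", "y", "z")])))
  expect_equal(rg_series(trh, selection = 1:6, mass_weighted = FALSE),
               0.1 * R, tolerance = 1e-12)
  # random cloud against an independent direct evaluation, mass-weighted
  tr2 <- toy_traj(n_res = 25, n_frames = 3, sigma = 0.5, seed = 5)
  got <- rg_series(tr2, "heavy")
  at <- tr2$topology$atoms
  idx <- which(!at$is_hetero)
  m <- element_mass(at$element[idx])
  want <- vapply(tr2$frames, function(f) {
    x <- f[idx, ]
    com <- colSums(x * m) / sum(m)
    0.1 * sqrt(sum(m * rowSums(sweep(x, 2, com)^2)) / sum(m))
  }, 0)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("RMSF is zero for static trajectories and d for a two-state toggle", {
  s <- make_toy_structure(40, seed = 4)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  static <- new_trajectory(s, list(xyz, xyz, xyz))
  expect_equal(max(rmsf_per_residue(static, "backbone")), 0, tolerance = 1e-10)
  expect_error(rmsf_per_residue(new_trajectory(s, list(xyz)), "backbone"),
               "at least 2")
  # one residue's backbone toggling +/- d along x, equal occupancy
  d <- 0.8
  up <- xyz; dn <- xyz
  res20 <- which(s$atoms$res_seq == 20 & s$atoms$atom_name %in%
                   c("N", "CA", "C", "O"))
  up[res20, 1] <- up[res20, 1] + d
  dn[res20, 1] <- dn[res20, 1] - d
  tr <- new_trajectory(s, rep(list(up, dn), 10))
  f <- rmsf_per_residue(tr, "backbone")
  # the superposition fit absorbs a little of the motion (4 of 160 atoms
  # move), so allow a few percent below the ideal two-state value
  expect_equal(unname(f["A:20"]), 0.1 * d, tolerance = 0.05)
  expect_lt(max(f[names(f) != "A:20"]), 0.1 * d * 0.1)
})

test_that("hydrogen-bond occupancy counts criterion-satisfying frames", {
  atoms <- data.frame(serial = 1:2, atom_name = c("OG", "O1"),
                      element = c("O", "O"), chain_id = c("A", "L"),
                      res_name = c("SER", "TCD"), res_seq = c(1L, 1L),
                      ins = "", x = c(0, 3), y = 0, z = 0, occ = 1,
                      is_hetero = c(FALSE, TRUE), stringsAsFactors = FALSE)
  s <- pocketcons:::new_structure(atoms)
  near <- as.matrix(atoms[, c("x", "y", "z")])
  far <- near; far[2, 1] <- 6
  frames <- c(rep(list(near), 7), rep(list(far), 3))
  hb <- hbond_series(new_trajectory(s, frames), "A:1:OG", "L:1:O1")
  expect_equal(hb$count, c(rep(1L, 7), rep(0L, 3)))
  expect_equal(hb$occupancy$occupancy, 0.7)
  none <- hbond_series(new_trajectory(s, rep(list(far), 4)), "A:1:OG", "L:1:O1")
  expect_true(all(none$count == 0))
  expect_equal(nrow(none$occupancy), 0L)
})

test_that("mean smallest-distance matrices follow the convention and the oracle", {
  # two residues, closest atoms 5 A apart -> 0.5 nm entry
  atoms <- data.frame(serial = 1:4, atom_name = c("CA", "CB", "CA", "CB"),
                      element = "C", chain_id = "A", res_name = "ALA",
                      res_seq = c(1L, 1L, 2L, 2L), ins = "",
                      x = c(0, 1, 6, 9), y = 0, z = 0, occ = 1,
                      is_hetero = FALSE, stringsAsFactors = FALSE)
  s <- pocketcons:::new_structure(atoms)
  tr <- new_trajectory(s, list(as.matrix(atoms[, c("x", "y", "z")])))
  md <- mean_smallest_distance_matrix(tr)
  expect_equal(md$matrix["A:1", "A:2"], 0.5)
  expect_equal(diag(md$matrix), c(0, 0), ignore_attr = TRUE)
  # far-apart residues cap at the truncation distance
  atoms2 <- atoms; atoms2$x <- c(0, 1, 20, 21)
  tr2 <- new_trajectory(pocketcons:::new_structure(atoms2),
                        list(as.matrix(atoms2[, c("x", "y", "z")])))
  expect_equal(mean_smallest_distance_matrix(tr2)$matrix["A:1", "A:2"], 1.5)
  expect_equal(mean_smallest_distance_matrix(tr2, truncation = 5)$matrix[1, 2],
               1.9)
  # random toy trajectory equals the brute-force double-loop oracle
  tr3 <- toy_traj(n_res = 6, n_frames = 3, sigma = 0.4, seed = 6)
  md3 <- mean_smallest_distance_matrix(tr3)
  expect_equal(md3$matrix, mdmat_oracle(tr3), tolerance = 1e-12)
  expect_equal(md3$matrix, t(md3$matrix))
  expect_equal(md3$mean_offdiag,
               mean(md3$matrix[row(md3$matrix) != col(md3$matrix)]))
})

test_that("all trajectory metrics are invariant under a global rigid transform", {
  tr <- toy_traj(n_res = 10, n_frames = 4, sigma = 0.3, seed = 9)
  moved <- tr
  moved$frames <- lapply(tr$frames, random_rigid, seed = 42)
  expect_equal(rmsd_series(moved), rmsd_series(tr), tolerance = 1e-8)
  expect_equal(rg_series(moved), rg_series(tr), tolerance = 1e-10)
  expect_equal(rmsf_per_residue(moved), rmsf_per_residue(tr), tolerance = 1e-8)
  expect_equal(mean_smallest_distance_matrix(moved)$matrix,
               mean_smallest_distance_matrix(tr)$matrix, tolerance = 1e-10)
})

test_that("trajectories round-trip through multi-MODEL PDB files", {
  tr <- toy_traj(n_res = 5, n_frames = 3, sigma = 0.2, seed = 2)
  path <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(tr, path)
  back <- read_trajectory_pdb(path)
  expect_length(back$frames, 3)
  for (m in 1:3)
    expect_equal(back$frames[[m]], round(tr$frames[[m]], 3), tolerance = 1e-9)
  expect_equal(back$topology$atoms$atom_name, tr$topology$atoms$atom_name)
})
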