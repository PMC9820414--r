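test_that("superposition recovers rigid motions exactly", {
  set.seed(11)
  x <- matrix(rnorm(60, sd = 4), ncol = 3)
  expect_equal(kabsch_superpose(x, x)$rmsd, 0, tolerance = 1e-10)

  # 90 degree rotation about z plus translation
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  y <- x %*% Rz
  y <- sweep(y, 2, c(5, 0, 0), "+")
  fit <- kabsch_superpose(y, x)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(apply_transform(y, fit), x, tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  expect_equal(crossprod(fit$rotation), diag(3), tolerance = 1e-8)
})

test_that("superposition enforces proper rotations on mirror images", {
  # asymmetric 4-point set and its mirror: a reflection would fit
  # perfectly, a proper rotation cannot
  p <- matrix(c(0, 0, 0, 1, 0, 0, 0, 2, 0, 0, 0, 3), ncol = 3,
              byrow = TRUE)
  m <- p
  m[, 1] <- -m[, 1]
  fit <- kabsch_superpose(m, p)
  expect_gt(fit$rmsd, 0.1)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  expect_equal(fit$rmsd, quaternion_rmsd(m, p), tolerance = 1e-6)
})

test_that("superposition matches the quaternion oracle on random pairs", {
  set.seed(23)
  for (i in 1:25) {
    a <- matrix(rnorm(45, sd = 3), ncol = 3)
    b <- matrix(rnorm(45, sd = 3), ncol = 3)
    expect_equal(kabsch_superpose(a, b)$rmsd, quaternion_rmsd(a, b),
                 tolerance = 1e-6)
  }
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line + 1), "collinear|degenerate")
  expect_error(kabsch_superpose(matrix(rnorm(6), 2, 3),
                                matrix(rnorm(6), 2, 3)), "3 points")
})

test_that("rmsd series is zero for static or rigidly moved frames", {
  set.seed(5)
  top <- toy_topology(10)
  base <- helix_coords(10)
  coords <- array(rep(base, 4), dim = c(10, 3, 4))
  # frame 3: rigid rotation + translation of the whole selection
  rt <- random_rigid()
  coords[, , 3] <- sweep(base %*% rt$R, 2, rt$t, "+")
  traj <- trajectory(top, coords)
  s <- rmsd_series(traj, select_atoms(top, "name CA"))
  expect_equal(s$rmsd_A, rep(0, 4), tolerance = 1e-8)
  expect_identical(s$rmsd_A[1], 0)           # reference entry exactly 0
  expect_error(rmsd_series(traj, integer(0)), "empty")
})

test_that("rmsd series equals a brute-force per-frame fit", {
  set.seed(9)
  top <- toy_topology(10)
  base <- helix_coords(10)
  coords <- array(rep(base, 3), dim = c(10, 3, 3))
  coords[4, , 2] <- coords[4, , 2] + c(2, 0, 0)   # one displaced atom
  coords[, , 3] <- coords[, , 3] + rnorm(30, sd = 0.3)
  traj <- trajectory(top, coords)
  s <- rmsd_series(traj, select_atoms(top, "name CA"))
  for (f in 2:3) {
    expect_equal(s$rmsd_A[f], quaternion_rmsd(coords[, , f], base),
                 tolerance = 1e-8)
  }
})

test_that("rmsf of a static trajectory is zero and a single frame gives zeros", {
  top <- toy_topology(8)
  base <- helix_coords(8)
  traj <- trajectory(top, array(rep(base, 5), dim = c(8, 3, 5)))
  sel <- select_atoms(top, "name CA")
  expect_equal(rmsf_profile(traj, sel)$rmsf_A, rep(0, 8), tolerance = 1e-10)
  expect_equal(rmsf_profile(traj, sel, window = 2L)$rmsf_A, rep(0, 8))
  expect_error(rmsf_profile(traj, sel, window = integer(0)), "window")
})

test_that("rmsf calibrates to sigma*sqrt(3) under isotropic jitter", {
  set.seed(31)
  # enough atoms that the 6 rigid-body degrees of freedom removed by the
  # superposition do not bias per-atom fluctuations appreciably
  n_atoms <- 120
  n_frames <- 2000
  sigma <- 0.5
  base <- matrix(runif(n_atoms * 3, -20, 20), ncol = 3)
  coords <- array(rep(base, n_frames), dim = c(n_atoms, 3, n_frames)) +
    array(rnorm(n_atoms * 3 * n_frames, 0, sigma),
          dim = c(n_atoms, 3, n_frames))
  top <- toy_topology(n_atoms)
  prof <- rmsf_profile(trajectory(top, coords),
                       select_atoms(top, "name CA"))
  atom_rmsf <- attr(prof, "atom_rmsf")$rmsf_A
  expect_true(all(abs(atom_rmsf - sigma * sqrt(3)) / (sigma * sqrt(3))
                  < 0.05))
})

test_that("rmsf is invariant to a global rigid transform of all frames", {
  set.seed(13)
  sys <- small_system(frames = 20, replicas = 1)
  traj <- sys$dimer[[1]]
  sel <- select_atoms(traj, "name CA")
  base <- rmsf_profile(traj, sel)$rmsf_A
  rt <- random_rigid()
  moved <- traj
  for (f in seq_len(n_frames(traj))) {
    moved$coords[, , f] <- sweep(traj$coords[, , f] %*% rt$R, 2, rt$t, "+")
  }
  expect_equal(rmsf_profile(moved, sel)$rmsf_A, base, tolerance = 1e-8)
})

test_that("dimer building is a fixed point on the template's own chains", {
  sys <- small_system(frames = 10, replicas = 1)
  traj <- sys$dimer[[1]]
  prot <- select_atoms(traj, "chain A or chain B")
  template <- trajectory(topology(as.data.frame(traj$topology[prot, ])),
                         traj$coords[prot, , 1, drop = FALSE])
  split_chain <- function(ch) {
    idx <- select_atoms(template, paste("chain", ch))
    top <- as.data.frame(template$topology[idx, ])
    top$chain_id <- "X"
    trajectory(topology(top), template$coords[idx, , 1, drop = FALSE])
  }
  mapping <- list(A = data.frame(template_res = 1:10, monomer_res = 1:10),
                  B = data.frame(template_res = 1:10, monomer_res = 1:10))
  built <- build_dimer(template, split_chain("A"), split_chain("B"),
                       mapping)
  expect_equal(unname(built$fit_rmsd), c(0, 0), tolerance = 1e-8)
  expect_equal(built$structure$coords, template$coords, tolerance = 1e-8)

  # rigid invariance: pre-translated monomers give the same dimer
  shift <- function(t) { t$coords <- t$coords + 10; t }
  built2 <- build_dimer(template, shift(split_chain("A")),
                        shift(split_chain("B")), mapping)
  expect_equal(built2$structure$coords, built$structure$coords,
               tolerance = 1e-8)
})

test_that("dimer building counts planted clashes and validates mappings", {
  sys <- small_system(frames = 10, replicas = 1)
  traj <- sys$dimer[[1]]
  prot <- select_atoms(traj, "chain A or chain B")
  template <- trajectory(topology(as.data.frame(traj$topology[prot, ])),
                         traj$coords[prot, , 1, drop = FALSE])
  idx_a <- select_atoms(template, "chain A")
  mon_a_top <- as.data.frame(template$topology[idx_a, ])
  mon_a <- trajectory(topology(mon_a_top),
                      template$coords[idx_a, , 1, drop = FALSE])
  # plant one chain-A atom 1.5 A from a chain-B atom
  idx_b <- select_atoms(template, "chain B")
  mon_b_top <- as.data.frame(template$topology[idx_b, ])
  mon_b <- trajectory(topology(mon_b_top),
                      template$coords[idx_b, , 1, drop = FALSE])
  target <- mon_b$coords[1, , 1] + c(1.5, 0, 0)
  mon_a$coords[1, , 1] <- target
  # the planted atom is not a CA used in fitting, so the fit is untouched
  mapping <- list(A = data.frame(template_res = 2:10, monomer_res = 2:10),
                  B = data.frame(template_res = 1:10, monomer_res = 1:10))
  built <- build_dimer(template, mon_a, mon_b, mapping, clash_cutoff = 2.0)
  expect_gte(built$clash_count, 1)
  bad_map <- list(A = data.frame(template_res = 98:100, monomer_res = 98:100),
                  B = mapping$B)
  expect_error(build_dimer(template, mon_a, mon_b, bad_map), "missing")
})
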