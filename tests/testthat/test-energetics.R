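test_that("pair energies match closed forms", {
  model <- nonbonded_model()
  # pure Coulomb: k q1 q2 / r with k = 332.0636
  expect_equal(pair_energy(1, 1, 0, 0, 0, 0, r = 3.320636, model), 100,
               tolerance = 1e-10)
  # LJ minimum: -epsilon at r = 2^(1/6) sigma
  sig <- 3.4
  expect_equal(pair_energy(0, 0, sig, sig, 0.2, 0.2,
                           r = 2^(1 / 6) * sig, model), -0.2,
               tolerance = 1e-10)
  # hard cutoff zeroes both terms
  expect_identical(pair_energy(1, -1, 3, 3, 0.1, 0.1, r = 10, model), 0)
  expect_gt(abs(pair_energy(1, -1, 3, 3, 0.1, 0.1, r = 9, model)), 0)
  expect_error(pair_energy(1, 1, 0, 0, 0, 0, r = 0), "zero")
  # symmetry in arguments
  expect_equal(pair_energy(0.3, -0.7, 3.1, 3.9, 0.1, 0.3, 5),
               pair_energy(-0.7, 0.3, 3.9, 3.1, 0.3, 0.1, 5))
})

test_that("group energy equals the brute-force double loop", {
  set.seed(41)
  n <- 50
  top <- topology(data.frame(
    serial = 1:n, name = "X", element = "C", res_name = "ALA",
    res_seq = 1:n, chain_id = rep(c("A", "B"), each = n / 2),
    charge = runif(n, -0.5, 0.5), sigma = runif(n, 2.5, 4),
    epsilon = runif(n, 0.05, 0.3)))
  frame <- matrix(runif(n * 3, 0, 18), ncol = 3)
  sel_a <- 1:25
  sel_b <- 26:50
  model <- nonbonded_model()
  expect_equal(group_energy(frame, top, sel_a, sel_b, model),
               brute_group_energy(frame, top, sel_a, sel_b),
               tolerance = 1e-8)
  expect_equal(group_energy(frame, top, sel_a, sel_b, model),
               group_energy(frame, top, sel_b, sel_a, model),
               tolerance = 1e-12)
  # single-atom groups reduce to pair_energy
  r <- sqrt(sum((frame[1, ] - frame[30, ])^2))
  expect_equal(group_energy(frame, top, 1L, 30L, model),
               pair_energy(top$charge[1], top$charge[30], top$sigma[1],
                           top$sigma[30], top$epsilon[1], top$epsilon[30],
                           r, model))
  expect_error(group_energy(frame, top, 1:3, 3:5, model), "overlap")
})

test_that("internal energy applies the residue-separation exclusion", {
  model <- nonbonded_model()
  mk_top <- function(n_res) topology(data.frame(
    serial = seq_len(n_res), name = "CA", element = "C",
    res_name = "ALA", res_seq = seq_len(n_res), chain_id = "A",
    charge = 0.2, sigma = 3.2, epsilon = 0.1))
  # 2 residues, exclusion 2: no eligible pairs
  f2 <- rbind(c(0, 0, 0), c(3, 0, 0))
  expect_identical(internal_energy(f2, mk_top(2), 1:2, model), 0)
  # 3 residues: only the (1,3) pair is eligible
  f3 <- rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0))
  top3 <- mk_top(3)
  want <- pair_energy(0.2, 0.2, 3.2, 3.2, 0.1, 0.1, 6, model)
  expect_equal(internal_energy(f3, top3, 1:3, model), want,
               tolerance = 1e-12)
  # a rigid chain has constant internal energy across frames
  sys <- small_system(frames = 10, replicas = 1, jitter_sigma = 0,
                      interactions = list())
  traj <- sys$dimer[[1]]
  sel <- select_atoms(traj, "chain A")
  vals <- vapply(1:4, function(f) {
    internal_energy(traj$coords[, , f], traj$topology, sel, model)
  }, numeric(1))
  expect_equal(diff(range(vals)), 0, tolerance = 1e-10)
  expect_error(internal_energy(f3, sys$dimer[[1]]$topology,
                               select_atoms(traj, "chain A or chain B"),
                               model), "one chain")
})

test_that("component series agrees with the explicit pair-enumeration oracle", {
  sys <- small_system(frames = 10, replicas = 1, seed = 4)
  traj <- sys$dimer[[1]]
  fast <- components_series(traj)
  slow <- reference_components(traj)
  key <- function(d) paste(d$frame, d$chain, d$term, d$partner)
  m <- match(key(fast), key(slow))
  expect_false(anyNA(m))
  expect_equal(fast$energy, slow$energy[m], tolerance = 1e-8)
  # chain-chain rows are symmetric
  cc <- fast[fast$term == "chain", ]
  ab <- cc[cc$chain == "A", "energy"]
  ba <- cc[cc$chain == "B", "energy"]
  expect_equal(ab, ba, tolerance = 1e-12)
})

test_that("a system without waters reports zero chain-water energy", {
  sys <- small_system(frames = 10, replicas = 1, n_waters = 0, n_ions = 0)
  comp <- components_series(sys$dimer[[1]])
  expect_true(all(comp$energy[comp$term == "water"] == 0))
  expect_true(all(comp$energy[comp$term == "ions"] == 0))
})

test_that("two isolated opposite charges give the closed-form Coulomb energy", {
  top <- assign_groups(two_chain_top(c(
    list(atom_row("CA", "C", "ALA", 1, "A"),
         atom_row("CA", "C", "ALA", 1, "B")))))
  top$charge <- c(0.5, -0.5)
  traj <- trajectory(top, rbind(c(0, 0, 0), c(4, 0, 0)))
  comp <- components_series(traj)
  cc <- comp$energy[comp$term == "chain" & comp$chain == "A"]
  expect_equal(cc, 332.0636 * 0.5 * -0.5 / 4, tolerance = 1e-12)
})

test_that("formation energy ledger: null, chain-chain-only and shifted cases", {
  # identical components, zero chain-chain -> exactly 0
  fx <- formation_fixture(cc = 0)
  fe <- dimer_formation_energy(fx$dimer, fx$mono, fx$mono, window = 1)
  expect_identical(fe$mean, 0)
  expect_identical(unname(fe$per_replica), c(0, 0))
  # constant chain-chain -10, all else identical -> exactly -10
  fx <- formation_fixture(cc = -10)
  fe <- dimer_formation_energy(fx$dimer, fx$mono, fx$mono, window = 0.5)
  expect_equal(fe$mean, -10, tolerance = 1e-12)
  expect_true(fe$favorable)
  # chain-chain -5 plus a -3 membrane shift on chain A -> -8, using the
  # homodimer rule (single monomer counted twice)
  fx <- formation_fixture(cc = -5, mem_shift = -3)
  fe <- dimer_formation_energy(fx$dimer, fx$mono, mon_b = NULL, window = 1)
  expect_equal(fe$mean, -8, tolerance = 1e-12)
  # hand-summed ledger for the homodimer rule:
  # dimer total = (-2-3) + (-1) + 0.5 + 3 + (-2) + (-1) + 0.5 + 3 - 5 = -7
  # monomer total = -2 - 1 + 0.5 + 3 = 0.5, counted twice -> 1
  # formation = -7 - 1 = -8
  expect_equal(unname(fe$per_replica), c(-8, -8))
  # SEM definition: sample SD over replicas / sqrt(replicas)
  fx2 <- formation_fixture(cc = -5)
  fx2$dimer$energy[fx2$dimer$replica == 2 &
                     fx2$dimer$term == "chain"] <- -7
  fe2 <- dimer_formation_energy(fx2$dimer, fx2$mono, fx2$mono, window = 1)
  expect_equal(unname(fe2$per_replica), c(-5, -7))
  expect_equal(fe2$mean, -6)
  expect_equal(fe2$sem, sd(c(-5, -7)) / sqrt(2))
  # replica mismatch is a pairing error
  mono_bad <- fx$mono[fx$mono$replica == 1, ]
  expect_error(dimer_formation_energy(fx$dimer, mono_bad), "replica")
})

test_that("the energy window selects the trailing fraction of frames", {
  fx <- formation_fixture(cc = 0, n_frames = 4)
  # chain-chain = -20 in the first half, -10 in the second half
  cc_rows <- fx$dimer$term == "chain"
  fx$dimer$energy[cc_rows & fx$dimer$frame <= 2] <- -20
  fx$dimer$energy[cc_rows & fx$dimer$frame > 2] <- -10
  fe_half <- dimer_formation_energy(fx$dimer, fx$mono, fx$mono,
                                    window = 0.5)
  expect_equal(fe_half$mean, -10, tolerance = 1e-12)
  fe_all <- dimer_formation_energy(fx$dimer, fx$mono, fx$mono, window = 1)
  expect_equal(fe_all$mean, -15, tolerance = 1e-12)
})

test_that("a non-interacting dimer has formation energy within noise", {
  # chains ~25 A apart: every cross-chain pair lies beyond the cutoff,
  # and each monomer sees the same environment as its chain in the dimer
  sys <- generate_system(synthetic_spec(
    frames_per_replica = 60, replicas = 3, n_lipids = 40, n_waters = 60,
    n_ions = 6, chain_separation = 25, interactions = list(),
    conformers = data.frame(population = 1, displacement = 0),
    seed = 99))
  model <- nonbonded_model()
  dimer <- components_series(merge_replicas(sys$dimer), model)
  expect_true(all(dimer$energy[dimer$term == "chain"] == 0))
  mon_a <- components_series(merge_replicas(sys$monomers$A), model)
  mon_b <- components_series(merge_replicas(sys$monomers$B), model)
  fe <- dimer_formation_energy(dimer, mon_a, mon_b, window = 0.5)
  expect_lt(abs(fe$mean), 3 * fe$sem)
})

test_that("stronger planted interface charges strictly lower the formation energy", {
  vals <- vapply(c(0.1, 0.3, 0.5), function(q) {
    sys <- generate_system(synthetic_spec(
      frames_per_replica = 30, replicas = 2, n_lipids = 30, n_waters = 40,
      n_ions = 4, interface_charge = q, seed = 7))
    model <- nonbonded_model()
    dimer <- components_series(merge_replicas(sys$dimer), model)
    mon_a <- components_series(merge_replicas(sys$monomers$A), model)
    mon_b <- components_series(merge_replicas(sys$monomers$B), model)
    dimer_formation_energy(dimer, mon_a, mon_b, window = 0.5)$mean
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})
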