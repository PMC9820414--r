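# explicit hydrogen-bond geometry: donor N-H on chain A, acceptor O (with
# a C antecedent) on chain B, all positions controlled by the test
hbond_fixture <- function(d_ha = 2.0, donor_angle = 180,
                          acceptor_angle = 180) {
  top <- two_chain_top(c(
    list(atom_row("N", "N", "ALA", 1, "A"),
         atom_row("H", "H", "ALA", 1, "A"),
         atom_row("O", "O", "ALA", 1, "B"),
         atom_row("C", "C", "ALA", 1, "B"))))
  n <- c(0, 0, 0)
  h <- c(1.0, 0, 0)
  # acceptor placed so that angle(D-H...A) = donor_angle at distance d_ha
  th <- (180 - donor_angle) * pi / 180
  a <- h + d_ha * c(cos(th), sin(th), 0)
  # antecedent placed so that angle(H...A-C) = acceptor_angle
  u <- (h - a) / sqrt(sum((h - a)^2))
  ph <- (180 - acceptor_angle) * pi / 180
  v <- c(cos(ph) * -u[1] - sin(ph) * -u[2],
         sin(ph) * -u[1] + cos(ph) * -u[2], 0)
  cc <- a + 1.4 * v
  list(top = top, frame = rbind(n, h, a, cc))
}

test_that("hydrogen-bond detection honours distance and angle criteria", {
  f <- hbond_fixture(d_ha = 2.0, donor_angle = 180, acceptor_angle = 150)
  expect_equal(detect_hbonds_frame(f$frame, f$top),
               "hbond|A|1|N|B|1|O")
  # too long
  f2 <- hbond_fixture(d_ha = 3.5)
  expect_length(detect_hbonds_frame(f2$frame, f2$top), 0L)
  # bent donor angle
  f3 <- hbond_fixture(d_ha = 2.0, donor_angle = 90)
  expect_length(detect_hbonds_frame(f3$frame, f3$top), 0L)
  # acceptor angle below the minimum
  f4 <- hbond_fixture(d_ha = 2.0, donor_angle = 180, acceptor_angle = 45)
  expect_length(detect_hbonds_frame(f4$frame, f4$top), 0L)
})

test_that("hydrogen-free systems fall back to heavy-atom distance", {
  top <- two_chain_top(c(
    list(atom_row("OG", "O", "SER", 1, "A"),
         atom_row("OG1", "O", "THR", 1, "B"))))
  near <- rbind(c(0, 0, 0), c(3.0, 0, 0))
  far <- rbind(c(0, 0, 0), c(3.9, 0, 0))
  expect_equal(detect_hbonds_frame(near, top), "hbond|A|1|OG|B|1|OG1")
  expect_length(detect_hbonds_frame(far, top), 0L)
})

test_that("salt bridges pair opposite charges within the cutoff", {
  top <- two_chain_top(c(
    list(atom_row("NZ", "N", "LYS", 1, "A"),
         atom_row("OE1", "O", "GLU", 2, "B"),
         atom_row("NH1", "N", "ARG", 3, "B"))))
  frame <- rbind(c(0, 0, 0), c(3.5, 0, 0), c(2.0, 0, 0))
  keys <- detect_salt_bridges_frame(frame, top)
  # Lys(+)...Glu(-) at 3.5 A detected; Lys(+)...Arg(+) at 2 A is not
  expect_equal(keys, "salt_bridge|A|1|basic|B|2|acidic")
  far <- rbind(c(0, 0, 0), c(4.5, 0, 0), c(20, 0, 0))
  expect_length(detect_salt_bridges_frame(far, top), 0L)
  # formal-charge annotations stand in for templates on synthetic atoms
  top2 <- two_chain_top(c(
    list(atom_row("X1", "C", "ALA", 1, "A", formal_charge = 1),
         atom_row("X2", "C", "ALA", 1, "B", formal_charge = -1))))
  expect_length(detect_salt_bridges_frame(rbind(c(0, 0, 0), c(3, 0, 0)),
                                          top2), 1L)
})

test_that("ring interactions cover face-to-face, edge-to-face and cation-pi", {
  top <- two_chain_top(c(phe_rows(1, "A"), phe_rows(1, "B"),
                         list(atom_row("NZ", "N", "LYS", 2, "B"))))
  ring_a <- hexagon(c(0, 0, 0), c(0, 0, 1))
  # parallel rings 3.8 A apart -> face-to-face
  face <- rbind(ring_a, hexagon(c(0, 0, 3.8), c(0, 0, 1)), c(50, 50, 50))
  keys <- detect_ring_interactions_frame(face, top)
  expect_true("pi_pi|A|1|ring|B|1|ring" %in% keys)
  # perpendicular rings 5.0 A apart -> edge-to-face
  edge <- rbind(ring_a, hexagon(c(0, 0, 5.0), c(1, 0, 0)), c(50, 50, 50))
  expect_true("pi_pi|A|1|ring|B|1|ring" %in%
                detect_ring_interactions_frame(edge, top))
  # parallel but too far for face, not perpendicular enough for edge
  neither <- rbind(ring_a, hexagon(c(0, 0, 5.0), c(0, 0, 1)), c(50, 50, 50))
  expect_false(any(startsWith(detect_ring_interactions_frame(neither, top),
                              "pi_pi")))
  # cation 4 A above the ring centroid along the normal
  cat_on <- rbind(ring_a, hexagon(c(30, 0, 0), c(0, 0, 1)), c(0, 0, 4))
  expect_true("cation_pi|A|1|ring|B|2|NZ" %in%
                detect_ring_interactions_frame(cat_on, top))
  # cation in the ring plane, outside the cone
  cat_off <- rbind(ring_a, hexagon(c(30, 0, 0), c(0, 0, 1)), c(4, 0, 0))
  expect_false(any(startsWith(detect_ring_interactions_frame(cat_off, top),
                              "cation_pi")))
})

test_that("detection is symmetric in chain order and rigid-invariant", {
  set.seed(17)
  sys <- small_system(frames = 10, replicas = 1)
  traj <- sys$dimer[[1]]
  det <- detect_interactions(traj)
  rt <- random_rigid()
  moved <- traj
  for (f in seq_len(n_frames(traj))) {
    moved$coords[, , f] <- sweep(traj$coords[, , f] %*% rt$R, 2, rt$t, "+")
  }
  expect_identical(detect_interactions(moved), det)
  # relabel chains A<->B: canonical keys must be unchanged
  swapped <- traj
  tt <- as.data.frame(swapped$topology)
  tt$chain_id <- chartr("AB", "BA", tt$chain_id)
  ord <- order(match(tt$chain_id, unique(tt$chain_id)))
  # reorder atoms so residues stay contiguous after the relabel
  tt2 <- tt[ord, ]
  tt2$serial <- seq_len(nrow(tt2))
  swapped <- trajectory(assign_groups(topology(tt2)),
                        traj$coords[ord, , , drop = FALSE])
  # compare as unordered end-point sets after undoing the relabel
  norm <- function(keys) {
    sort(vapply(keys, function(k) {
      p <- strsplit(k, "|", fixed = TRUE)[[1]]
      ends <- sort(c(paste(p[2:4], collapse = ":"),
                     paste(p[5:7], collapse = ":")))
      paste(p[1], ends[1], ends[2])
    }, character(1), USE.NAMES = FALSE))
  }
  expect_identical(lapply(detect_interactions(swapped), function(k)
    norm(chartr("AB", "BA", k))),
    lapply(det, norm))
})

test_that("occupancies are recovered exactly and filtered at threshold", {
  sys <- small_system(frames = 50, replicas = 3)
  merged <- merge_replicas(sys$dimer)
  det <- detect_interactions(merged)
  tab <- occupancy_table(det, merged, equilibration_frames = 0,
                         threshold = 0.2)
  truth <- sys$ground_truth$interactions
  m <- match(truth$key, attr(tab, "keys"))
  expect_false(anyNA(m))
  expect_equal(tab$occ_merged[m], truth$occupancy)
  # per-replica occupancies are exact too (deterministic schedule)
  expect_equal(tab$occ_rep_1[m], truth$occupancy)
  expect_identical(tab$retained[m], truth$occupancy >= 0.2)
  # nothing but the planted interactions is detected
  expect_equal(nrow(tab), nrow(truth))
  # sorted by merged occupancy descending
  expect_true(all(diff(tab$occ_merged) <= 0))
})

test_that("occupancy bookkeeping: weighted-mean identity and monotone filter", {
  sys <- small_system(frames = 50, replicas = 3)
  merged <- merge_replicas(sys$dimer)
  det <- detect_interactions(merged)
  # unequal analysed lengths: drop 10 frames from replica 1 only
  keep <- setdiff(seq_len(n_frames(merged)), 1:10)
  sub <- trajectory(merged$topology,
                    merged$coords[, , keep, drop = FALSE],
                    frame_interval = merged$frame_interval,
                    frame_replica = merged$frame_replica[keep])
  tab <- occupancy_table(det[keep], sub, 0, 0.2)
  n_an <- attr(tab, "analyzed_frames")
  occ_cols <- paste0("occ_rep_", names(n_an))
  weighted <- as.matrix(tab[, occ_cols]) %*% n_an / sum(n_an)
  expect_equal(as.numeric(weighted), tab$occ_merged, tolerance = 1e-12)
  # lowering the threshold never removes a retained key
  lo <- occupancy_table(det[keep], sub, 0, 0.05)
  expect_true(all(attr(tab, "keys")[tab$retained] %in%
                    attr(lo, "keys")[lo$retained]))
  expect_true(sum(lo$retained) >= sum(tab$retained))
  # equilibration cannot consume a whole replica
  expect_error(occupancy_table(det, merged, 50, 0.2), "equilibration")
})

test_that("equilibration exclusion drops leading frames per replica", {
  sys <- small_system(frames = 50, replicas = 2)
  merged <- merge_replicas(sys$dimer)
  det <- detect_interactions(merged)
  tab <- occupancy_table(det, merged, equilibration_frames = 10,
                         threshold = 0.2)
  expect_equal(unname(attr(tab, "analyzed_frames")), c(40L, 40L))
  # the modular planting schedule is exact on whole decades, so
  # occupancies still equal the planted targets after exclusion
  truth <- sys$ground_truth$interactions
  m <- match(truth$key, attr(tab, "keys"))
  expect_equal(tab$occ_merged[m], truth$occupancy)
})

test_that("count series reproduces the planted schedule", {
  sys <- small_system(frames = 50, replicas = 2)
  merged <- merge_replicas(sys$dimer)
  det <- detect_interactions(merged)
  cs <- count_series(det, merged, kind = "hbond")
  expect_equal(nrow(cs), 100L)
  expect_equal(unique(cs$replica), 1:2)
  # planted hbonds at occupancies 1.0/0.3/0.1: deciles 0-9 carry counts
  # 3,2,2,1,1,1,1,1,1,1 by the mod-10 schedule
  decile <- (seq_len(50) - 1) %% 10
  expected <- 1 + (decile < 3) + (decile < 1)
  for (r in 1:2) {
    expect_equal(cs$count[cs$replica == r], expected)
  }
  expect_equal(cs$time_ps[cs$replica == 2],
               (seq_len(50) - 1) * merged$frame_interval)
})
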