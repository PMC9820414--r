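#' Specification of a synthetic dimer/monomer system
#'
#' Defines a toy two-chain membrane system with planted, exactly known
#' ground truth: two idealized helical mini-chains side by side in a
#' coarse lipid slab with scattered waters and ions, simulated as a base
#' conformation per planted conformer plus seeded Gaussian jitter.
#' Planted inter-chain interactions are realised by deterministically
#' toggling side-site geometry in exactly the scheduled frames (frame
#' index mod 10 < 10 x occupancy, 0-based within each replica), so
#' recovered occupancies equal the targets exactly. Conformers are
#' likewise assigned by the decile of the frame index, so planted
#' populations are exact on any whole number of decades.
#'
#' Defaults are the package's toy scale: 10 residues per chain, 4 sites
#' per residue, ~100 lipid particles, ~200 waters, ~10 ions, 500 frames
#' per replica, 3 replicas.
#'
#' @param residues_per_chain residues in each protein chain
#' @param frames_per_replica frames per replica (multiple of 10)
#' @param replicas number of replicas
#' @param frame_interval frame spacing, ps
#' @param jitter_sigma Gaussian jitter per coordinate, Angstrom
#' @param interactions list of planted interactions, each
#'   \code{list(kind, res_a, res_b, occupancy)} with kind \code{"hbond"}
#'   or \code{"salt_bridge"} and occupancy a multiple of 0.1
#' @param conformers data.frame \code{population, displacement}:
#'   populations (multiples of 0.1, summing to 1) and rigid displacement
#'   of chain B along the chain-separation axis per conformer, Angstrom
#'   (a displacement changes the inter-centroid distance, so no global
#'   superposition can absorb it and conformers stay separable by fitted
#'   RMSD)
#' @param n_lipids,n_waters,n_ions environment particle counts
#' @param chain_separation distance between the two chain axes, Angstrom
#' @param interface_charge partial charge (+/-) planted on hydrogen-bond
#'   side sites, elementary units
#' @param seed RNG seed driving all randomness
#' @return list of class \code{"synthetic_spec"}
#' @export
synthetic_spec <- function(residues_per_chain = 10L,
                           frames_per_replica = 500L,
                           replicas = 3L,
                           frame_interval = 100,
                           jitter_sigma = 0.1,
                           interactions = list(
                             list(kind = "hbond", res_a = 3L, res_b = 3L,
                                  occupancy = 1.0),
                             list(kind = "hbond", res_a = 5L, res_b = 5L,
                                  occupancy = 0.3),
                             list(kind = "hbond", res_a = 7L, res_b = 7L,
                                  occupancy = 0.1),
                             list(kind = "salt_bridge", res_a = 9L,
                                  res_b = 9L, occupancy = 0.5)),
                           conformers = data.frame(
                             population = c(0.6, 0.4),
                             displacement = c(0, 5)),
                           n_lipids = 100L, n_waters = 200L, n_ions = 10L,
                           chain_separation = 10,
                           interface_charge = 0.25,
                           seed = 42L) {
  spec <- as.list(environment())
  spec$interactions <- lapply(spec$interactions, function(p) {
    p$res_a <- as.integer(p$res_a)
    p$res_b <- as.integer(p$res_b)
    p
  })
  interactions <- spec$interactions
  if (frames_per_replica %% 10L != 0L) {
    stop("synthetic_spec(): frames_per_replica must be a multiple of 10 ",
         "for exact occupancy/population planting")
  }
  occ <- vapply(interactions, `[[`, numeric(1L), "occupancy")
  if (any(occ < 0 | occ > 1) ||
      any(abs(occ * 10 - round(occ * 10)) > 1e-9)) {
    stop("synthetic_spec(): occupancies must be multiples of 0.1 in [0, 1]")
  }
  pop <- conformers$population
  if (abs(sum(pop) - 1) > 1e-9 ||
      any(abs(pop * 10 - round(pop * 10)) > 1e-9)) {
    stop("synthetic_spec(): conformer populations must be multiples of ",
         "0.1 summing to 1")
  }
  res_planted <- c(vapply(interactions, `[[`, integer(1L), "res_a"),
                   vapply(interactions, `[[`, integer(1L), "res_b"))
  if (any(res_planted < 1L | res_planted > residues_per_chain)) {
    stop("synthetic_spec(): planted residue outside chain")
  }
  class(spec) <- "synthetic_spec"
  spec
}

# residue/atom naming of planted interaction end sites; the distinct
# residue names give each site its own (res_name, atom_name) parameter key
planted_site <- function(kind, chain) {
  if (kind == "hbond") {
    if (chain == "A") list(res_name = "SER", atom = "OG", element = "O",
                           formal = 0)
    else list(res_name = "THR", atom = "OG1", element = "O", formal = 0)
  } else if (kind == "salt_bridge") {
    if (chain == "A") list(res_name = "LYS", atom = "NZ", element = "N",
                           formal = 1)
    else list(res_name = "GLU", atom = "OE1", element = "O", formal = -1)
  } else {
    stop("planted interactions support kinds 'hbond' and 'salt_bridge'")
  }
}

# contact distances realising "on"/"off" frames: on satisfies the default
# criteria for its kind, off violates all of them
planted_distance <- function(kind, on) {
  if (kind == "hbond") {
    if (on) 3.0 else 7.0           # fallback D...A <= 3.5
  } else {
    if (on) 3.8 else 7.0           # salt bridge <= 4.0 but > 3.5 (no hbond)
  }
}

# base geometry: topology + base coordinates + planted site positions
synthetic_base <- function(spec) {
  R <- spec$residues_per_chain
  sep <- spec$chain_separation
  rise <- 1.5
  radius <- 2.3
  planted <- list()
  for (k in seq_along(spec$interactions)) {
    pi_k <- spec$interactions[[k]]
    planted[[k]] <- list(kind = pi_k$kind, res_a = pi_k$res_a,
                         res_b = pi_k$res_b, occupancy = pi_k$occupancy,
                         y = 2.5 * (k - mean(seq_along(spec$interactions))),
                         z = rise * (pi_k$res_a + pi_k$res_b) / 2)
  }
  build_chain <- function(chain, x0) {
    res_a_planted <- vapply(planted, `[[`, integer(1L),
                            if (chain == "A") "res_a" else "res_b")
    kinds <- vapply(planted, `[[`, character(1L), "kind")
    rows <- list()
    xyz <- list()
    for (i in seq_len(R)) {
      theta <- 100 * i * pi / 180
      ca <- c(x0 + radius * cos(theta), radius * sin(theta), rise * i)
      k <- match(i, res_a_planted)
      if (!is.na(k)) {
        site <- planted_site(kinds[k], chain)
        res_name <- site$res_name
        side <- list(name = site$atom, element = site$element,
                     formal = site$formal, planted = k)
      } else {
        res_name <- "ALA"
        side <- list(name = "CB", element = "C", formal = 0, planted = NA)
      }
      # backbone N, CA, C plus one side site
      atoms <- data.frame(
        name = c("N", "CA", "C", side$name),
        element = c("N", "C", "C", side$element),
        res_name = res_name, res_seq = i, chain_id = chain,
        formal_charge = c(0, 0, 0, side$formal),
        planted = c(NA, NA, NA, side$planted))
      # side site points radially away from the chain axis by default
      outward <- c(cos(theta), sin(theta), 0) *
        (if (chain == "A") 1 else -1)
      xyz[[i]] <- rbind(ca + c(0.6, 0.8, -0.9),
                        ca,
                        ca + c(-0.7, 0.9, 0.8),
                        ca + 1.5 * outward)
      rows[[i]] <- atoms
    }
    list(top = do.call(rbind, rows), xyz = do.call(rbind, xyz))
  }
  ca_z_mid <- rise * (R + 1) / 2
  cha <- build_chain("A", 0)
  chb <- build_chain("B", sep)
  # planted "off" side-site base positions (overridden per frame)
  prot_top <- rbind(cha$top, chb$top)
  prot_xyz <- rbind(cha$xyz, chb$xyz)
  for (k in seq_along(planted)) {
    p <- planted[[k]]
    off <- planted_distance(p$kind, FALSE)
    ia <- which(prot_top$chain_id == "A" & !is.na(prot_top$planted) &
                  prot_top$planted == k)
    ib <- which(prot_top$chain_id == "B" & !is.na(prot_top$planted) &
                  prot_top$planted == k)
    prot_xyz[ia, ] <- c(sep / 2 - off / 2, p$y, p$z)
    prot_xyz[ib, ] <- c(sep / 2 + off / 2, p$y, p$z)
    planted[[k]]$idx_a <- ia
    planted[[k]]$idx_b <- ib
  }

  # lipid slab: grid in the membrane plane, two leaflets, carved out
  # around the protein chains
  disp <- spec$conformers$displacement
  grid <- expand.grid(x = seq(-14, sep + 14 + max(disp, 0), by = 4),
                      y = seq(-14, 14, by = 4),
                      z = ca_z_mid + c(-3, 3))
  # keep lipids clear of the chains in every planted conformer placement
  ca_xy <- prot_xyz[prot_top$name == "CA", 1:2, drop = FALSE]
  b_ca <- prot_xyz[prot_top$name == "CA" & prot_top$chain_id == "B", 1:2,
                   drop = FALSE]
  for (d in disp[disp != 0]) {
    ca_xy <- rbind(ca_xy, sweep(b_ca, 2L, c(d, 0), "+"))
  }
  keep <- apply(grid[, 1:2], 1L, function(p) {
    min(sqrt((ca_xy[, 1] - p[1])^2 + (ca_xy[, 2] - p[2])^2)) > 7
  })
  grid <- grid[keep, , drop = FALSE]
  n_lip <- min(spec$n_lipids, nrow(grid))
  lip_xyz <- as.matrix(grid[seq_len(n_lip), , drop = FALSE])
  lip_top <- data.frame(name = "C1", element = "C", res_name = "POPC",
                        res_seq = seq_len(n_lip), chain_id = "M",
                        formal_charge = 0, planted = NA)
  list(prot_top = prot_top, prot_xyz = prot_xyz,
       lip_top = lip_top, lip_xyz = lip_xyz,
       planted = planted, z_mid = ca_z_mid, sep = sep)
}

# seeded placement of waters and ions in two slabs above and below the
# membrane, kept clear of existing atoms
scatter_solvent <- function(spec, base) {
  n <- spec$n_waters + spec$n_ions
  sep <- base$sep
  placed <- matrix(NA_real_, nrow = n, ncol = 3L)
  # avoid the protein in every conformer placement, not just the base one
  b_rows <- base$prot_top$chain_id == "B"
  shifted <- lapply(spec$conformers$displacement[
    spec$conformers$displacement != 0], function(d) {
      sweep(base$prot_xyz[b_rows, , drop = FALSE], 2L, c(d, 0, 0), "+")
    })
  existing <- do.call(rbind, c(list(base$prot_xyz, base$lip_xyz), shifted))
  count <- 0L
  while (count < n) {
    cand <- c(stats::runif(1, -14, sep + 14), stats::runif(1, -14, 14),
              base$z_mid + sample(c(-1, 1), 1L) * stats::runif(1, 7, 16))
    d2 <- min((existing[, 1] - cand[1])^2 + (existing[, 2] - cand[2])^2 +
                (existing[, 3] - cand[3])^2)
    if (d2 > 2.8^2) {
      count <- count + 1L
      placed[count, ] <- cand
      existing <- rbind(existing, cand)
    }
  }
  nw <- spec$n_waters
  wat_xyz <- placed[seq_len(nw), , drop = FALSE]
  wat_top <- data.frame(name = rep("O", nw), element = rep("O", nw),
                        res_name = rep("HOH", nw),
                        res_seq = seq_len(nw), chain_id = rep("W", nw),
                        formal_charge = rep(0, nw), planted = rep(NA, nw))
  ion_xyz <- placed[spec$n_waters + seq_len(spec$n_ions), , drop = FALSE]
  ion_name <- rep(c("NA", "CL"), length.out = spec$n_ions)
  ion_top <- data.frame(name = ion_name, element = ion_name,
                        res_name = ion_name,
                        res_seq = seq_len(spec$n_ions),
                        chain_id = rep("I", spec$n_ions),
                        formal_charge = rep(0, spec$n_ions),
                        planted = rep(NA, spec$n_ions))
  list(wat_top = wat_top, wat_xyz = wat_xyz,
       ion_top = ion_top, ion_xyz = ion_xyz)
}

# nonbonded parameter table covering every (res_name, atom_name) present
synthetic_params <- function(spec) {
  q <- spec$interface_charge
  rows <- list(
    c("ALA", "N", -0.30, 3.30, 0.12), c("ALA", "CA", 0.00, 3.50, 0.10),
    c("ALA", "C", 0.30, 3.40, 0.10), c("ALA", "CB", 0.00, 3.60, 0.10),
    c("SER", "N", -0.30, 3.30, 0.12), c("SER", "CA", 0.00, 3.50, 0.10),
    c("SER", "C", 0.30, 3.40, 0.10), c("SER", "OG", q, 3.20, 0.15),
    c("THR", "N", -0.30, 3.30, 0.12), c("THR", "CA", 0.00, 3.50, 0.10),
    c("THR", "C", 0.30, 3.40, 0.10), c("THR", "OG1", -q, 3.20, 0.15),
    c("LYS", "N", -0.30, 3.30, 0.12), c("LYS", "CA", 0.00, 3.50, 0.10),
    c("LYS", "C", 0.30, 3.40, 0.10), c("LYS", "NZ", 1.00, 3.25, 0.17),
    c("GLU", "N", -0.30, 3.30, 0.12), c("GLU", "CA", 0.00, 3.50, 0.10),
    c("GLU", "C", 0.30, 3.40, 0.10), c("GLU", "OE1", -1.00, 3.00, 0.21),
    c("POPC", "C1", 0.00, 4.00, 0.15),
    c("HOH", "O", 0.00, 3.15, 0.15),
    c("NA", "NA", 1.00, 2.73, 0.10),
    c("CL", "CL", -1.00, 4.40, 0.10))
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("res_name", "atom_name", "charge", "sigma", "epsilon")
  df$charge <- as.numeric(df$charge)
  df$sigma <- as.numeric(df$sigma)
  df$epsilon <- as.numeric(df$epsilon)
  df
}

#' Generate a synthetic dimer system with planted ground truth
#'
#' Builds the dimer system and the two monomer systems (each protein chain
#' re-simulated alone in an identical environment), emitting everything
#' the analysis pipeline consumes — trajectories with groups and
#' nonbonded parameters assigned, the parameter table, a toy helix
#' annotation, and the exact ground truth (planted occupancies, per-frame
#' conformer assignments, planted interaction keys).
#'
#' All randomness derives from \code{spec$seed}; the same spec generates
#' bitwise-identical output.
#'
#' @param spec a \code{\link{synthetic_spec}}
#' @return list with elements \code{dimer} (list of per-replica
#'   trajectories), \code{monomers} (\code{$A}, \code{$B}: lists of
#'   per-replica trajectories), \code{params}, \code{annotation},
#'   \code{ground_truth}, \code{spec}
#' @export
generate_system <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  base <- synthetic_base(spec)
  solvent <- scatter_solvent(spec, base)

  full_top_df <- rbind(base$prot_top, base$lip_top, solvent$wat_top,
                       solvent$ion_top)
  full_xyz <- rbind(base$prot_xyz, base$lip_xyz, solvent$wat_xyz,
                    solvent$ion_xyz)
  params <- synthetic_params(spec)

  make_topology <- function(df) {
    df$serial <- seq_len(nrow(df))
    top <- topology(df[, c("serial", "name", "element", "res_name",
                           "res_seq", "chain_id", "formal_charge")])
    top <- assign_groups(top)
    assign_parameters(top, params)
  }

  nf <- spec$frames_per_replica
  decile <- (seq_len(nf) - 1L) %% 10L
  conf_id <- findInterval(decile,
                          cumsum(round(10 * spec$conformers$population)),
                          left.open = FALSE) + 1L
  on_schedule <- lapply(base$planted, function(p) {
    decile < round(10 * p$occupancy)
  })

  # frames for one system: rows 'sel' of the full system, with chain B
  # displaced per conformer and planted sites toggled
  gen_replica <- function(sel, with_b_conformers, planted_active,
                          replica_id) {
    n_at <- length(sel)
    xyz0 <- full_xyz[sel, , drop = FALSE]
    chain_b_rows <- which(full_top_df$chain_id[sel] == "B" &
                            is.na(full_top_df$planted[sel]))
    coords <- array(NA_real_, dim = c(n_at, 3L, nf))
    for (f in seq_len(nf)) {
      x <- xyz0 + matrix(stats::rnorm(3L * n_at, 0, spec$jitter_sigma),
                         ncol = 3L)
      if (with_b_conformers && length(chain_b_rows) > 0L) {
        x[chain_b_rows, 1L] <- x[chain_b_rows, 1L] +
          spec$conformers$displacement[conf_id[f]]
      }
      for (k in seq_along(base$planted)) {
        p <- base$planted[[k]]
        on <- planted_active && on_schedule[[k]][f]
        d <- planted_distance(p$kind, on)
        pos_a <- c(base$sep / 2 - d / 2, p$y, p$z)
        pos_b <- c(base$sep / 2 + d / 2, p$y, p$z)
        ia <- match(p$idx_a, sel)
        ib <- match(p$idx_b, sel)
        if (!is.na(ia)) x[ia, ] <- pos_a
        if (!is.na(ib)) x[ib, ] <- pos_b
      }
      coords[, , f] <- x
    }
    coords
  }

  prot_rows <- seq_len(nrow(base$prot_top))
  env_rows <- nrow(base$prot_top) + seq_len(nrow(full_top_df) -
                                              nrow(base$prot_top))
  sel_dimer <- seq_len(nrow(full_top_df))
  sel_a <- c(prot_rows[base$prot_top$chain_id == "A"], env_rows)
  sel_b <- c(prot_rows[base$prot_top$chain_id == "B"], env_rows)

  top_dimer <- make_topology(full_top_df[sel_dimer, , drop = FALSE])
  top_a <- make_topology(full_top_df[sel_a, , drop = FALSE])
  top_b <- make_topology(full_top_df[sel_b, , drop = FALSE])

  dimer <- lapply(seq_len(spec$replicas), function(r) {
    trajectory(top_dimer,
               gen_replica(sel_dimer, TRUE, TRUE, r),
               frame_interval = spec$frame_interval, replica_id = r)
  })
  mon_a <- lapply(seq_len(spec$replicas), function(r) {
    trajectory(top_a, gen_replica(sel_a, FALSE, FALSE, r),
               frame_interval = spec$frame_interval, replica_id = r)
  })
  mon_b <- lapply(seq_len(spec$replicas), function(r) {
    trajectory(top_b, gen_replica(sel_b, FALSE, FALSE, r),
               frame_interval = spec$frame_interval, replica_id = r)
  })

  planted_keys <- vapply(base$planted, function(p) {
    sa <- planted_site(p$kind, "A")
    sb <- planted_site(p$kind, "B")
    if (p$kind == "salt_bridge") {
      make_keys("salt_bridge", "A", p$res_a, "basic", "B", p$res_b,
                "acidic")
    } else {
      make_keys("hbond", "A", p$res_a, sa$atom, "B", p$res_b, sb$atom)
    }
  }, character(1L))

  ground_truth <- list(
    interactions = data.frame(
      kind = vapply(base$planted, `[[`, character(1L), "kind"),
      res_a = vapply(base$planted, `[[`, integer(1L), "res_a"),
      res_b = vapply(base$planted, `[[`, integer(1L), "res_b"),
      occupancy = vapply(base$planted, `[[`, numeric(1L), "occupancy"),
      key = planted_keys),
    conformer_id = conf_id,
    conformer_population = spec$conformers$population,
    seed = spec$seed)

  annotation <- list(
    A = helix_annotation(data.frame(
      segment = c("TM3", "ICL2"),
      start = c(1L, 6L), end = c(5L, 10L), anchor = c(3L, 7L))),
    B = helix_annotation(data.frame(
      segment = c("TM3", "ICL2"),
      start = c(1L, 6L), end = c(5L, 10L), anchor = c(3L, 7L))))

  list(dimer = dimer, monomers = list(A = mon_a, B = mon_b),
       params = params, annotation = annotation,
       ground_truth = ground_truth, spec = spec)
}

#' Write a generated system to disk
#'
#' Emits one multi-model PDB per system and replica
#' (\code{dimer_rep<r>.pdb}, \code{monomer_A_rep<r>.pdb},
#' \code{monomer_B_rep<r>.pdb}), the nonbonded parameter CSV, the helix
#' annotation YAML and the ground-truth JSON, all plain text.
#'
#' @param sys result of \code{\link{generate_system}}
#' @param dir output directory (created if needed)
#' @return invisibly, the list of written file paths
#' @export
write_synthetic_system <- function(sys, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(trajs, stem) {
    for (r in seq_along(trajs)) {
      p <- file.path(dir, sprintf("%s_rep%d.pdb", stem, r))
      write_pdb(trajs[[r]], file = p)
      paths <<- c(paths, p)
    }
  }
  emit(sys$dimer, "dimer")
  emit(sys$monomers$A, "monomer_A")
  emit(sys$monomers$B, "monomer_B")
  p <- file.path(dir, "params.csv")
  utils::write.csv(sys$params, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "annotation.yaml")
  yaml::write_yaml(lapply(sys$annotation, function(a) {
    lapply(seq_len(nrow(a)), function(i) {
      list(segment = a$segment[i], start = a$start[i], end = a$end[i],
           anchor = a$anchor[i])
    })
  }), p)
  paths <- c(paths, p)
  p <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(sys$ground_truth, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}

#' Reference energy components by explicit pair enumeration
#'
#' An independent oracle for \code{\link{components_series}}: the same
#' energy decomposition computed by a plain double loop over all atom
#' pairs, classifying each pair by group, with no vectorisation or
#' neighbour acceleration. Quadratic in atoms and intended for small
#' systems and few frames.
#'
#' @param traj a \code{\link{trajectory}} with groups and parameters
#' @param model a \code{\link{nonbonded_model}}
#' @param exclusion internal-energy residue separation (default 2)
#' @return data.frame in the \code{\link{components_series}} layout
#' @export
reference_components <- function(traj, model = nonbonded_model(),
                                 exclusion = 2L) {
  top <- traj$topology
  chains <- protein_chains(top)
  terms <- c("membrane", "water", "ions", "internal")
  nf <- n_frames(traj)
  out <- list()
  group_of <- top$group
  group_of[group_of == "ion"] <- "ions"
  for (f in seq_len(nf)) {
    acc <- list()
    key <- function(chain, term, partner) paste(chain, term, partner)
    add <- function(chain, term, partner, e) {
      k <- key(chain, term, partner)
      acc[[k]] <<- (if (is.null(acc[[k]])) 0 else acc[[k]]) + e
    }
    for (ch in chains) for (term in terms) {
      partner <- if (term == "internal") ch else term
      add(ch, term, partner, 0)
    }
    if (length(chains) > 1L) {
      cmb <- utils::combn(chains, 2L)
      for (p in seq_len(ncol(cmb))) {
        add(cmb[1L, p], "chain", cmb[2L, p], 0)
        add(cmb[2L, p], "chain", cmb[1L, p], 0)
      }
    }
    xyz <- traj$coords[, , f, drop = TRUE]
    n <- nrow(top)
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        gi <- group_of[i]
        gj <- group_of[j]
        pi_ <- startsWith(gi, "protein:")
        pj <- startsWith(gj, "protein:")
        if (!pi_ && !pj) next
        r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        if (r > model$cutoff) next
        e <- pair_energy(top$charge[i], top$charge[j],
                         top$sigma[i], top$sigma[j],
                         top$epsilon[i], top$epsilon[j], r, model)
        ci <- sub("^protein:", "", gi)
        cj <- sub("^protein:", "", gj)
        if (pi_ && pj) {
          if (ci == cj) {
            if (abs(top$res_seq[i] - top$res_seq[j]) >= exclusion) {
              add(ci, "internal", ci, e)
            }
          } else {
            add(ci, "chain", cj, e)
            add(cj, "chain", ci, e)
          }
        } else if (pi_) {
          add(ci, gj, gj, e)
        } else {
          add(cj, gi, gi, e)
        }
      }
    }
    keys <- names(acc)
    parts <- do.call(rbind, strsplit(keys, " "))
    out[[f]] <- data.frame(frame = f,
                           time_ps = (f - 1L) * traj$frame_interval,
                           replica = traj$frame_replica[f],
                           chain = parts[, 1L], term = parts[, 2L],
                           partner = parts[, 3L],
                           energy = unlist(acc, use.names = FALSE))
  }
  do.call(rbind, out)
}
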