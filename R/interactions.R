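#' Geometric criteria for interface interaction detection
#'
#' The underlying simulations name the interaction classes (hydrogen bonds,
#' salt bridges, pi-pi, cation-pi) without geometric definitions; the
#' defaults here follow common Maestro-style criteria and are all
#' configurable.
#'
#' @param hbond_ha_max max H...acceptor distance, Angstrom
#' @param hbond_donor_angle_min min donor angle D-H...A, degrees
#' @param hbond_acceptor_angle_min min acceptor angle H...A-antecedent,
#'   degrees
#' @param hbond_da_max heavy-atom fallback donor...acceptor distance,
#'   Angstrom (used when the system carries no hydrogens)
#' @param salt_bridge_max max charged-atom distance, Angstrom
#' @param pipi_face_max,pipi_face_angle_max face-to-face branch: max
#'   centroid distance (Angstrom) and max interplanar angle (degrees)
#' @param pipi_edge_max,pipi_edge_angle_min edge-to-face branch: max
#'   centroid distance and min interplanar angle
#' @param catpi_max,catpi_angle_max max cation-centroid distance and max
#'   angle from the ring normal
#' @param his_protonated treat histidine ND1/NE2 as positively charged
#' @return list of criteria (class \code{"geometric_criteria"})
#' @export
geometric_criteria <- function(hbond_ha_max = 2.8,
                               hbond_donor_angle_min = 120,
                               hbond_acceptor_angle_min = 90,
                               hbond_da_max = 3.5,
                               salt_bridge_max = 4.0,
                               pipi_face_max = 4.4,
                               pipi_face_angle_max = 30,
                               pipi_edge_max = 5.5,
                               pipi_edge_angle_min = 60,
                               catpi_max = 6.0,
                               catpi_angle_max = 45,
                               his_protonated = FALSE) {
  crit <- as.list(environment())
  dists <- unlist(crit[c("hbond_ha_max", "hbond_da_max", "salt_bridge_max",
                         "pipi_face_max", "pipi_edge_max", "catpi_max")])
  if (any(dists <= 0)) stop("geometric_criteria(): distances must be > 0")
  angs <- unlist(crit[c("hbond_donor_angle_min", "hbond_acceptor_angle_min",
                        "pipi_face_angle_max", "pipi_edge_angle_min",
                        "catpi_angle_max")])
  if (any(angs < 0 | angs > 180)) {
    stop("geometric_criteria(): angles must lie in [0, 180]")
  }
  class(crit) <- "geometric_criteria"
  crit
}

# ---- internal site derivation -----------------------------------------

# protein atom mask: assigned groups when available, residue names otherwise
protein_mask <- function(top) {
  if (!anyNA(top$group)) {
    startsWith(top$group, "protein:")
  } else {
    top$res_name %in% standard_amino_acids()
  }
}

is_hydrogen <- function(top) {
  top$element == "H" | (top$element == "" & grepl("^[0-9]*H", top$name))
}

# positively / negatively charged side-chain atoms, from residue templates
# or from nonzero formal-charge annotations (synthetic systems)
charged_sites <- function(top, crit, sign) {
  prot <- protein_mask(top)
  if (sign > 0) {
    tmpl <- (top$res_name == "ARG" & top$name %in% c("NE", "NH1", "NH2")) |
      (top$res_name == "LYS" & top$name == "NZ")
    if (isTRUE(crit$his_protonated)) {
      tmpl <- tmpl | (top$res_name == "HIS" & top$name %in% c("ND1", "NE2"))
    }
    which(prot & (tmpl | top$formal_charge > 0))
  } else {
    tmpl <- (top$res_name == "ASP" & top$name %in% c("OD1", "OD2")) |
      (top$res_name == "GLU" & top$name %in% c("OE1", "OE2")) |
      top$name == "OXT"
    which(prot & (tmpl | top$formal_charge < 0))
  }
}

ring_templates <- list(
  PHE = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(ring = c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(ring5 = c("CG", "CD1", "NE1", "CE2", "CD2"),
             ring6 = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")))

# rings as list of (chain, res_seq, label, atom indices)
aromatic_rings <- function(top, warn = TRUE) {
  prot <- which(protein_mask(top) & top$res_name %in% names(ring_templates))
  if (length(prot) == 0L) return(list())
  rings <- list()
  for (res in split(prot, paste(top$chain_id[prot], top$res_seq[prot]))) {
    rn <- top$res_name[res[1L]]
    for (label in names(ring_templates[[rn]])) {
      want <- ring_templates[[rn]][[label]]
      idx <- res[match(want, top$name[res])]
      if (anyNA(idx)) {
        if (warn) {
          warning(sprintf(
            "aromatic_rings(): %s %s%d missing ring atoms; skipped",
            rn, top$chain_id[res[1L]], top$res_seq[res[1L]]))
        }
        next
      }
      rings[[length(rings) + 1L]] <- list(chain = top$chain_id[idx[1L]],
                                          res = top$res_seq[idx[1L]],
                                          label = label, idx = idx)
    }
  }
  rings
}

ring_geometry <- function(frame, ring) {
  xyz <- frame[ring$idx, , drop = FALSE]
  centroid <- colMeans(xyz)
  centred <- sweep(xyz, 2L, centroid)
  sv <- svd(centred, nu = 0L, nv = 3L)
  list(centroid = centroid, normal = sv$v[, 3L])
}

vec_angle <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# canonical interaction key: ends sorted so (a,b) and (b,a) collide
make_keys <- function(kind, chain_a, res_a, atom_a, chain_b, res_b, atom_b) {
  if (length(chain_a) == 0L) return(character())
  ka <- paste(chain_a, sprintf("%06d", res_a), atom_a)
  kb <- paste(chain_b, sprintf("%06d", res_b), atom_b)
  flip <- kb < ka
  ea <- ifelse(flip, paste(chain_b, res_b, atom_b, sep = "|"),
               paste(chain_a, res_a, atom_a, sep = "|"))
  eb <- ifelse(flip, paste(chain_a, res_a, atom_a, sep = "|"),
               paste(chain_b, res_b, atom_b, sep = "|"))
  unique(paste(kind, ea, eb, sep = "|"))
}

#' Parse interaction keys into a data.frame
#' @param keys character vector of canonical interaction keys
#' @return data.frame \code{kind, chain_a, res_a, atom_a, chain_b, res_b,
#'   atom_b}
#' @export
parse_keys <- function(keys) {
  if (length(keys) == 0L) {
    return(data.frame(kind = character(), chain_a = character(),
                      res_a = integer(), atom_a = character(),
                      chain_b = character(), res_b = integer(),
                      atom_b = character()))
  }
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  data.frame(kind = parts[, 1L],
             chain_a = parts[, 2L], res_a = as.integer(parts[, 3L]),
             atom_a = parts[, 4L],
             chain_b = parts[, 5L], res_b = as.integer(parts[, 6L]),
             atom_b = parts[, 7L])
}

# ---- per-frame detectors ----------------------------------------------

#' Detect hydrogen bonds in one frame
#'
#' With hydrogens present, a bond is reported when the H...acceptor
#' distance, the donor angle D-H...A and the acceptor angle
#' H...A-antecedent all satisfy the criteria; without hydrogens the
#' heavy-atom fallback (donor...acceptor distance) applies. Donors and
#' acceptors are nitrogen and oxygen atoms of protein residues.
#'
#' @param frame \code{n x 3} coordinate matrix
#' @param top the \code{topology}
#' @param crit \code{\link{geometric_criteria}}
#' @param inter_chain restrict to pairs on different chains (default TRUE)
#' @return character vector of canonical interaction keys (at
#'   donor-atom/acceptor-atom resolution)
#' @export
detect_hbonds_frame <- function(frame, top, crit = geometric_criteria(),
                                inter_chain = TRUE) {
  prot <- protein_mask(top)
  hyd <- which(prot & is_hydrogen(top))
  heavy <- which(prot & top$element %in% c("N", "O"))
  if (length(heavy) < 2L) return(character())

  if (length(hyd) == 0L) {
    # heavy-atom fallback: all N/O are treated as both donor and acceptor
    d2 <- cross_dist2(frame[heavy, , drop = FALSE],
                      frame[heavy, , drop = FALSE])
    hit <- which(upper.tri(d2) & d2 <= crit$hbond_da_max^2, arr.ind = TRUE)
    if (nrow(hit) == 0L) return(character())
    a <- heavy[hit[, 1L]]
    b <- heavy[hit[, 2L]]
    ok <- top$chain_id[a] != top$chain_id[b] |
      !inter_chain & top$res_seq[a] != top$res_seq[b]
    if (inter_chain) ok <- top$chain_id[a] != top$chain_id[b]
    a <- a[ok]; b <- b[ok]
    return(make_keys("hbond", top$chain_id[a], top$res_seq[a], top$name[a],
                     top$chain_id[b], top$res_seq[b], top$name[b]))
  }

  # attach each H to its nearest heavy N/O in the same residue (<= 1.3 A)
  out_a <- integer(); out_b <- integer()
  reskey <- paste(top$chain_id, top$res_seq)
  for (h in hyd) {
    cand <- heavy[reskey[heavy] == reskey[h]]
    if (length(cand) == 0L) next
    dh <- sqrt(rowSums(sweep(frame[cand, , drop = FALSE], 2L, frame[h, ])^2))
    if (min(dh) > 1.3) next
    donor <- cand[which.min(dh)]
    acc <- heavy[heavy != donor]
    if (inter_chain) acc <- acc[top$chain_id[acc] != top$chain_id[donor]]
    if (length(acc) == 0L) next
    dha <- sqrt(rowSums(sweep(frame[acc, , drop = FALSE], 2L, frame[h, ])^2))
    acc <- acc[dha <= crit$hbond_ha_max]
    for (a in acc) {
      ang_d <- vec_angle(frame[donor, ] - frame[h, ], frame[a, ] - frame[h, ])
      if (ang_d < crit$hbond_donor_angle_min) next
      ante <- which(!is_hydrogen(top) & reskey == reskey[a] &
                      seq_len(nrow(top)) != a)
      if (length(ante) > 0L) {
        da <- sqrt(rowSums(sweep(frame[ante, , drop = FALSE],
                                 2L, frame[a, ])^2))
        ante <- ante[da <= 1.8]
      }
      if (length(ante) > 0L) {
        ang_a <- min(vapply(ante, function(x) {
          vec_angle(frame[h, ] - frame[a, ], frame[x, ] - frame[a, ])
        }, numeric(1L)))
        if (ang_a < crit$hbond_acceptor_angle_min) next
      }
      out_a <- c(out_a, donor)
      out_b <- c(out_b, a)
    }
  }
  make_keys("hbond", top$chain_id[out_a], top$res_seq[out_a],
            top$name[out_a], top$chain_id[out_b], top$res_seq[out_b],
            top$name[out_b])
}

#' Detect salt bridges in one frame
#'
#' A residue pair is reported when any positively charged side-chain atom
#' (Arg NE/NH1/NH2, Lys NZ, optionally protonated His, or positive formal
#' charge) lies within the cutoff of any negatively charged atom (Asp
#' OD1/OD2, Glu OE1/OE2, OXT, or negative formal charge). Keys are at
#' residue resolution with roles \code{basic}/\code{acidic}.
#'
#' @inheritParams detect_hbonds_frame
#' @return character vector of canonical interaction keys
#' @export
detect_salt_bridges_frame <- function(frame, top,
                                      crit = geometric_criteria(),
                                      inter_chain = TRUE) {
  pos <- charged_sites(top, crit, +1)
  neg <- charged_sites(top, crit, -1)
  if (length(pos) == 0L || length(neg) == 0L) return(character())
  d2 <- cross_dist2(frame[pos, , drop = FALSE], frame[neg, , drop = FALSE])
  hit <- which(d2 <= crit$salt_bridge_max^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(character())
  p <- pos[hit[, 1L]]
  n <- neg[hit[, 2L]]
  if (inter_chain) {
    keep <- top$chain_id[p] != top$chain_id[n]
    p <- p[keep]; n <- n[keep]
  }
  make_keys("salt_bridge", top$chain_id[p], top$res_seq[p], "basic",
            top$chain_id[n], top$res_seq[n], "acidic")
}

#' Detect pi-pi and cation-pi interactions in one frame
#'
#' Aromatic rings come from residue templates (Phe, Tyr, His, Trp). A pi-pi
#' contact is reported through either the face-to-face branch (small
#' centroid distance, near-parallel planes) or the edge-to-face branch
#' (larger distance, near-perpendicular planes); a cation-pi contact when a
#' positively charged site sits within the distance cutoff and inside the
#' angular cone about the ring normal.
#'
#' @inheritParams detect_hbonds_frame
#' @return character vector of canonical interaction keys (kinds
#'   \code{pi_pi} and \code{cation_pi})
#' @export
detect_ring_interactions_frame <- function(frame, top,
                                           crit = geometric_criteria(),
                                           inter_chain = TRUE) {
  rings <- aromatic_rings(top)
  keys <- character()
  if (length(rings) >= 2L) {
    geo <- lapply(rings, function(r) ring_geometry(frame, r))
    for (i in seq_along(rings)[-length(rings)]) {
      for (j in seq((i + 1L), length(rings))) {
        ri <- rings[[i]]; rj <- rings[[j]]
        if (inter_chain && ri$chain == rj$chain) next
        if (ri$chain == rj$chain && ri$res == rj$res) next
        d <- sqrt(sum((geo[[i]]$centroid - geo[[j]]$centroid)^2))
        ang <- vec_angle(geo[[i]]$normal, geo[[j]]$normal)
        ang <- min(ang, 180 - ang)           # interplanar angle in [0, 90]
        face <- d <= crit$pipi_face_max && ang <= crit$pipi_face_angle_max
        edge <- d <= crit$pipi_edge_max && ang >= crit$pipi_edge_angle_min
        if (face || edge) {
          keys <- c(keys, make_keys("pi_pi", ri$chain, ri$res, ri$label,
                                    rj$chain, rj$res, rj$label))
        }
      }
    }
  }
  cations <- charged_sites(top, crit, +1)
  if (length(rings) >= 1L && length(cations) >= 1L) {
    geo <- lapply(rings, function(r) ring_geometry(frame, r))
    for (i in seq_along(rings)) {
      r <- rings[[i]]
      for (cat in cations) {
        if (inter_chain && top$chain_id[cat] == r$chain) next
        v <- frame[cat, ] - geo[[i]]$centroid
        d <- sqrt(sum(v^2))
        if (d > crit$catpi_max || d == 0) next
        ang <- vec_angle(v, geo[[i]]$normal)
        ang <- min(ang, 180 - ang)           # cone about either face
        if (ang <= crit$catpi_angle_max) {
          keys <- c(keys, make_keys("cation_pi", top$chain_id[cat],
                                    top$res_seq[cat], top$name[cat],
                                    r$chain, r$res, r$label))
        }
      }
    }
  }
  unique(keys)
}

#' Detect interactions in every frame of a trajectory
#'
#' @param traj a \code{\link{trajectory}}
#' @param crit \code{\link{geometric_criteria}}
#' @param kinds interaction classes to detect
#' @param inter_chain restrict to inter-chain pairs (default TRUE)
#' @return list of length \code{n_frames(traj)}; each element a character
#'   vector of canonical interaction keys
#' @export
detect_interactions <- function(traj, crit = geometric_criteria(),
                                kinds = c("hbond", "salt_bridge",
                                          "pi_pi", "cation_pi"),
                                inter_chain = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  top <- traj$topology
  lapply(seq_len(n_frames(traj)), function(i) {
    frame <- traj$coords[, , i, drop = TRUE]
    keys <- character()
    if ("hbond" %in% kinds) {
      keys <- c(keys, detect_hbonds_frame(frame, top, crit, inter_chain))
    }
    if ("salt_bridge" %in% kinds) {
      keys <- c(keys, detect_salt_bridges_frame(frame, top, crit,
                                                inter_chain))
    }
    if (any(c("pi_pi", "cation_pi") %in% kinds)) {
      rk <- detect_ring_interactions_frame(frame, top, crit, inter_chain)
      rk <- rk[sub("\\|.*", "", rk) %in% kinds]
      keys <- c(keys, rk)
    }
    keys
  })
}

#' Interaction occupancy table with equilibration exclusion and filtering
#'
#' Occupancy of each interaction key is the fraction of analysed frames in
#' which its geometric criteria hold, computed per replica and merged over
#' replicas (the merged value is the analysed-frame-count weighted mean of
#' the per-replica values). The first \code{equilibration_frames} frames of
#' each replica are excluded as equilibration. A key is retained when its
#' merged occupancy reaches the threshold (default 20\%); output is sorted
#' by merged occupancy descending, ties by key order.
#'
#' @param detections per-frame key lists from \code{\link{detect_interactions}}
#' @param traj the trajectory the detections were computed on (supplies
#'   per-frame replica labels)
#' @param equilibration_frames frames to drop at the start of each replica
#' @param threshold merged-occupancy retention threshold, fraction
#' @return data.frame with key columns, \code{occ_rep_<r>} per replica,
#'   \code{occ_merged} and \code{retained}; attributes
#'   \code{"analyzed_frames"} (named per-replica counts) and
#'   \code{"threshold"}
#' @export
occupancy_table <- function(detections, traj, equilibration_frames = 0L,
                            threshold = 0.2) {
  stopifnot(inherits(traj, "trajectory"),
            length(detections) == n_frames(traj))
  reps <- replica_frames(traj)
  analyzed <- lapply(reps, function(fr) {
    if (equilibration_frames >= length(fr)) {
      stop("occupancy_table(): equilibration (", equilibration_frames,
           " frames) >= replica length (", length(fr), ")")
    }
    fr[seq_along(fr) > equilibration_frames]
  })
  n_analyzed <- vapply(analyzed, length, 1L)
  all_keys <- sort(unique(unlist(lapply(unlist(analyzed, use.names = FALSE),
                                        function(i) detections[[i]]),
                          use.names = FALSE)))
  occ <- matrix(0, nrow = length(all_keys), ncol = length(analyzed),
                dimnames = list(NULL, paste0("occ_rep_", names(analyzed))))
  for (j in seq_along(analyzed)) {
    counts <- table(factor(unlist(detections[analyzed[[j]]],
                                  use.names = FALSE), levels = all_keys))
    occ[, j] <- as.numeric(counts) / length(analyzed[[j]])
  }
  merged <- as.numeric(occ %*% n_analyzed) / sum(n_analyzed)
  tab <- cbind(parse_keys(all_keys), as.data.frame(occ))
  tab$occ_merged <- merged
  tab$retained <- merged >= threshold
  ord <- order(-tab$occ_merged, all_keys)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "analyzed_frames") <- n_analyzed
  attr(tab, "threshold") <- threshold
  attr(tab, "keys") <- all_keys[ord]
  tab
}

#' Per-replica interaction count time series
#'
#' Counts inter-chain interactions of one kind per frame, with time
#' measured within each replica — the data behind "H-bond count vs.
#' simulation time" interface plots.
#'
#' @param detections per-frame key lists
#' @param traj the trajectory the detections were computed on
#' @param kind interaction kind to count (default \code{"hbond"})
#' @return data.frame \code{replica, time_ps, count}
#' @export
count_series <- function(detections, traj, kind = "hbond") {
  stopifnot(length(detections) == n_frames(traj))
  counts <- vapply(detections, function(k) {
    sum(startsWith(k, paste0(kind, "|")))
  }, 1L)
  reps <- replica_frames(traj)
  do.call(rbind, lapply(names(reps), function(r) {
    fr <- reps[[r]]
    data.frame(replica = as.integer(r),
               time_ps = (seq_along(fr) - 1L) * traj$frame_interval,
               count = counts[fr])
  }))
}
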