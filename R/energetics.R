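#' Nonbonded energy model
#'
#' A transparent surrogate pair potential: Coulomb term
#' \code{k q_i q_j / r} with k = 332.0636 kcal A mol^-1 e^-2 plus
#' Lennard-Jones \code{4 eps [(sigma/r)^12 - (sigma/r)^6]} under
#' Lorentz-Berthelot combining rules (arithmetic-mean sigma,
#' geometric-mean epsilon), with a hard cutoff applied to both terms
#' (default 9 Angstrom, the coulombic cutoff used in the underlying
#' simulations). Absolute values are not comparable with force-field
#' energies; the model exists so that energy balances are exactly
#' reproducible.
#'
#' @param cutoff interaction cutoff, Angstrom
#' @param coulomb_k Coulomb constant, kcal A mol^-1 e^-2
#' @return list of class \code{"nonbonded_model"}
#' @export
nonbonded_model <- function(cutoff = 9, coulomb_k = 332.0636) {
  stopifnot(cutoff > 0)
  structure(list(cutoff = cutoff, coulomb_k = coulomb_k),
            class = "nonbonded_model")
}

#' Nonbonded pair energy
#'
#' @param q_i,q_j partial charges, elementary units
#' @param sigma_i,sigma_j Lennard-Jones sigma, Angstrom
#' @param eps_i,eps_j Lennard-Jones epsilon, kcal/mol
#' @param r interatomic distance, Angstrom (> 0)
#' @param model a \code{\link{nonbonded_model}}
#' @return energy in kcal/mol (0 beyond the cutoff)
#' @export
pair_energy <- function(q_i, q_j, sigma_i, sigma_j, eps_i, eps_j, r,
                        model = nonbonded_model()) {
  if (any(r == 0)) stop("pair_energy(): zero interatomic distance")
  sig <- (sigma_i + sigma_j) / 2
  eps <- sqrt(eps_i * eps_j)
  sr6 <- (sig / r)^6
  e <- model$coulomb_k * q_i * q_j / r + 4 * eps * (sr6^2 - sr6)
  e[r > model$cutoff] <- 0
  e
}

# vectorised group-group energy on one frame; a_idx/b_idx are atom indices
group_pair_sum <- function(frame, top, a_idx, b_idx, model) {
  if (length(a_idx) == 0L || length(b_idx) == 0L) return(0)
  d2 <- cross_dist2(frame[a_idx, , drop = FALSE],
                    frame[b_idx, , drop = FALSE])
  hit <- which(d2 <= model$cutoff^2)
  if (length(hit) == 0L) return(0)
  r <- sqrt(d2[hit])
  if (any(r == 0)) stop("group energy: zero interatomic distance")
  ii <- a_idx[(hit - 1L) %% length(a_idx) + 1L]
  jj <- b_idx[(hit - 1L) %/% length(a_idx) + 1L]
  sig <- (top$sigma[ii] + top$sigma[jj]) / 2
  eps <- sqrt(top$epsilon[ii] * top$epsilon[jj])
  sr6 <- ifelse(sig > 0, (sig / r)^6, 0)
  sum(model$coulomb_k * top$charge[ii] * top$charge[jj] / r +
        4 * eps * (sr6^2 - sr6))
}

#' Group-group interaction energy for one frame
#'
#' Sum of pair energies over all cross pairs between two disjoint atom
#' selections within the model cutoff.
#'
#' @param frame \code{n x 3} coordinate matrix
#' @param top the \code{topology} (with parameters assigned)
#' @param sel_a,sel_b disjoint atom selections
#' @param model a \code{\link{nonbonded_model}}
#' @return energy in kcal/mol
#' @export
group_energy <- function(frame, top, sel_a, sel_b,
                         model = nonbonded_model()) {
  if (length(intersect(sel_a, sel_b)) > 0L) {
    stop("group_energy(): selections overlap")
  }
  group_pair_sum(frame, top, as.integer(sel_a), as.integer(sel_b), model)
}

#' Intra-chain nonbonded (internal) energy for one frame
#'
#' Sums pair energies over atom pairs within one chain whose residues are
#' separated by at least \code{exclusion} positions in sequence (default 2:
#' same and adjacent residues are excluded, a bond-topology-free proxy for
#' the usual bonded-neighbour exclusions). Tracks the energy of chain
#' rearrangement between monomeric and dimeric simulations.
#'
#' @param frame \code{n x 3} coordinate matrix
#' @param top the \code{topology}
#' @param sel atom selection within a single chain
#' @param model a \code{\link{nonbonded_model}}
#' @param exclusion minimum residue-sequence separation (default 2)
#' @return energy in kcal/mol
#' @export
internal_energy <- function(frame, top, sel, model = nonbonded_model(),
                            exclusion = 2L) {
  sel <- as.integer(sel)
  if (length(sel) < 2L) return(0)
  if (length(unique(top$chain_id[sel])) != 1L) {
    stop("internal_energy(): selection spans more than one chain")
  }
  res <- top$res_seq[sel]
  pair <- which(upper.tri(diag(length(sel))) &
                  abs(outer(res, res, "-")) >= exclusion, arr.ind = TRUE)
  if (nrow(pair) == 0L) return(0)
  ii <- sel[pair[, 1L]]
  jj <- sel[pair[, 2L]]
  r <- sqrt(rowSums((frame[ii, , drop = FALSE] -
                       frame[jj, , drop = FALSE])^2))
  keep <- r <= model$cutoff
  if (!any(keep)) return(0)
  sum(pair_energy(top$charge[ii[keep]], top$charge[jj[keep]],
                  top$sigma[ii[keep]], top$sigma[jj[keep]],
                  top$epsilon[ii[keep]], top$epsilon[jj[keep]],
                  r[keep], model))
}

#' Per-frame, per-chain energy component series
#'
#' For every frame and every protein chain c, computes E(c, partner chain)
#' once per unordered chain pair (reported symmetrically for both chains),
#' E(c, membrane), E(c, water), E(c, ions) and the intra-chain internal
#' energy. Groups must be assigned and nonbonded parameters loaded.
#'
#' @param traj a \code{\link{trajectory}} with groups and parameters set
#' @param model a \code{\link{nonbonded_model}}
#' @param exclusion internal-energy residue separation (default 2)
#' @return data.frame of class \code{"energy_components"}:
#'   \code{frame, time_ps, replica, chain, term, partner, energy}
#'   with \code{term} in \{chain, membrane, water, ions, internal\}
#' @export
components_series <- function(traj, model = nonbonded_model(),
                              exclusion = 2L) {
  stopifnot(inherits(traj, "trajectory"))
  top <- traj$topology
  if (anyNA(top$group)) {
    stop("components_series(): groups not assigned; call assign_groups()")
  }
  chains <- protein_chains(top)
  if (length(chains) == 0L) stop("components_series(): no protein chains")
  chain_idx <- lapply(chains, function(ch) {
    which(top$group == paste0("protein:", ch))
  })
  names(chain_idx) <- chains
  env_idx <- list(membrane = which(top$group == "membrane"),
                  water = which(top$group == "water"),
                  ions = which(top$group == "ion"))
  # fixed record layout, identical for every frame
  rec_chain <- character(); rec_term <- character(); rec_partner <- character()
  for (ch in chains) {
    rec_chain <- c(rec_chain, rep(ch, 4L))
    rec_term <- c(rec_term, "membrane", "water", "ions", "internal")
    rec_partner <- c(rec_partner, "membrane", "water", "ions", ch)
  }
  pairs <- if (length(chains) > 1L) utils::combn(seq_along(chains), 2L) else
    matrix(integer(), 2L, 0L)
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1L, p]; b <- pairs[2L, p]
    rec_chain <- c(rec_chain, chains[a], chains[b])
    rec_term <- c(rec_term, "chain", "chain")
    rec_partner <- c(rec_partner, chains[b], chains[a])
  }
  nrec <- length(rec_chain)
  nf <- n_frames(traj)
  energy <- matrix(NA_real_, nrow = nrec, ncol = nf)
  for (i in seq_len(nf)) {
    frame <- traj$coords[, , i, drop = TRUE]
    e <- numeric(0L)
    for (ch in chains) {
      e <- c(e,
             vapply(env_idx, function(idx) {
               group_pair_sum(frame, top, chain_idx[[ch]], idx, model)
             }, numeric(1L)),
             internal_energy(frame, top, chain_idx[[ch]], model, exclusion))
    }
    for (p in seq_len(ncol(pairs))) {
      ecc <- group_pair_sum(frame, top, chain_idx[[pairs[1L, p]]],
                            chain_idx[[pairs[2L, p]]], model)
      e <- c(e, ecc, ecc)
    }
    energy[, i] <- e
  }
  out <- data.frame(
    frame = rep(seq_len(nf), each = nrec),
    time_ps = rep((seq_len(nf) - 1L) * traj$frame_interval, each = nrec),
    replica = rep(traj$frame_replica, each = nrec),
    chain = rep(rec_chain, nf),
    term = rep(rec_term, nf),
    partner = rep(rec_partner, nf),
    energy = as.numeric(energy))
  class(out) <- c("energy_components", "data.frame")
  out
}

# per-replica trailing-window mean of the summed terms
# chain-chain counted once (unordered pairs); env + internal per chain
window_total <- function(comp, window, chain_chain = TRUE) {
  reps <- sort(unique(comp$replica))
  vapply(reps, function(r) {
    sub <- comp[comp$replica == r, , drop = FALSE]
    frames <- sort(unique(sub$frame))
    n_keep <- max(1L, ceiling(window * length(frames)))
    keep <- frames[(length(frames) - n_keep + 1L):length(frames)]
    sub <- sub[sub$frame %in% keep, , drop = FALSE]
    env <- sub[sub$term != "chain", , drop = FALSE]
    total <- sum(env$energy) / length(keep)
    if (chain_chain) {
      cc <- sub[sub$term == "chain", , drop = FALSE]
      # each unordered pair appears twice (symmetric rows): count once
      total <- total + sum(cc$energy) / 2 / length(keep)
    }
    total
  }, numeric(1L))
}

#' Dimer formation energy with replica statistics
#'
#' For each replica r, the formation energy is the trailing-window mean of
#' the dimer's total energy terms — chain-chain counted once, plus
#' chain-membrane, chain-water, chain-ions and internal energy of both
#' chains — minus the same-window means of the corresponding monomer
#' terms, with the dimer replica paired positionally with the monomer
#' replicas. For a homodimer the single monomer is counted twice. A
#' negative value indicates that dimer formation is energetically
#' favourable. The mean and the standard error of the mean (SEM, sample
#' SD / sqrt(replicas)) over replicas are reported.
#'
#' @param dimer \code{\link{components_series}} of the dimer system
#' @param mon_a components of the chain-A monomer system
#' @param mon_b components of the chain-B monomer system, or \code{NULL}
#'   for a homodimer (monomer A counted twice)
#' @param window trailing fraction of each replica's frames to average
#'   over (default 0.5)
#' @return list of class \code{"formation_energy"}: \code{per_replica},
#'   \code{mean}, \code{sem}, \code{window}, \code{favorable}
#' @export
dimer_formation_energy <- function(dimer, mon_a, mon_b = NULL,
                                   window = 0.5) {
  stopifnot(window > 0, window <= 1)
  if (is.null(mon_b)) mon_b <- mon_a
  reps <- sort(unique(dimer$replica))
  if (!identical(reps, sort(unique(mon_a$replica))) ||
      !identical(reps, sort(unique(mon_b$replica)))) {
    stop("dimer_formation_energy(): replica sets of dimer and monomers ",
         "do not match")
  }
  vals <- window_total(dimer, window, chain_chain = TRUE) -
    window_total(mon_a, window, chain_chain = FALSE) -
    window_total(mon_b, window, chain_chain = FALSE)
  names(vals) <- reps
  m <- mean(vals)
  sem <- if (length(vals) > 1L) stats::sd(vals) / sqrt(length(vals)) else NA_real_
  structure(list(per_replica = vals, mean = m, sem = sem, window = window,
                 favorable = m < 0),
            class = "formation_energy")
}

#' @export
print.formation_energy <- function(x, ...) {
  cat(sprintf(
    "dimer formation energy: %.3f +/- %.3f kcal/mol (SEM, %d replicas, trailing %d%% window)%s\n",
    x$mean, x$sem, length(x$per_replica), round(100 * x$window),
    if (isTRUE(x$favorable)) " [favorable]" else ""))
  invisible(x)
}
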