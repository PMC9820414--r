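#' Kabsch superposition of two point sets
#'
#' Finds the proper rotation and translation minimising the least-squares
#' deviation of \code{mobile} onto \code{reference} (uniform weights), via
#' the SVD of the cross-covariance with the determinant sign corrected so
#' that reflections are never returned.
#'
#' The returned transform applies as \code{x \%*\% rotation + translation}
#' (row vectors of coordinates).
#'
#' @param mobile,reference \code{n x 3} matrices of paired points, n >= 3
#' @return list with \code{rotation} (3x3, det +1), \code{translation}
#'   (length-3) and \code{rmsd} (Angstrom, after superposition)
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, ncol(reference) == 3L)
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("kabsch_superpose(): point counts differ")
  if (n < 3L) stop("kabsch_superpose(): need at least 3 points")
  mu_m <- colMeans(mobile)
  mu_r <- colMeans(reference)
  mc <- sweep(mobile, 2L, mu_m)
  rc <- sweep(reference, 2L, mu_r)
  C <- crossprod(mc, rc)                     # 3x3 cross-covariance
  sv <- svd(C)
  if (sv$d[2L] <= max(sv$d[1L], 1) * 1e-12) {
    stop("kabsch_superpose(): degenerate (collinear) point set")
  }
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  # residual computed explicitly: the eigenvalue shortcut loses ~1e-7 A
  # to cancellation between large coordinate sums
  rmsd <- sqrt(sum((mc %*% R - rc)^2) / n)
  list(rotation = R, translation = as.numeric(mu_r - mu_m %*% R),
       rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param coords \code{n x 3} matrix
#' @param tf transform from \code{\link{kabsch_superpose}}
#' @return transformed \code{n x 3} matrix
#' @export
apply_transform <- function(coords, tf) {
  sweep(as.matrix(coords) %*% tf$rotation, 2L, tf$translation, "+")
}

#' Fitted RMSD between two point sets
#' @param a,b \code{n x 3} matrices
#' @return RMSD in Angstrom after optimal superposition
#' @export
fitted_rmsd <- function(a, b) kabsch_superpose(a, b)$rmsd

#' Per-frame RMSD series against a reference frame
#'
#' Each frame is optimally superposed (Kabsch, uniform weights) onto the
#' reference frame on the given selection — conventionally the C-alpha
#' atoms — and the residual RMSD recorded. The reference entry is exactly
#' zero.
#'
#' @param traj a \code{\link{trajectory}}
#' @param sel atom selection (see \code{\link{select_atoms}})
#' @param reference_frame frame index used as reference (default 1)
#' @return data.frame \code{frame, time_ps, replica, rmsd_A}
#' @export
rmsd_series <- function(traj, sel, reference_frame = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(sel) == 0L) stop("rmsd_series(): empty selection")
  nf <- n_frames(traj)
  ref <- traj$coords[sel, , reference_frame, drop = TRUE]
  vals <- vapply(seq_len(nf), function(i) {
    if (i == reference_frame) return(0)
    fitted_rmsd(traj$coords[sel, , i, drop = TRUE], ref)
  }, numeric(1L))
  data.frame(frame = seq_len(nf),
             time_ps = (seq_len(nf) - 1L) * traj$frame_interval,
             replica = traj$frame_replica,
             rmsd_A = vals)
}

#' Per-residue RMSF profile
#'
#' All frames in the window are superposed onto the reference frame on the
#' selection (single pass; no iterative mean refitting), per-atom
#' fluctuations are computed as the root-mean-square deviation from the
#' time-averaged position, and per-residue values are the mean over each
#' residue's selected atoms.
#'
#' @param traj a \code{\link{trajectory}}
#' @param sel atom selection
#' @param window frame indices to include (default all frames)
#' @param reference_frame frame used for superposition (default the first
#'   window frame)
#' @return data.frame \code{chain_id, res_seq, rmsf_A} with attribute
#'   \code{"atom_rmsf"}: data.frame \code{atom, rmsf_A} per selected atom
#' @export
rmsf_profile <- function(traj, sel, window = seq_len(n_frames(traj)),
                         reference_frame = window[1L]) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(sel) == 0L) stop("rmsf_profile(): empty selection")
  if (length(window) == 0L) stop("rmsf_profile(): empty frame window")
  ref <- traj$coords[sel, , reference_frame, drop = TRUE]
  n <- length(sel)
  fitted <- array(NA_real_, dim = c(n, 3L, length(window)))
  for (k in seq_along(window)) {
    x <- traj$coords[sel, , window[k], drop = TRUE]
    tf <- kabsch_superpose(x, ref)
    fitted[, , k] <- apply_transform(x, tf)
  }
  mean_pos <- apply(fitted, c(1L, 2L), mean)
  dev2 <- sweep(fitted, c(1L, 2L), mean_pos)^2
  atom_rmsf <- sqrt(apply(dev2, 1L, sum) / length(window))
  top <- traj$topology[sel, , drop = FALSE]
  res <- stats::aggregate(atom_rmsf,
                          by = list(chain_id = top$chain_id,
                                    res_seq = top$res_seq),
                          FUN = mean)
  names(res)[3L] <- "rmsf_A"
  res <- res[order(res$chain_id, res$res_seq), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "atom_rmsf") <- data.frame(atom = as.integer(sel),
                                       rmsf_A = atom_rmsf)
  res
}

#' Build a dimer by superposing monomers onto a template dimer
#'
#' Each monomer is rigidly placed by a Kabsch fit of mapped C-alpha atoms
#' onto the corresponding chain of a two-chain template structure — the
#' standard way of generating homo-/hetero-dimer models from a solved dimer
#' (e.g. placing receptor monomers on a crystallographic CXCR4 homodimer).
#' Steric strain is reported as a count of inter-chain heavy-atom clashes;
#' relieving it (energy minimisation) is outside this package's scope.
#'
#' @param template single-frame, two-chain \code{\link{trajectory}}
#' @param mon_a,mon_b single-frame monomer trajectories
#' @param mapping list with elements named after the two template chains;
#'   each a data.frame \code{template_res, monomer_res} of corresponding
#'   residue numbers (>= 3 pairs)
#' @param clash_cutoff inter-chain heavy-atom distance (Angstrom) counted
#'   as a clash (default 2.0)
#' @return list: \code{structure} (single-frame trajectory, chain A atoms
#'   then chain B atoms, relabelled to the template chain ids),
#'   \code{fit_rmsd} (named numeric, Angstrom per chain),
#'   \code{clash_count}
#' @export
build_dimer <- function(template, mon_a, mon_b, mapping, clash_cutoff = 2.0) {
  stopifnot(inherits(template, "trajectory"), n_frames(template) == 1L,
            n_frames(mon_a) == 1L, n_frames(mon_b) == 1L)
  tchains <- chain_ids(template)
  if (length(tchains) != 2L) stop("build_dimer(): template must have 2 chains")
  if (!all(tchains %in% names(mapping))) {
    stop("build_dimer(): mapping must have elements named ",
         paste(tchains, collapse = " and "))
  }
  place <- function(mon, tchain) {
    map <- mapping[[tchain]]
    if (nrow(map) < 3L) stop("build_dimer(): need >= 3 mapped residues")
    ttop <- template$topology
    mtop <- mon$topology
    t_idx <- match(paste(tchain, map$template_res, "CA"),
                   paste(ttop$chain_id, ttop$res_seq, ttop$name))
    m_idx <- match(paste(mtop$chain_id[1L], map$monomer_res, "CA"),
                   paste(mtop$chain_id, mtop$res_seq, mtop$name))
    if (anyNA(t_idx) || anyNA(m_idx)) {
      stop("build_dimer(): mapping references residues missing a CA atom ",
           "in chain ", tchain)
    }
    tf <- kabsch_superpose(mon$coords[m_idx, , 1L, drop = TRUE],
                           template$coords[t_idx, , 1L, drop = TRUE])
    top <- mtop
    top$chain_id <- tchain
    list(top = top,
         coords = apply_transform(mon$coords[, , 1L, drop = TRUE], tf),
         rmsd = tf$rmsd)
  }
  pa <- place(mon_a, tchains[1L])
  pb <- place(mon_b, tchains[2L])
  top <- rbind(as.data.frame(pa$top), as.data.frame(pb$top))
  top$serial <- seq_len(nrow(top))
  dimer <- trajectory(topology(top), rbind(pa$coords, pb$coords),
                      frame_interval = template$frame_interval)
  heavy_a <- pa$top$element != "H"
  heavy_b <- pb$top$element != "H"
  d2 <- cross_dist2(pa$coords[heavy_a, , drop = FALSE],
                    pb$coords[heavy_b, , drop = FALSE])
  clashes <- sum(d2 < clash_cutoff^2)
  fit <- c(pa$rmsd, pb$rmsd)
  names(fit) <- tchains
  list(structure = dimer, fit_rmsd = fit, clash_count = clashes)
}

# squared distances between rows of a (n x 3) and rows of b (m x 3)
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}
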