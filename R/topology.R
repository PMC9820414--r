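#' Construct a topology
#'
#' A topology holds the static atom table of a simulated system: one row per
#' atom with PDB-style identity fields, optional nonbonded parameters
#' (partial charge, Lennard-Jones sigma/epsilon), an optional formal charge
#' used by the salt-bridge detector for synthetic atoms, and an environment
#' group label (\code{"protein:<chain>"}, \code{"membrane"}, \code{"water"}
#' or \code{"ion"}).
#'
#' Atoms must be ordered so that each residue \code{(chain_id, res_seq)}
#' occupies a contiguous range of rows, and \code{(chain_id, res_seq, name)}
#' must be unique.
#'
#' @param atoms data.frame with columns \code{serial}, \code{name},
#'   \code{element}, \code{res_name}, \code{res_seq}, \code{chain_id} and
#'   optionally \code{charge}, \code{sigma}, \code{epsilon},
#'   \code{formal_charge}, \code{group}. Missing optional columns are filled
#'   with defaults (0 for parameters, \code{NA} for group).
#' @return An object of class \code{"topology"}: the completed atom
#'   data.frame.
#' @export
topology <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  required <- c("serial", "name", "element", "res_name", "res_seq", "chain_id")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("topology(): missing columns: ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("charge", "sigma", "epsilon", "formal_charge")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- 0
  }
  if (is.null(atoms$group)) atoms$group <- NA_character_
  atoms$serial <- as.integer(atoms$serial)
  atoms$res_seq <- as.integer(atoms$res_seq)
  atoms <- atoms[, c(required, "charge", "sigma", "epsilon",
                     "formal_charge", "group")]

  key <- paste(atoms$chain_id, atoms$res_seq, atoms$name, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- atoms[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("topology(): duplicate atom (chain %s, residue %d, name %s)",
                 dup$chain_id, dup$res_seq, dup$name))
  }
  rkey <- paste(atoms$chain_id, atoms$res_seq, sep = "\r")
  runs <- rle(rkey)$values
  if (anyDuplicated(runs)) {
    stop("topology(): residues must occupy contiguous atom ranges; residue ",
         sub("\r", ":", runs[duplicated(runs)][1L]), " is split")
  }
  if (any(atoms$sigma < 0) || any(atoms$epsilon < 0)) {
    stop("topology(): sigma and epsilon must be non-negative")
  }
  rownames(atoms) <- NULL
  class(atoms) <- c("topology", "data.frame")
  atoms
}

#' Number of atoms in a topology or trajectory
#' @param x a \code{topology} or \code{trajectory}
#' @return integer atom count
#' @export
n_atoms <- function(x) {
  if (inherits(x, "trajectory")) x <- x$topology
  nrow(x)
}

#' Chain identifiers present in a topology or trajectory
#' @param x a \code{topology} or \code{trajectory}
#' @return character vector of chain ids, in order of first appearance
#' @export
chain_ids <- function(x) {
  if (inherits(x, "trajectory")) x <- x$topology
  unique(x$chain_id)
}

#' Protein chain identifiers (group \code{protein:<chain>})
#' @param x a \code{topology} or \code{trajectory}
#' @return character vector of protein chain ids
#' @export
protein_chains <- function(x) {
  if (inherits(x, "trajectory")) x <- x$topology
  g <- x$group
  sub("^protein:", "", unique(g[!is.na(g) & startsWith(g, "protein:")]))
}

#' Construct a trajectory
#'
#' A trajectory couples a \code{\link{topology}} with an ordered stack of
#' coordinate frames (in Angstrom) on a regular time grid, plus replica
#' bookkeeping so that analyses can be run per replica after
#' \code{\link{merge_replicas}}.
#'
#' @param topology a \code{topology}
#' @param coords numeric array \code{n_atoms x 3 x n_frames} (a single
#'   \code{n_atoms x 3} matrix is promoted to one frame)
#' @param frame_interval time between recorded frames, ps
#' @param replica_id integer replica label
#' @param frame_replica optional integer vector, per-frame replica label
#'   (defaults to \code{replica_id} for every frame)
#' @return An object of class \code{"trajectory"}.
#' @export
trajectory <- function(topology, coords, frame_interval = 100,
                       replica_id = 1L, frame_replica = NULL) {
  stopifnot(inherits(topology, "topology"))
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[1] != nrow(topology)) {
    stop("trajectory(): coordinate frames have ", dim(coords)[1],
         " atoms but topology has ", nrow(topology))
  }
  if (!all(is.finite(coords))) stop("trajectory(): non-finite coordinates")
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("trajectory(): frame_interval must be positive")
  }
  n_fr <- dim(coords)[3]
  if (is.null(frame_replica)) frame_replica <- rep(as.integer(replica_id), n_fr)
  stopifnot(length(frame_replica) == n_fr)
  structure(list(topology = topology, coords = coords,
                 frame_interval = as.numeric(frame_interval),
                 replica_id = as.integer(replica_id),
                 frame_replica = as.integer(frame_replica)),
            class = "trajectory")
}

#' Number of frames in a trajectory
#' @param traj a \code{trajectory}
#' @return integer frame count
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  dim(traj$coords)[3]
}

#' Coordinates of one frame
#' @param traj a \code{trajectory}
#' @param i frame index (1-based)
#' @return \code{n_atoms x 3} numeric matrix
#' @export
frame_coords <- function(traj, i) {
  stopifnot(inherits(traj, "trajectory"))
  if (i < 1L || i > n_frames(traj)) {
    stop("frame_coords(): frame index ", i, " out of range 1..", n_frames(traj))
  }
  traj$coords[, , i, drop = TRUE]
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "trajectory: %d atoms, %d frames @ %g ps, chains [%s], replicas {%s}\n",
    n_atoms(x), n_frames(x), x$frame_interval,
    paste(chain_ids(x), collapse = ","),
    paste(unique(x$frame_replica), collapse = ",")))
  invisible(x)
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d chains, %d residues\n",
              nrow(x), length(unique(x$chain_id)),
              length(unique(paste(x$chain_id, x$res_seq)))))
  NextMethod()
}
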