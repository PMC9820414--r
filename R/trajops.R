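#' Subsample a trajectory at a coarser time stride
#'
#' Keeps frames 0, k, 2k, ... (0-based) where
#' \code{k = stride_ps / frame_interval}, and updates the frame interval to
#' the stride — the standard pre-analysis thinning of a densely recorded
#' production trajectory (e.g. a 100 ps recording grid thinned to 500 ps).
#'
#' @param traj a \code{\link{trajectory}}
#' @param stride_ps new time spacing, ps; must be a positive integer
#'   multiple of \code{traj$frame_interval}
#' @return the subsampled \code{trajectory}
#' @export
subsample <- function(traj, stride_ps) {
  stopifnot(inherits(traj, "trajectory"))
  k <- stride_ps / traj$frame_interval
  if (!is.finite(k) || k < 1 || abs(k - round(k)) > 1e-9) {
    stop("subsample(): stride must be a positive integer multiple of the ",
         "frame interval (", traj$frame_interval, " ps)")
  }
  k <- as.integer(round(k))
  keep <- seq(1L, n_frames(traj), by = k)
  trajectory(traj$topology, traj$coords[, , keep, drop = FALSE],
             frame_interval = stride_ps, replica_id = traj$replica_id,
             frame_replica = traj$frame_replica[keep])
}

#' Merge replica trajectories into one
#'
#' Frames are concatenated in replica order; per-frame replica labels are
#' preserved so per-replica occupancy and energy statistics remain
#' possible after merging (as done before conformational clustering).
#'
#' @param trajs list of \code{\link{trajectory}} objects sharing an
#'   identical topology and frame interval
#' @return a merged \code{trajectory}
#' @export
merge_replicas <- function(trajs) {
  stopifnot(is.list(trajs), length(trajs) >= 1L)
  if (length(trajs) == 1L) return(trajs[[1L]])
  ref <- trajs[[1L]]$topology
  for (i in seq_along(trajs)[-1L]) {
    top <- trajs[[i]]$topology
    if (nrow(top) != nrow(ref)) {
      stop("merge_replicas(): trajectory ", i, " has ", nrow(top),
           " atoms, expected ", nrow(ref))
    }
    same <- top$chain_id == ref$chain_id & top$res_seq == ref$res_seq &
      top$name == ref$name
    if (!all(same)) {
      j <- which(!same)[1L]
      stop(sprintf(
        "merge_replicas(): topology mismatch at atom %d (%s %d %s vs %s %d %s)",
        j, top$chain_id[j], top$res_seq[j], top$name[j],
        ref$chain_id[j], ref$res_seq[j], ref$name[j]))
    }
    if (trajs[[i]]$frame_interval != trajs[[1L]]$frame_interval) {
      stop("merge_replicas(): frame intervals differ")
    }
  }
  coords <- array(unlist(lapply(trajs, `[[`, "coords"), use.names = FALSE),
                  dim = c(nrow(ref), 3L, sum(vapply(trajs, n_frames, 1L))))
  frame_replica <- unlist(lapply(trajs, `[[`, "frame_replica"),
                          use.names = FALSE)
  trajectory(ref, coords, frame_interval = trajs[[1L]]$frame_interval,
             replica_id = trajs[[1L]]$replica_id,
             frame_replica = frame_replica)
}

#' Split a merged trajectory back into per-replica frame index lists
#' @param traj a merged \code{trajectory}
#' @return named list: replica label -> integer frame indices
#' @keywords internal
replica_frames <- function(traj) {
  split(seq_len(n_frames(traj)), traj$frame_replica)
}
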