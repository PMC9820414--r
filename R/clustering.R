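#' Pairwise Kabsch-fitted RMSD matrix
#'
#' Entry \code{(i, j)} is the RMSD between frames i and j on the selection
#' after optimal per-pair superposition (not fit-to-reference), the
#' standard input of Gromos conformational clustering. The O(n^2) fit loop
#' runs in compiled code.
#'
#' @param traj a \code{\link{trajectory}}
#' @param sel atom selection (conventionally C-alpha atoms)
#' @return symmetric \code{n_frames x n_frames} matrix, Angstrom
#' @export
pairwise_rmsd_matrix <- function(traj, sel) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(sel) == 0L) stop("pairwise_rmsd_matrix(): empty selection")
  cpp_pairwise_rmsd(traj$coords[sel, , , drop = FALSE])
}

#' Gromos (Daura-type) conformational clustering
#'
#' Iteratively, the unassigned frame with the most unassigned neighbours
#' within the RMSD threshold becomes a cluster medoid (ties broken toward
#' the smallest frame index); it and its neighbours form a cluster and are
#' removed, until no frames remain. Clusters are ordered by size
#' descending, ties by smaller medoid index — the procedure is fully
#' deterministic.
#'
#' @param mat symmetric pairwise RMSD matrix
#' @param threshold neighbour cutoff, Angstrom (e.g. 1.6)
#' @return list of class \code{"cluster_result"}: \code{clusters} (list of
#'   integer frame-index vectors), \code{medoids}, \code{sizes},
#'   \code{threshold}
#' @export
gromos_cluster <- function(mat, threshold) {
  mat <- as.matrix(mat)
  if (nrow(mat) == 0L) stop("gromos_cluster(): empty matrix")
  stopifnot(nrow(mat) == ncol(mat), threshold > 0)
  n <- nrow(mat)
  adj <- mat <= threshold
  diag(adj) <- FALSE
  alive <- rep(TRUE, n)
  clusters <- list()
  medoids <- integer()
  while (any(alive)) {
    counts <- as.integer(adj %*% alive)
    counts[!alive] <- -1L
    center <- which.max(counts)            # which.max takes the first tie
    members <- which(alive & (adj[center, ] | seq_len(n) == center))
    clusters[[length(clusters) + 1L]] <- members
    medoids <- c(medoids, center)
    alive[members] <- FALSE
    adj[, members] <- FALSE
  }
  sizes <- lengths(clusters)
  ord <- order(-sizes, medoids)
  structure(list(clusters = clusters[ord], medoids = medoids[ord],
                 sizes = sizes[ord], threshold = threshold),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("gromos clustering @ %g A: %d clusters over %d frames\n",
              x$threshold, length(x$clusters), sum(x$sizes)))
  k <- min(5L, length(x$clusters))
  for (i in seq_len(k)) {
    cat(sprintf("  #%d: %d frames, medoid frame %d\n",
                i, x$sizes[i], x$medoids[i]))
  }
  invisible(x)
}

#' Extract the medoid structure of a cluster
#'
#' Returns the medoid frame of the \code{rank}-th most populated cluster
#' as a single-frame trajectory, exportable via \code{\link{write_pdb}}.
#' Ranks are 1-based: rank 1 is the most populated cluster.
#'
#' @param traj the clustered \code{\link{trajectory}}
#' @param result a \code{\link{gromos_cluster}} result
#' @param rank cluster rank by population (1-based)
#' @return single-frame \code{trajectory}
#' @export
medoid_structure <- function(traj, result, rank = 1L) {
  stopifnot(inherits(traj, "trajectory"), inherits(result, "cluster_result"))
  if (rank < 1L || rank > length(result$clusters)) {
    stop("medoid_structure(): rank ", rank, " out of range 1..",
         length(result$clusters))
  }
  i <- result$medoids[rank]
  trajectory(traj$topology, traj$coords[, , i, drop = FALSE],
             frame_interval = traj$frame_interval,
             replica_id = traj$frame_replica[i])
}

#' Cluster membership as a data.frame
#' @param result a \code{cluster_result}
#' @param traj optional trajectory supplying per-frame replica labels
#' @return data.frame \code{frame, replica, cluster_id}
#' @export
cluster_assignments <- function(result, traj = NULL) {
  n <- sum(result$sizes)
  id <- integer(n)
  for (k in seq_along(result$clusters)) id[result$clusters[[k]]] <- k
  out <- data.frame(frame = seq_len(n), cluster_id = id)
  if (!is.null(traj)) {
    out <- data.frame(frame = out$frame, replica = traj$frame_replica,
                      cluster_id = out$cluster_id)
  }
  out
}
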