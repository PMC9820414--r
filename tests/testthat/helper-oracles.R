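# Independent oracles used to cross-check the package's implementations.
# Each is written from the underlying definition, not from the package code.

# Horn's quaternion characteristic-polynomial method for the optimal
# proper-rotation RMSD between paired point sets.
quaternion_rmsd <- function(a, b) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  S <- crossprod(a, b)
  K <- matrix(c(
    S[1, 1] + S[2, 2] + S[3, 3], S[2, 3] - S[3, 2],
    S[3, 1] - S[1, 3], S[1, 2] - S[2, 1],
    S[2, 3] - S[3, 2], S[1, 1] - S[2, 2] - S[3, 3],
    S[1, 2] + S[2, 1], S[3, 1] + S[1, 3],
    S[3, 1] - S[1, 3], S[1, 2] + S[2, 1],
    -S[1, 1] + S[2, 2] - S[3, 3], S[2, 3] + S[3, 2],
    S[1, 2] - S[2, 1], S[3, 1] + S[1, 3],
    S[2, 3] + S[3, 2], -S[1, 1] - S[2, 2] + S[3, 3]), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(a^2) + sum(b^2) - 2 * lam) / nrow(a)
  sqrt(max(msd, 0))
}

# Exhaustive reference implementation of Gromos (Daura) clustering:
# neighbour lists recomputed from scratch by explicit loops each round.
brute_gromos <- function(mat, threshold) {
  n <- nrow(mat)
  unassigned <- seq_len(n)
  clusters <- list()
  medoids <- integer()
  while (length(unassigned) > 0) {
    best <- NA_integer_
    best_n <- -1L
    for (i in unassigned) {
      cnt <- 0L
      for (j in unassigned) {
        if (j != i && mat[i, j] <= threshold) cnt <- cnt + 1L
      }
      if (cnt > best_n) {
        best_n <- cnt
        best <- i
      }
    }
    members <- best
    for (j in unassigned) {
      if (j != best && mat[best, j] <= threshold) members <- c(members, j)
    }
    members <- sort(members)
    clusters[[length(clusters) + 1]] <- members
    medoids <- c(medoids, best)
    unassigned <- setdiff(unassigned, members)
  }
  sizes <- lengths(clusters)
  ord <- order(-sizes, medoids)
  list(clusters = clusters[ord], medoids = medoids[ord], sizes = sizes[ord])
}

# Plain double-loop group-group nonbonded energy (Coulomb + LJ, hard
# cutoff on both terms, Lorentz-Berthelot combination).
brute_group_energy <- function(frame, top, sel_a, sel_b, cutoff = 9,
                               k = 332.0636) {
  e <- 0
  for (i in sel_a) {
    for (j in sel_b) {
      r <- sqrt(sum((frame[i, ] - frame[j, ])^2))
      if (r > cutoff) next
      sig <- (top$sigma[i] + top$sigma[j]) / 2
      eps <- sqrt(top$epsilon[i] * top$epsilon[j])
      sr6 <- if (sig > 0) (sig / r)^6 else 0
      e <- e + k * top$charge[i] * top$charge[j] / r +
        4 * eps * (sr6 * sr6 - sr6)
    }
  }
  e
}

# random rigid transform (rotation from QR of a Gaussian matrix, det +1)
random_rigid <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 5))
}
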