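#' LOWESS smoothing (locally weighted scatterplot smoothing)
#'
#' Robust locally weighted linear regression after Cleveland: for each
#' target point, a tricube-weighted linear fit over the nearest
#' \code{floor(frac * n)} points (at least 2), with optional bisquare
#' robustness iterations that down-weight outlying residuals. This is a
#' faithful port of the classic algorithm with no interpolation
#' short-cut (delta = 0), so every point is fitted exactly; x values must
#' be strictly increasing.
#'
#' @param x strictly increasing numeric vector (n >= 3)
#' @param y numeric response, same length
#' @param frac fraction of points in each local neighbourhood (0, 1]
#' @param robust_iters number of bisquare robustness iterations
#'   (default 3, as in the classic implementation)
#' @return numeric vector of smoothed y values
#' @export
lowess_smooth <- function(x, y, frac = 2 / 3, robust_iters = 3L) {
  n <- length(x)
  if (n < 3L) stop("lowess_smooth(): need at least 3 points")
  stopifnot(length(y) == n, frac > 0, frac <= 1, robust_iters >= 0)
  if (any(diff(x) <= 0)) stop("lowess_smooth(): x must be strictly increasing")

  ns <- max(2L, min(n, as.integer(frac * n + 1e-7)))
  ys <- numeric(n)
  rw <- rep(1, n)
  range_x <- x[n] - x[1L]

  fit_at <- function(i, nleft, nright, use_rw) {
    xs <- x[i]
    h <- max(xs - x[nleft], x[nright] - xs)
    h9 <- 0.999 * h
    h1 <- 0.001 * h
    w <- numeric(n)
    a <- 0
    j <- nleft
    while (j <= n) {
      r <- abs(x[j] - xs)
      if (r <= h9) {
        w[j] <- if (r <= h1) 1 else (1 - (r / h)^3)^3
        if (use_rw) w[j] <- w[j] * rw[j]
        a <- a + w[j]
      } else if (x[j] > xs) {
        break
      }
      j <- j + 1L
    }
    nrt <- j - 1L
    if (a <= 0) return(y[i])                 # all robustness weights zero
    jj <- nleft:nrt
    w[jj] <- w[jj] / a
    if (h > 0) {
      xbar <- sum(w[jj] * x[jj])
      b <- xs - xbar
      cc <- sum(w[jj] * (x[jj] - xbar)^2)
      if (sqrt(cc) > 0.001 * range_x) {
        b <- b / cc
        w[jj] <- w[jj] * (b * (x[jj] - xbar) + 1)
      }
    }
    sum(w[jj] * y[jj])
  }

  for (iter in seq_len(robust_iters + 1L)) {
    nleft <- 1L
    nright <- ns
    for (i in seq_len(n)) {
      while (nright < n) {
        d1 <- x[i] - x[nleft]
        d2 <- x[nright + 1L] - x[i]
        if (d1 > d2) {
          nleft <- nleft + 1L
          nright <- nright + 1L
        } else break
      }
      ys[i] <- fit_at(i, nleft, nright, use_rw = iter > 1L)
    }
    if (iter > robust_iters) break
    res <- y - ys
    sc <- mean(abs(res))
    srw <- sort(abs(res))
    cmad <- if (n %% 2L == 0L) {
      3 * (srw[n %/% 2L] + srw[n %/% 2L + 1L])
    } else {
      6 * srw[(n + 1L) %/% 2L]
    }
    if (cmad < 1e-7 * sc) break              # effectively exact fit
    c9 <- 0.999 * cmad
    c1 <- 0.001 * cmad
    r <- abs(res)
    rw <- ifelse(r <= c1, 1,
                 ifelse(r <= c9, (1 - (r / cmad)^2)^2, 0))
  }
  ys
}
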