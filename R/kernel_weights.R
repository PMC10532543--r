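#' Gaussian-kernel density weights
#'
#' Initial per-point weights measuring local density: for each point,
#' \eqn{w_i = q^{-1} \sum_{j \in S_{iq}} \exp(-d^2(x_i, x_j)/\sigma)} where
#' \eqn{S_{iq}} holds the q nearest neighbours of \eqn{x_i} (the point itself
#' excluded) and \eqn{d^2} is squared Euclidean distance.  Points in dense
#' regions get weights near 1; isolated points (noise, outliers) get small
#' weights.  Smaller \eqn{\sigma} sharpens the contrast between dense and
#' sparse regions.
#'
#' @param cloud a \code{\link{point_cloud}} or coordinate matrix.
#' @param sigma positive kernel scale (default 25, in squared data units).
#' @param q number of nearest neighbours (default 20); must be < N.
#' @return numeric vector of N weights in (0, 1].
#' @export
kernel_weights <- function(cloud, sigma = 25, q = 20) {
  X <- cloud_matrix(cloud)
  n <- nrow(X)
  if (q < 1) stop("q must be >= 1")
  if (q >= n) stop("q must be smaller than the number of points")
  if (sigma <= 0) stop("sigma must be positive")
  sq <- rowSums(X^2)
  w <- numeric(n)
  chunk <- max(1L, floor(2e6 / n))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    # squared distances from points idx to all points
    D <- outer(sq[idx], sq, `+`) - 2 * (X[idx, , drop = FALSE] %*% t(X))
    D[cbind(seq_along(idx), idx)] <- Inf    # exclude self
    D[D < 0] <- 0
    for (r in seq_along(idx)) {
      dd <- sort.int(D[r, ], partial = q)[seq_len(q)]
      w[idx[r]] <- mean(exp(-dd / sigma))
    }
  }
  pmin(w, 1)
}
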