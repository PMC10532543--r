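#' Construct a point cloud
#'
#' A point cloud is an N x d numeric matrix of coordinates with an optional
#' vector of per-point weights in (0, 1] and an optional vector of provenance
#' labels (e.g. the generating mixture component, or \code{"noise"}).
#'
#' @param points numeric matrix (N x d) or data frame of coordinates; a
#'   numeric vector is treated as a one-column matrix.
#' @param weights optional numeric vector of length N with values in (0, 1].
#' @param labels optional character/integer vector of length N.
#' @return An object of class \code{point_cloud}: a list with elements
#'   \code{points}, \code{weights}, \code{labels}, \code{n}, \code{dim}.
#' @export
point_cloud <- function(points, weights = NULL, labels = NULL) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.vector(points) && is.numeric(points)) points <- matrix(points, ncol = 1L)
  if (!is.matrix(points) || !is.numeric(points))
    stop("'points' must be a numeric matrix")
  storage.mode(points) <- "double"
  if (nrow(points) < 1L) stop("a point cloud needs at least one point")
  if (!all(is.finite(points))) stop("all coordinates must be finite")
  n <- nrow(points)
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != n) stop("'weights' must have one entry per point")
    if (!all(is.finite(weights)) || any(weights <= 0) || any(weights > 1))
      stop("weights must lie in (0, 1]")
  }
  if (!is.null(labels) && length(labels) != n)
    stop("'labels' must have one entry per point")
  structure(list(points = points, weights = weights, labels = labels,
                 n = n, dim = ncol(points)),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points in %d-D%s%s\n", x$n, x$dim,
              if (!is.null(x$weights)) ", weighted" else "",
              if (!is.null(x$labels)) ", labelled" else ""))
  invisible(x)
}

#' Coerce to a point cloud
#' @param x matrix, data frame or point_cloud.
#' @param ... unused.
#' @return a \code{point_cloud}.
#' @export
as_point_cloud <- function(x, ...) {
  if (inherits(x, "point_cloud")) return(x)
  point_cloud(x)
}

# Internal: extract the coordinate matrix from cloud-or-matrix input.
cloud_matrix <- function(x) {
  if (inherits(x, "point_cloud")) x$points else as_point_cloud(x)$points
}
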