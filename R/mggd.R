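#' Multivariate generalized Gaussian component
#'
#' Defines one multivariate generalized Gaussian distribution (MGGD) with
#' density
#' \deqn{p(x) = \frac{\beta\,\Gamma(d/2)}
#'   {\Gamma(d/(2\beta))\,\pi^{d/2}\,2^{d/(2\beta)}\,m^{d/2}\,|\Sigma|^{1/2}}
#'   \exp\!\left(-\frac{[(x-\mu)^\top\Sigma^{-1}(x-\mu)]^\beta}{2 m^\beta}\right)}
#' where \eqn{\mu} is the mean, \eqn{\Sigma} the scatter matrix, \eqn{m > 0}
#' the scale and \eqn{\beta > 0} the shape.  \eqn{\beta = 1} recovers the
#' multivariate Gaussian with covariance \eqn{m\Sigma}; \eqn{\beta < 1} gives a
#' sharper peak and heavier tails.  Only the product \eqn{C = m\Sigma} is
#' identifiable in the density.
#'
#' @param mean numeric length-d mean vector.
#' @param scatter d x d symmetric positive-definite scatter matrix.
#' @param shape positive shape parameter beta (estimation assumes beta <= 1).
#' @param scale positive scale parameter m.
#' @return An object of class \code{mggd_component}.
#' @export
mggd_component <- function(mean, scatter, shape = 1, scale = 1) {
  mean <- as.numeric(mean)
  scatter <- as.matrix(scatter)
  d <- length(mean)
  if (!all(dim(scatter) == d)) stop("scatter must be d x d")
  if (max(abs(scatter - t(scatter))) >
      1e-8 * max(1, max(abs(scatter))))
    stop("scatter must be symmetric")
  scatter <- (scatter + t(scatter)) / 2
  R <- tryCatch(chol(scatter), error = function(e) NULL)
  if (is.null(R)) stop("scatter must be positive definite")
  if (!is.finite(shape) || shape <= 0) stop("shape must be > 0")
  if (!is.finite(scale) || scale <= 0) stop("scale must be > 0")
  structure(list(mean = mean, scatter = scatter, shape = shape,
                 scale = scale, dim = d,
                 chol = R, logdet = 2 * sum(log(diag(R)))),
            class = "mggd_component")
}

#' @export
print.mggd_component <- function(x, ...) {
  cat(sprintf("MGGD component (d = %d): beta = %.3g, m = %.3g\n",
              x$dim, x$shape, x$scale))
  cat("mean:", format(x$mean, digits = 4), "\n")
  invisible(x)
}

# Squared Mahalanobis distances of the rows of X from comp's mean, under
# comp's scatter.  Clamped below at 1e-12: y^(beta-1) diverges at y = 0 for
# beta < 1 (removable measure-zero singularity).
mahalanobis_sq <- function(X, comp, clamp = TRUE) {
  X <- as.matrix(X)
  if (ncol(X) != comp$dim) stop("dimension mismatch between points and component")
  Xc <- sweep(X, 2L, comp$mean)
  Z <- backsolve(comp$chol, t(Xc), transpose = TRUE)
  y <- colSums(Z^2)
  if (clamp) y <- pmax(y, 1e-12)
  y
}

# beta/m-free part of the MGGD log normalizing constant.
mggd_logconst <- function(d, beta) {
  log(beta) + lgamma(d / 2) - lgamma(d / (2 * beta)) -
    (d / 2) * log(pi) - (d / (2 * beta)) * log(2)
}

#' MGGD density
#'
#' Evaluates the MGGD density at one point or at each row of a matrix.
#' Computed in log space internally so that \eqn{|\Sigma|^{-1/2}} and the
#' Gamma-function ratios cannot under- or overflow.
#'
#' @param x numeric length-d vector, or an N x d matrix (one point per row).
#' @param comp an \code{\link{mggd_component}}.
#' @param log logical; return log density?
#' @return numeric vector of (log) density values, strictly positive for
#'   finite input on the natural scale.
#' @export
dmggd <- function(x, comp, log = FALSE) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  d <- comp$dim
  beta <- comp$shape
  y <- mahalanobis_sq(X, comp)
  lp <- mggd_logconst(d, beta) - (d / 2) * log(comp$scale) -
    comp$logdet / 2 - y^beta / (2 * comp$scale^beta)
  if (log) lp else exp(lp)
}

#' Weighted MGGD density
#'
#' Density of an observation carrying weight \eqn{w}: the weighted likelihood
#' \eqn{p(x)^w} is proportional to the MGGD density with scale
#' \eqn{m\,w^{-1/\beta}}, which is what this function evaluates (a proper
#' density in x).  For \eqn{w = 1} it equals \code{\link{dmggd}}.
#'
#' @param x vector or matrix of points as in \code{\link{dmggd}}.
#' @param comp an \code{\link{mggd_component}}.
#' @param w positive weight(s); scalar or one per row of \code{x}.
#' @param log logical; return log density?
#' @return numeric vector of (log) density values.
#' @export
dmggd_weighted <- function(x, comp, w, log = FALSE) {
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive")
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  d <- comp$dim
  beta <- comp$shape
  y <- mahalanobis_sq(X, comp)
  lp <- mggd_logconst(d, beta) - (d / 2) * log(comp$scale) -
    comp$logdet / 2 + (d / (2 * beta)) * log(w) -
    w * y^beta / (2 * comp$scale^beta)
  if (log) lp else exp(lp)
}

#' Gamma-marginalized MGGD density
#'
#' Closed form of \eqn{\int \hat p(x;\theta,w)\,\mathcal G(w;a,b)\,dw}: the
#' heavy-tailed density obtained when the observation weight is a
#' Gamma(\eqn{a}, rate \eqn{b}) random variable,
#' \deqn{\bar p(x) = \frac{\beta\,\Gamma(d/2)\,\Gamma(a + d/(2\beta))}
#'   {(m\pi)^{d/2} (2b)^{d/(2\beta)} |\Sigma|^{1/2}\,\Gamma(a)\,\Gamma(d/(2\beta))}
#'   \left(\frac{y^\beta}{2 b m^\beta} + 1\right)^{-(a + d/(2\beta))}}
#' with \eqn{y = (x-\mu)^\top\Sigma^{-1}(x-\mu)}.
#'
#' @param x vector or matrix of points.
#' @param comp an \code{\link{mggd_component}}.
#' @param a,b positive Gamma prior parameters (scalar or one per row).
#' @param log logical; return log density?
#' @return numeric vector of (log) density values.
#' @export
dmggd_marginal <- function(x, comp, a, b, log = FALSE) {
  if (any(!is.finite(a)) || any(a <= 0) || any(!is.finite(b)) || any(b <= 0))
    stop("Gamma prior parameters 'a' and 'b' must be positive")
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  d <- comp$dim
  beta <- comp$shape
  m <- comp$scale
  y <- mahalanobis_sq(X, comp)
  apost <- a + d / (2 * beta)
  lp <- log(beta) + lgamma(d / 2) + lgamma(apost) -
    (d / 2) * log(m * pi) - (d / (2 * beta)) * log(2 * b) -
    comp$logdet / 2 - lgamma(a) - lgamma(d / (2 * beta)) -
    apost * log1p(y^beta / (2 * b * m^beta))
  if (log) lp else exp(lp)
}

#' Sample from an MGGD
#'
#' Stochastic representation \eqn{x = \mu + \tau\, C^{1/2} u} with
#' \eqn{C = m\Sigma}, \eqn{u} uniform on the unit d-sphere and
#' \eqn{\tau^{2\beta} \sim \mathrm{Gamma}(d/(2\beta), \mathrm{scale} = 2)}.
#' The symmetric (eigendecomposition) matrix square root is used; the sampled
#' law is invariant to that choice.
#'
#' @param n number of draws.
#' @param comp an \code{\link{mggd_component}}.
#' @param seed optional integer seed for reproducibility.
#' @return a \code{\link{point_cloud}} with n points.
#' @export
rmggd <- function(n, comp, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  d <- comp$dim
  beta <- comp$shape
  C <- comp$scale * comp$scatter
  Chalf <- sym_sqrt(C)
  G <- matrix(stats::rnorm(n * d), n, d)
  u <- G / sqrt(rowSums(G^2))
  tau <- stats::rgamma(n, shape = d / (2 * beta), scale = 2)^(1 / (2 * beta))
  X <- sweep(tau * (u %*% Chalf), 2L, comp$mean, `+`)
  point_cloud(X)
}

# Symmetric positive-definite matrix square root.
sym_sqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (any(e$values <= 0)) stop("matrix is not positive definite")
  e$vectors %*% (sqrt(e$values) * t(e$vectors))
}

#' Correlation coefficient of a 2-D component
#'
#' Off-diagonal correlation \eqn{\rho = C_{12}/\sqrt{C_{11} C_{22}}} of the
#' full scatter \eqn{C = m\Sigma} (invariant to m), used to summarize the
#' orientation of a 2-D component.
#'
#' @param comp an \code{\link{mggd_component}} with d = 2, or a 2 x 2 matrix.
#' @return correlation in [-1, 1].
#' @export
correlation_coefficient <- function(comp) {
  C <- if (inherits(comp, "mggd_component")) {
    if (comp$dim != 2) stop("correlation_coefficient is defined for d = 2 only")
    comp$scale * comp$scatter
  } else {
    C <- as.matrix(comp)
    if (!all(dim(C) == 2)) stop("correlation_coefficient is defined for d = 2 only")
    C
  }
  C[1, 2] / sqrt(C[1, 1] * C[2, 2])
}
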