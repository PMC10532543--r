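#' Finite MGGD mixture model
#'
#' @param weights_mix numeric simplex vector of mixing coefficients.
#' @param components list of \code{\link{mggd_component}} objects, one per
#'   mixing coefficient, all of the same dimension.
#' @return An object of class \code{mixture_model}.
#' @export
mixture_model <- function(weights_mix, components) {
  weights_mix <- as.numeric(weights_mix)
  if (length(weights_mix) != length(components))
    stop("one mixing coefficient per component required")
  if (any(weights_mix < 0)) stop("mixing coefficients must be >= 0")
  if (abs(sum(weights_mix) - 1) > 1e-10)
    stop("mixing coefficients must sum to 1")
  if (!all(vapply(components, inherits, TRUE, "mggd_component")))
    stop("components must be mggd_component objects")
  d <- components[[1L]]$dim
  if (!all(vapply(components, function(cc) cc$dim, 0L) == d))
    stop("all components must share the same dimension")
  structure(list(weights_mix = weights_mix, components = components,
                 K = length(components), dim = d),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("MGGD mixture: K = %d components in %d-D\n", x$K, x$dim))
  for (k in seq_len(x$K)) {
    ck <- x$components[[k]]
    cat(sprintf("  [%d] pi = %.4f  mean = (%s)  beta = %.3f  m = %.3f\n",
                k, x$weights_mix[k],
                paste(format(ck$mean, digits = 4), collapse = ", "),
                ck$shape, ck$scale))
  }
  invisible(x)
}

#' Mixture density
#'
#' @param x vector or N x d matrix of evaluation points.
#' @param model a \code{\link{mixture_model}}.
#' @param log logical; return log density (computed by log-sum-exp)?
#' @return numeric vector of (log) mixture density values.
#' @export
dmixture <- function(x, model, log = FALSE) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  lp <- component_logdens(X, model)
  lp <- sweep(lp, 2L, log(model$weights_mix), `+`)
  out <- logsumexp_rows(lp)
  if (log) out else exp(out)
}

# N x K matrix of per-component MGGD log densities.
component_logdens <- function(X, model) {
  vapply(model$components, function(cc) dmggd(X, cc, log = TRUE),
         numeric(nrow(X)))
}

logsumexp_rows <- function(L) {
  if (!is.matrix(L)) L <- matrix(L, nrow = 1L)
  mx <- apply(L, 1L, max)
  bad <- !is.finite(mx)
  mx[bad] <- 0
  out <- mx + log(rowSums(exp(L - mx)))
  out[bad] <- -Inf
  out
}

#' Sample from a mixture model
#'
#' Ancestral sampling: a component index is drawn from the mixing
#' coefficients, then a point from that component's MGGD.  This is exact
#' i.i.d. sampling from the finite mixture.
#'
#' @param model a \code{\link{mixture_model}}.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return a \code{\link{point_cloud}} with component indices as labels.
#' @export
sample_mixture <- function(model, n, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ks <- sample.int(model$K, n, replace = TRUE, prob = model$weights_mix)
  X <- matrix(0, n, model$dim)
  for (k in seq_len(model$K)) {
    idx <- which(ks == k)
    if (length(idx))
      X[idx, ] <- rmggd(length(idx), model$components[[k]])$points
  }
  point_cloud(X, labels = ks)
}
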