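#' Match fitted components to reference components
#'
#' Exact assignment minimizing the total Euclidean distance between matched
#' means, by brute-force search over permutations (fine for K <= 8, the
#' regime of this package).  Permutation-invariant: relabelling the fitted
#' components yields the same matching.
#'
#' @param fitted,reference \code{\link{mixture_model}}s with the same K (if
#'   K differs, the smaller set is matched into the larger).
#' @return integer vector \code{idx} such that fitted component
#'   \code{idx[j]} corresponds to reference component j (NA where the
#'   reference component is unmatched).
#' @export
match_components <- function(fitted, reference) {
  mf <- t(vapply(fitted$components, function(cc) cc$mean,
                 numeric(fitted$dim)))
  mr <- t(vapply(reference$components, function(cc) cc$mean,
                 numeric(reference$dim)))
  D <- as.matrix(stats::dist(rbind(mr, mf)))[seq_len(nrow(mr)),
                                             nrow(mr) + seq_len(nrow(mf)),
                                             drop = FALSE]
  kr <- nrow(mr); kf <- nrow(mf)
  if (kf > 8 && kr > 8) stop("component matching supports K <= 8")
  if (kr <= kf) {
    perms <- all_perms(kf)
    best <- NULL; best_cost <- Inf
    for (p in perms) {
      cost <- sum(D[cbind(seq_len(kr), p[seq_len(kr)])])
      if (cost < best_cost) { best_cost <- cost; best <- p[seq_len(kr)] }
    }
    best
  } else {
    perms <- all_perms(kr)
    best <- NULL; best_cost <- Inf
    for (p in perms) {
      cost <- sum(D[cbind(p[seq_len(kf)], seq_len(kf))])
      if (cost < best_cost) { best_cost <- cost; best <- p[seq_len(kf)] }
    }
    out <- rep(NA_integer_, kr)
    out[best] <- seq_len(kf)
    out
  }
}

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_perms(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Evaluate a fit against its generating specification
#'
#' Matches fitted components to the truth by mean distance and reports
#' per-component deltas of the identifiable quantities: mean (Euclidean),
#' mixing coefficient, shape, full scatter \eqn{C = m\Sigma} (Frobenius) and
#' 2-D correlation coefficient.
#'
#' @param fit a \code{\link{wmggmm_fit}} (or \code{mixture_model}).
#' @param spec a \code{\link{mixture_spec}} (or reference
#'   \code{mixture_model}).
#' @return list: \code{k_plus}, \code{matching}, and a data frame
#'   \code{deltas} with one row per matched reference component.
#' @export
evaluate_fit <- function(fit, spec) {
  model <- if (inherits(fit, "wmggmm_fit")) fit$model else fit
  truth <- if (inherits(spec, "mixture_spec")) spec$model else spec
  idx <- match_components(model, truth)
  rows <- lapply(seq_along(idx), function(j) {
    k <- idx[j]
    if (is.na(k)) return(data.frame(ref = j, fitted = NA, d_mean = NA,
                                    d_pi = NA, d_beta = NA, d_C = NA,
                                    d_rho = NA))
    cf <- model$components[[k]]; ct <- truth$components[[j]]
    Cf <- cf$scale * cf$scatter; Ct <- ct$scale * ct$scatter
    data.frame(ref = j, fitted = k,
               d_mean = sqrt(sum((cf$mean - ct$mean)^2)),
               d_pi = model$weights_mix[k] - truth$weights_mix[j],
               d_beta = cf$shape - ct$shape,
               d_C = sqrt(sum((Cf - Ct)^2)),
               d_rho = if (model$dim == 2)
                 correlation_coefficient(cf) - correlation_coefficient(ct)
               else NA_real_)
  })
  list(k_plus = model$K, matching = idx, deltas = do.call(rbind, rows))
}

#' Evaluate a registration run against ground truth
#'
#' Wraps \code{\link{registration_errors}} and flags convergence to the
#' 180-degree local optimum of near-symmetric scenes (absolute rotation
#' error above 90 degrees).
#'
#' @param result a \code{registration} object from
#'   \code{\link{register_clouds}}, or a \code{\link{rigid_transform}}.
#' @param truth the ground-truth \code{\link{rigid_transform}}.
#' @return list: the error fields of \code{\link{registration_errors}} plus
#'   \code{local_optimum}.
#' @export
evaluate_registration <- function(result, truth) {
  tf <- if (inherits(result, "registration")) result$transform else result
  err <- registration_errors(tf, truth)
  err$local_optimum <- err$rot_abs > pi / 2
  err
}
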