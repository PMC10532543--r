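#' Rigid transform
#'
#' A rotation plus translation, \eqn{x \mapsto R x + t}.  In 2-D the rotation
#' is parameterized by an angle \eqn{\alpha} with
#' \eqn{R = [[\cos\alpha, -\sin\alpha], [\sin\alpha, \cos\alpha]]}; in higher
#' dimensions a rotation matrix is supplied directly.
#'
#' @param angle rotation angle in radians (2-D).
#' @param translation numeric translation vector.
#' @param rotation optional d x d rotation matrix (orthogonal, det +1);
#'   overrides \code{angle} when given.
#' @return object of class \code{rigid_transform} with fields \code{angle}
#'   (2-D only, wrapped to (-pi, pi]), \code{rotation}, \code{translation}.
#' @export
rigid_transform <- function(angle = 0, translation = c(0, 0), rotation = NULL) {
  translation <- as.numeric(translation)
  d <- length(translation)
  if (is.null(rotation)) {
    if (d != 2) stop("angle parameterization requires d = 2")
    rotation <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  } else {
    rotation <- as.matrix(rotation)
    if (!all(dim(rotation) == d)) stop("rotation must be d x d")
    if (max(abs(crossprod(rotation) - diag(d))) > 1e-10)
      stop("rotation must be orthogonal")
    if (abs(det(rotation) - 1) > 1e-10)
      stop("rotation must have determinant +1")
  }
  ang <- if (d == 2) wrap_angle(atan2(rotation[2, 1], rotation[1, 1])) else NA_real_
  structure(list(angle = ang, rotation = rotation, translation = translation,
                 dim = d),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform (d = %d): angle = %.4f rad, t = (%s)\n",
              x$dim, x$angle, paste(format(x$translation, digits = 5),
                                    collapse = ", ")))
  invisible(x)
}

# Wrap an angle (difference) into (-pi, pi].
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  ifelse(a <= -pi, a + 2 * pi, a)
}

#' Invert or compose rigid transforms
#'
#' \code{tf_inverse(tf)} returns the inverse map; \code{tf_compose(b, a)}
#' returns the composition "a then b".
#'
#' @param tf,a,b rigid transforms.
#' @return a \code{\link{rigid_transform}}.
#' @export
tf_inverse <- function(tf) {
  rigid_transform(translation = -as.numeric(t(tf$rotation) %*% tf$translation),
                  rotation = t(tf$rotation))
}

#' @rdname tf_inverse
#' @export
tf_compose <- function(b, a) {
  rigid_transform(translation = as.numeric(b$rotation %*% a$translation) +
                    b$translation,
                  rotation = b$rotation %*% a$rotation)
}

#' Apply a rigid transform to a point cloud
#'
#' @param cloud a \code{\link{point_cloud}} or matrix.
#' @param tf a \code{\link{rigid_transform}}.
#' @return transformed \code{\link{point_cloud}}; weights and labels carried
#'   unchanged.
#' @export
transform_points <- function(cloud, tf) {
  cloud <- as_point_cloud(cloud)
  if (cloud$dim != tf$dim) stop("dimension mismatch")
  X <- sweep(cloud$points %*% t(tf$rotation), 2L, tf$translation, `+`)
  point_cloud(X, weights = cloud$weights, labels = cloud$labels)
}

#' Apply a rigid transform to a mixture model
#'
#' Transforms the mixture in closed form: \eqn{\mu' = R\mu + t},
#' \eqn{\Sigma' = R \Sigma R^\top}; shape, scale and mixing coefficients are
#' unchanged.  Because \eqn{|\det R| = 1}, the transformed mixture satisfies
#' the density identity \eqn{p'(Rx + t) = p(x)} pointwise, so registration
#' never needs to refit the mixture.
#'
#' @param model a \code{\link{mixture_model}}.
#' @param tf a \code{\link{rigid_transform}}.
#' @return transformed \code{\link{mixture_model}}.
#' @export
transform_model <- function(model, tf) {
  comps <- lapply(model$components, function(cc) {
    mggd_component(as.numeric(tf$rotation %*% cc$mean) + tf$translation,
                   tf$rotation %*% cc$scatter %*% t(tf$rotation),
                   cc$shape, cc$scale)
  })
  mixture_model(model$weights_mix, comps)
}

#' Monte-Carlo KL divergence between two mixtures
#'
#' \deqn{\mathrm{KLD}_{MC}(P_S \| P_M) = \frac1n \sum_i [\log P_S(x_i) -
#' \log P_M(x_i)]} over samples \eqn{x_i} drawn from \eqn{P_S}.  May be
#' negative for finite n (Monte-Carlo noise); it is not floored.  Sample log
#' densities under \eqn{P_M} that underflow are floored at -745 and counted
#' in the \code{"n_floored"} attribute.
#'
#' @param model_s,model_m source and target \code{\link{mixture_model}}s.
#' @param samples points drawn from \code{model_s} (cloud or matrix).
#' @param logp_s optional precomputed \code{log P_S(samples)} (constant
#'   across an optimization over transforms of \code{model_m}).
#' @return scalar divergence estimate with attribute \code{"n_floored"}.
#' @export
kld_mc <- function(model_s, model_m, samples, logp_s = NULL) {
  X <- cloud_matrix(samples)
  if (is.null(logp_s)) logp_s <- dmixture(X, model_s, log = TRUE)
  logp_m <- dmixture(X, model_m, log = TRUE)
  nfl <- sum(logp_m < -745)
  logp_m <- pmax(logp_m, -745)
  structure(mean(logp_s - logp_m), n_floored = nfl)
}

#' Registration configuration
#'
#' @param n_mc Monte-Carlo sample size for the KLD objective (default 1000).
#' @param sa_iters simulated-annealing iterations (default 500).
#' @param sa_temp0 initial temperature; \code{NULL} (default) calibrates it
#'   to half the magnitude of the initial objective value.
#' @param sa_cooling geometric cooling factor in (0, 1) (default 0.97).
#' @param proposal_scales optional numeric vector (angle, t_1, ..., t_d) of
#'   proposal standard deviations; default 5\% of the search bounds.
#' @param accept_rule \code{"metropolis"} (default; worsening moves accepted
#'   with probability \eqn{e^{-\Delta/T}}) or \code{"greedy"}.
#' @param polish run a deterministic Nelder-Mead refinement of the best
#'   transform on the frozen objective after annealing (default TRUE).
#' @param bounds_t optional half-width of the translation search box;
#'   default: the scene bounding-box diagonal.
#' @param seed optional integer seed.
#' @return list of class \code{registration_config}.
#' @export
registration_config <- function(n_mc = 1000L, sa_iters = 500L,
                                sa_temp0 = NULL, sa_cooling = 0.97,
                                proposal_scales = NULL,
                                accept_rule = c("metropolis", "greedy"),
                                polish = TRUE, bounds_t = NULL, seed = NULL) {
  accept_rule <- match.arg(accept_rule)
  stopifnot(n_mc >= 1, sa_cooling > 0, sa_cooling < 1, sa_iters >= 1)
  structure(list(n_mc = as.integer(n_mc), sa_iters = as.integer(sa_iters),
                 sa_temp0 = sa_temp0, sa_cooling = sa_cooling,
                 proposal_scales = proposal_scales,
                 accept_rule = accept_rule, polish = polish,
                 bounds_t = bounds_t, seed = seed),
            class = "registration_config")
}

# KLD objective over (alpha, tx, ty) for a frozen sample set.
kld_objective <- function(par, model_s, model_m, samples, logp_s) {
  tf <- rigid_transform(angle = wrap_angle(par[1]), translation = par[-1])
  as.numeric(kld_mc(model_s, transform_model(model_m, tf), samples, logp_s))
}

#' Rigid registration of two point clouds
#'
#' Fits a weighted MGGD mixture to the target scene and to the cloud to be
#' registered (each once), draws a frozen Monte-Carlo sample from the scene
#' mixture, and minimizes the Monte-Carlo KL divergence between the scene
#' mixture and the rigidly transformed model mixture over rotation angle and
#' translation by simulated annealing (transform applied to the mixture in
#' closed form -- no refitting).  Both clouds are pre-centered on their
#' kernel-weighted centroids, so annealing starts from the identity; the
#' centering is composed back into the returned transform.
#'
#' @param scene target scene \code{\link{point_cloud}}.
#' @param model_cloud cloud to be registered onto the scene.
#' @param em_config a \code{\link{wmggmm_config}} used for both fits.
#' @param reg_config a \code{\link{registration_config}}.
#' @return object of class \code{registration}: list with \code{transform}
#'   (model -> scene map), \code{kld} (final objective), \code{trace}
#'   (best-so-far objective per iteration), \code{fit_scene},
#'   \code{fit_model}, and \code{diagnostics}.
#' @export
register_clouds <- function(scene, model_cloud,
                            em_config = wmggmm_config(),
                            reg_config = registration_config()) {
  scene <- as_point_cloud(scene)
  model_cloud <- as_point_cloud(model_cloud)
  if (scene$dim != 2 || model_cloud$dim != 2)
    stop("rigid registration is implemented for 2-D clouds")
  if (!is.null(reg_config$seed)) set.seed(reg_config$seed)

  ws <- kernel_weights(scene, em_config$kernel_sigma, em_config$kernel_q)
  wm <- kernel_weights(model_cloud, em_config$kernel_sigma, em_config$kernel_q)
  c_s <- colSums(ws * scene$points) / sum(ws)
  c_m <- colSums(wm * model_cloud$points) / sum(wm)
  scene_c <- point_cloud(sweep(scene$points, 2L, c_s))
  model_c <- point_cloud(sweep(model_cloud$points, 2L, c_m))

  fit_s <- wmggmm_fit(scene_c, em_config)
  fit_m <- wmggmm_fit(model_c, em_config)

  samples <- sample_mixture(fit_s$model, reg_config$n_mc)
  logp_s <- dmixture(samples$points, fit_s$model, log = TRUE)

  diag_span <- sqrt(sum((apply(scene_c$points, 2, max) -
                           apply(scene_c$points, 2, min))^2))
  bt <- if (!is.null(reg_config$bounds_t)) reg_config$bounds_t else diag_span
  # proposal scales are matched to the objective's length scale: the angle
  # step is 5% of the angular range; the translation step is the average
  # fitted component radius (sqrt of mean scatter trace), the width of the
  # KLD basins -- after centroid pre-alignment the optimum is within a few
  # component radii of zero
  comp_radius <- mean(vapply(fit_s$model$components, function(cc)
    sqrt(sum(diag(cc$scale * cc$scatter)) / 2), 0))
  scales0 <- if (!is.null(reg_config$proposal_scales))
    reg_config$proposal_scales else
      c(0.05 * 2 * pi, rep(max(comp_radius, 0.02 * bt), 2))

  obj <- function(par) kld_objective(par, fit_s$model, fit_m$model,
                                     samples$points, logp_s)
  # initial transform: after centroid pre-alignment the translation is near
  # zero, so a coarse scan over the rotation angle locates the best basin
  # (both basins of a near-symmetric scene are evaluated and compared by
  # their KLD); annealing then starts from the scan's winner
  grid <- seq(-pi, pi, length.out = 25L)[-25L]
  g_obj <- vapply(grid, function(a) obj(c(a, 0, 0)), 0)
  par <- c(grid[which.min(g_obj)], 0, 0)
  f_cur <- min(g_obj)
  temp0 <- if (!is.null(reg_config$sa_temp0)) reg_config$sa_temp0 else
    0.5 * max(abs(f_cur), 0.2)
  temp <- temp0
  best_par <- par
  f_best <- f_cur
  trace <- numeric(reg_config$sa_iters)
  n_accept_worse <- 0L
  for (it in seq_len(reg_config$sa_iters)) {
    sc <- scales0 * max(temp / temp0, 0.05)
    # coordinate-wise proposal: perturb one parameter at a time, so an
    # angle move can find its basin while the translation stays put
    j <- sample.int(3L, 1L)
    cand <- par
    cand[j] <- cand[j] + stats::rnorm(1) * sc[j]
    cand[1] <- wrap_angle(cand[1])
    cand[2:3] <- pmin(pmax(cand[2:3], -bt), bt)
    f_cand <- obj(cand)
    delta <- f_cand - f_cur
    accept <- if (delta <= 0) TRUE else if (reg_config$accept_rule ==
                                            "metropolis") {
      stats::runif(1) < exp(-delta / temp)
    } else FALSE
    if (accept && delta > 0) n_accept_worse <- n_accept_worse + 1L
    if (accept) { par <- cand; f_cur <- f_cand }
    if (f_cur < f_best) { best_par <- par; f_best <- f_cur }
    trace[it] <- f_best
    temp <- temp * reg_config$sa_cooling
  }

  if (isTRUE(reg_config$polish)) {
    op <- stats::optim(best_par, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-10, maxit = 400))
    if (op$value <= f_best) { best_par <- op$par; f_best <- op$value }
  }

  R <- rigid_transform(angle = wrap_angle(best_par[1]),
                       translation = best_par[2:3])
  # compose the centroid pre-alignment back in:
  # x_scene = R (x_model - c_m) + t + c_s
  full <- rigid_transform(angle = R$angle,
                          translation = R$translation + c_s -
                            as.numeric(R$rotation %*% c_m))
  structure(list(transform = full, kld = f_best, trace = trace,
                 fit_scene = fit_s, fit_model = fit_m,
                 diagnostics = list(temp0 = temp0,
                                    n_accept_worse = n_accept_worse,
                                    centroids = list(scene = c_s,
                                                     model = c_m),
                                    seed = reg_config$seed)),
            class = "registration")
}

#' @export
print.registration <- function(x, ...) {
  cat(sprintf("registration: KLD = %.4f\n", x$kld))
  print(x$transform)
  invisible(x)
}

#' Rotational and translational registration errors
#'
#' Relative errors mirror the percent-error reporting convention:
#' \code{rot_rel = |wrap(angle_est - angle_true)| / |angle_true|} and
#' \code{trans_rel = ||t_est - t_true|| / ||t_true||}; absolute variants are
#' always included.  If the true angle (or translation) is zero, the
#' corresponding relative error is returned as NA with \code{degenerate =
#' TRUE}.
#'
#' @param estimated,truth \code{\link{rigid_transform}}s.
#' @return list: rot_abs (radians), trans_abs, rot_rel, trans_rel,
#'   degenerate.
#' @export
registration_errors <- function(estimated, truth) {
  rot_abs <- abs(wrap_angle(estimated$angle - truth$angle))
  trans_abs <- sqrt(sum((estimated$translation - truth$translation)^2))
  deg <- FALSE
  rot_rel <- if (abs(truth$angle) > 0) rot_abs / abs(truth$angle) else {
    deg <- TRUE; NA_real_
  }
  tnorm <- sqrt(sum(truth$translation^2))
  trans_rel <- if (tnorm > 0) trans_abs / tnorm else { deg <- TRUE; NA_real_ }
  list(rot_abs = rot_abs, trans_abs = trans_abs,
       rot_rel = rot_rel, trans_rel = trans_rel, degenerate = deg)
}
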