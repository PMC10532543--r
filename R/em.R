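#' EM configuration for WMGGMM fitting
#'
#' Collects every tunable of the weighted-data EM algorithm.  Defaults follow
#' the method's stated settings (beta initialized at 0.5, Gaussian-kernel
#' weight initialization with q = 20 neighbours and sigma = 25, Newton
#' learning rate 0.1) plus numerical tolerances chosen once for this package.
#'
#' @param k_max maximum number of mixture components to start from.
#' @param beta_init initial shape parameter in (0, 1].
#' @param kernel_sigma,kernel_q Gaussian-kernel weight parameters.
#' @param newton_rate damped Newton learning rate xi for the shape update.
#' @param fp_tol,fp_max_iter fixed-point (mu, Sigma) stopping rule:
#'   Frobenius/Euclidean change below \code{fp_tol} or \code{fp_max_iter}
#'   iterations.
#' @param newton_tol,newton_max_iter Newton stopping rule for beta.
#' @param mml_tol absolute EM stopping tolerance on the MML change; if
#'   \code{NULL} (default) it is set to \code{1e-4 * |MML|} of the first sweep.
#' @param em_max_iter maximum number of component-wise EM sweeps.
#' @param weight_mode \code{"bayesian"} (Gamma-posterior random weights, the
#'   default) or \code{"fixed"} (weights held at their initial values).
#' @param seed optional integer seed used for k-means initialization.
#' @return a list of class \code{wmggmm_config}.
#' @export
wmggmm_config <- function(k_max = 8L, beta_init = 0.5,
                          kernel_sigma = 25, kernel_q = 20L,
                          newton_rate = 0.1,
                          fp_tol = 1e-6, fp_max_iter = 100L,
                          newton_tol = 1e-5, newton_max_iter = 50L,
                          mml_tol = NULL, em_max_iter = 200L,
                          weight_mode = c("bayesian", "fixed"),
                          weight_clamp = TRUE, seed = NULL) {
  weight_mode <- match.arg(weight_mode)
  if (beta_init <= 0 || beta_init > 1) stop("beta_init must be in (0, 1]")
  stopifnot(fp_tol > 0, newton_tol > 0, kernel_sigma > 0, k_max >= 1)
  structure(list(k_max = as.integer(k_max), beta_init = beta_init,
                 kernel_sigma = kernel_sigma, kernel_q = as.integer(kernel_q),
                 newton_rate = newton_rate,
                 fp_tol = fp_tol, fp_max_iter = as.integer(fp_max_iter),
                 newton_tol = newton_tol,
                 newton_max_iter = as.integer(newton_max_iter),
                 mml_tol = mml_tol, em_max_iter = as.integer(em_max_iter),
                 weight_mode = weight_mode, weight_clamp = weight_clamp,
                 seed = seed),
            class = "wmggmm_config")
}

# Free parameters per component: d (mean) + d(d+1)/2 (scatter) + 2 (shape,
# scale).  For d = 2 this is M = 7.
params_per_component <- function(d) as.integer(d + d * (d + 1) / 2 + 2)

#' Initialize a WMGGMM fit
#'
#' k-means pre-clustering seeds the mixing coefficients (cluster fractions),
#' means (centroids) and scatters (within-cluster covariance, ridge
#' regularized); all shapes start at \code{beta_init} and each scale is set to
#' its maximizer given the cluster points, \eqn{m_k = [\beta/(d N_k) \sum_i
#' y_i^\beta]^{1/\beta}}.  Observation weights come from
#' \code{\link{kernel_weights}} and seed the Gamma priors \eqn{a_i = w_i^2,
#' b_i = w_i} (so the prior weight mean is \eqn{w_i} and its variance 1).
#'
#' @param cloud a \code{\link{point_cloud}}.
#' @param config a \code{\link{wmggmm_config}}.
#' @return list with elements \code{model} (a \code{\link{mixture_model}}),
#'   \code{wstate} (weight state: a0, b0, a_post, b_post, w_bar) and
#'   \code{weights} (the kernel weights).
#' @export
init_model <- function(cloud, config = wmggmm_config()) {
  cloud <- as_point_cloud(cloud)
  X <- cloud$points
  n <- cloud$n
  d <- cloud$dim
  kmax <- config$k_max
  # cap 1: enough points per component to estimate a scatter; cap 2: the
  # minimum-support annihilation threshold M*K/2 must stay below the average
  # support N/K, or every component dies on the first sweep
  cap <- min(floor(n / (d + 1)),
             max(1, floor(sqrt(2 * n / params_per_component(d)))))
  if (kmax > cap) {
    kmax <- max(1L, cap)
    warning(sprintf("too few points for k_max = %d; reduced to %d",
                    config$k_max, kmax))
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  km <- NULL
  for (try in 1:5) {
    km <- tryCatch(stats::kmeans(X, centers = kmax, nstart = 10, iter.max = 50),
                   error = function(e) NULL)
    if (!is.null(km) && all(tabulate(km$cluster, kmax) > 0)) break
    km <- NULL
  }
  if (is.null(km)) stop("k-means initialization failed (empty clusters)")

  comps <- vector("list", kmax)
  pi0 <- numeric(kmax)
  for (k in seq_len(kmax)) {
    idx <- which(km$cluster == k)
    pi0[k] <- length(idx) / n
    mu <- km$centers[k, ]
    Xk <- X[idx, , drop = FALSE]
    Sigma <- if (length(idx) > d) stats::cov(Xk) else diag(apply(X, 2, stats::var))
    Sigma <- Sigma + (1e-6 * sum(diag(Sigma)) / d + 1e-10) * diag(d)
    comp <- mggd_component(mu, Sigma, shape = config$beta_init, scale = 1)
    y <- mahalanobis_sq(Xk, comp)
    b <- config$beta_init
    m <- (b / (d * length(idx)) * sum(y^b))^(1 / b)
    comps[[k]] <- mggd_component(mu, Sigma, shape = b, scale = m)
  }
  model <- mixture_model(pi0, comps)

  w <- kernel_weights(cloud, sigma = config$kernel_sigma,
                      q = min(config$kernel_q, n - 1L))
  wstate <- list(a0 = w^2, b0 = w,
                 a_post = matrix(w^2, n, kmax),
                 b_post = matrix(w, n, kmax),
                 w_bar = matrix(pmin(w, 1), n, kmax))
  list(model = model, wstate = wstate, weights = w)
}

#' E-Z step: posterior component responsibilities
#'
#' In Bayesian weight mode, \eqn{\eta_{ik} \propto \pi_k\,\bar p(x_i;
#' \theta_k, a_{ik}, b_{ik})} using the Gamma-marginalized density; in fixed
#' mode, \eqn{\eta_{ik} \propto \pi_k\,\hat p(x_i; \theta_k, w_i)}.  Rows are
#' normalized by log-sum-exp; a fully underflowed row is set uniform over the
#' active components and counted.
#'
#' @param cloud a \code{\link{point_cloud}}.
#' @param model a \code{\link{mixture_model}} (zero mixing coefficients mark
#'   annihilated components).
#' @param wstate weight state from \code{\link{init_model}}/\code{\link{e_w_step}}.
#' @param config a \code{\link{wmggmm_config}}.
#' @param fixed_w optional fixed weights (length N) for fixed mode.
#' @return N x K responsibility matrix with attribute \code{"n_underflow"}.
#' @export
e_z_step <- function(cloud, model, wstate, config = wmggmm_config(),
                     fixed_w = NULL) {
  cloud <- as_point_cloud(cloud)
  X <- cloud$points
  n <- cloud$n
  K <- model$K
  lp <- matrix(-Inf, n, K)
  active <- which(model$weights_mix > 0)
  for (k in active) {
    comp <- model$components[[k]]
    lk <- if (config$weight_mode == "bayesian") {
      dmggd_marginal(X, comp, wstate$a_post[, k], wstate$b_post[, k], log = TRUE)
    } else {
      w <- if (!is.null(fixed_w)) fixed_w else
        if (!is.null(cloud$weights)) cloud$weights else rep(1, n)
      dmggd_weighted(X, comp, w, log = TRUE)
    }
    lp[, k] <- log(model$weights_mix[k]) + lk
  }
  tot <- logsumexp_rows(lp)
  bad <- !is.finite(tot)
  eta <- exp(lp - ifelse(is.finite(tot), tot, 0))
  if (any(bad)) {
    eta[bad, ] <- 0
    eta[bad, active] <- 1 / length(active)
  }
  attr(eta, "n_underflow") <- sum(bad)
  eta
}

#' E-W step: Gamma posterior of the observation weights
#'
#' Conjugate update of each point's weight posterior given assignment to
#' component k: \eqn{a_{ik} = a_i^{(0)} + d/(2\beta_k)}, \eqn{b_{ik} =
#' b_i^{(0)} + y_{ik}^{\beta_k} / (2 m_k^{\beta_k})} with \eqn{y_{ik}} the
#' squared Mahalanobis distance.  The posterior mean \eqn{\bar w_{ik} =
#' a_{ik}/b_{ik}} is clamped to (0, 1], the range required for fixed-point
#' convergence; clamping is monotone, so outliers keep strictly smaller
#' weights than in-cluster points.
#'
#' @inheritParams e_z_step
#' @return updated weight state.
#' @export
e_w_step <- function(cloud, model, wstate, clamp = TRUE) {
  cloud <- as_point_cloud(cloud)
  X <- cloud$points
  d <- cloud$dim
  for (k in which(model$weights_mix > 0)) {
    comp <- model$components[[k]]
    y <- mahalanobis_sq(X, comp)
    wstate$a_post[, k] <- wstate$a0 + d / (2 * comp$shape)
    wstate$b_post[, k] <- wstate$b0 + y^comp$shape / (2 * comp$scale^comp$shape)
    wb <- wstate$a_post[, k] / wstate$b_post[, k]
    wstate$w_bar[, k] <- if (clamp) pmin(wb, 1) else wb
  }
  wstate
}

#' M step for the mixing coefficients with MML annihilation
#'
#' \eqn{\pi_k = \max(0, \sum_i \eta_{ik} - M K^+/2) / \sum_l \max(0, \sum_i
#' \eta_{il} - M K^+/2)}: components whose responsibility mass falls below
#' half the per-component parameter count times the number of live components
#' are annihilated (mixing coefficient exactly zero).
#'
#' @param eta N x K responsibility matrix.
#' @param k_plus current number of non-empty components.
#' @param M free parameters per component (see
#'   \code{\link{wmggmm_fit}}; M = 7 for d = 2).
#' @param active optional indices of currently non-empty components; columns
#'   outside it are forced to zero.
#' @return simplex vector of length K.
#' @export
m_step_pi <- function(eta, k_plus, M, active = NULL) {
  support <- colSums(eta)
  if (!is.null(active)) support[-active] <- 0
  num <- pmax(0, support - M * k_plus / 2)
  if (sum(num) == 0)
    stop("model collapse: no component retains the minimum support ",
         "(k_max too large for this sample size)")
  num / sum(num)
}

#' Fixed-point update of a component mean
#'
#' Iterates \eqn{\mu \leftarrow \sum_i r_i y_i^{\beta-1} x_i / \sum_i r_i
#' y_i^{\beta-1}} with \eqn{r_i = \eta_{ik} w_i} and y recomputed each pass,
#' until the Euclidean change drops below \code{fp_tol}.  For \eqn{\beta = 1}
#' this is the plain weighted mean in one step.
#'
#' @param cloud a \code{\link{point_cloud}}.
#' @param comp current component (supplies Sigma, beta).
#' @param eta_k,w_k responsibilities and weights for this component.
#' @param fp_tol,fp_max_iter stopping rule.
#' @return converged mean with attribute \code{"converged"}.
#' @export
update_mu <- function(cloud, comp, eta_k, w_k, fp_tol = 1e-6,
                      fp_max_iter = 100L) {
  X <- cloud_matrix(cloud)
  r <- eta_k * w_k
  if (sum(eta_k) <= 0) stop("component has no responsibility mass")
  mu <- comp$mean
  beta <- comp$shape
  Sinv <- chol2inv(chol(comp$scatter))
  conv <- FALSE
  for (it in seq_len(fp_max_iter)) {
    Xc <- sweep(X, 2L, mu)
    y <- pmax(rowSums((Xc %*% Sinv) * Xc), 1e-12)
    u <- r * y^(beta - 1)
    mu_new <- colSums(u * X) / sum(u)
    delta <- sqrt(sum((mu_new - mu)^2))
    mu <- mu_new
    if (delta < fp_tol) { conv <- TRUE; break }
  }
  structure(mu, converged = conv)
}

#' Fixed-point update of a component scatter matrix
#'
#' Iterates the scale-free map \eqn{\Sigma \leftarrow d \sum_i r_i
#' y_i^{\beta-1} (x_i-\mu)(x_i-\mu)^\top / \sum_i r_i y_i^{\beta}} (y from the
#' current Sigma), symmetrizing each pass, until the Frobenius change drops
#' below \code{fp_tol}.  Convergence for \eqn{\beta \in (0,1]} and weights in
#' (0,1] follows from the contraction property of this map.  An iterate
#' losing positive definiteness is ridged by \code{1e-8 * trace/d}.
#'
#' @inheritParams update_mu
#' @param mu mean to center on (defaults to the component's).
#' @return SPD matrix with attribute \code{"converged"}.
#' @export
update_sigma <- function(cloud, comp, eta_k, w_k, fp_tol = 1e-6,
                         fp_max_iter = 100L, mu = NULL) {
  X <- cloud_matrix(cloud)
  d <- ncol(X)
  if (is.null(mu)) mu <- comp$mean
  r <- eta_k * w_k
  beta <- comp$shape
  Sigma <- comp$scatter
  Xc <- sweep(X, 2L, mu)
  conv <- FALSE
  for (it in seq_len(fp_max_iter)) {
    Sinv <- chol2inv(chol(Sigma))
    y <- pmax(rowSums((Xc %*% Sinv) * Xc), 1e-12)
    u <- r * y^(beta - 1)
    num <- crossprod(Xc * sqrt(u))
    den <- sum(r * y^beta)
    S_new <- d * num / den
    S_new <- (S_new + t(S_new)) / 2
    if (inherits(tryCatch(chol(S_new), error = function(e) e), "error"))
      S_new <- S_new + (1e-8 * sum(diag(S_new)) / d + 1e-12) * diag(d)
    delta <- sqrt(sum((S_new - Sigma)^2))
    Sigma <- S_new
    if (delta < fp_tol) { conv <- TRUE; break }
  }
  structure(Sigma, converged = conv)
}

#' Closed-form update of a component scale
#'
#' \eqn{m = [\beta \sum_i r_i y_i^\beta / (d \sum_i \eta_{ik})]^{1/\beta}}
#' with \eqn{r_i = \eta_{ik} w_i}, given the current mean, scatter and shape.
#'
#' @inheritParams update_sigma
#' @return positive scale.
#' @export
update_m <- function(cloud, comp, eta_k, w_k) {
  X <- cloud_matrix(cloud)
  d <- ncol(X)
  y <- mahalanobis_sq(X, comp)
  beta <- comp$shape
  (beta * sum(eta_k * w_k * y^beta) / (d * sum(eta_k)))^(1 / beta)
}

# Profile objective in beta for one component: the component's share of the
# expected complete-data log-likelihood with the scale m replaced by its
# closed-form maximizer (beta-free terms dropped).  A = sum eta,
# Lw = sum eta log w, S0 = sum r y^beta with r = eta * w.
beta_profile_q <- function(beta, d, A, Lw, y, r) {
  S0 <- sum(r * y^beta)
  A * log(beta) + (d / (2 * beta)) * Lw - A * lgamma(d / (2 * beta)) -
    A * (d / (2 * beta)) * log(2) -
    A * (d / (2 * beta)) * log(beta * S0 / (d * A)) - d * A / (2 * beta)
}

# Score f(beta) = d/dbeta of the profile objective, and its derivative
# f'(beta).  Derived analytically; verified in the tests against a
# central-difference oracle on the profile Q.
beta_score <- function(beta, d, A, Lw, y, r) {
  yb <- r * y^beta
  ly <- log(y)
  S0 <- sum(yb)
  S1 <- sum(yb * ly)
  S2 <- sum(yb * ly^2)
  G <- -Lw + A * (digamma(d / (2 * beta)) + log(2) + log(beta) +
                    log(S0) - log(d * A))
  f <- A / beta + (d / (2 * beta^2)) * G - (d * A / (2 * beta)) * S1 / S0
  Gp <- A * (-d / (2 * beta^2) * trigamma(d / (2 * beta)) + 1 / beta + S1 / S0)
  fp <- -A / beta^2 - (d / beta^3) * G + (d / (2 * beta^2)) * Gp +
    (d * A / (2 * beta^2)) * S1 / S0 -
    (d * A / (2 * beta)) * (S2 * S0 - S1^2) / S0^2
  list(f = f, fp = fp)
}

#' Damped Newton-Raphson update of a component shape
#'
#' Maximizes the component's expected complete-data log-likelihood profiled
#' over the scale m, by damped Newton iterations \eqn{\beta \leftarrow \beta -
#' \xi f(\beta)/f'(\beta)} on the score \eqn{f = \partial Q/\partial\beta}.
#' The learning rate \eqn{\xi} (default 0.1) is halved whenever \eqn{|f|}
#' grows between iterates; the iterate is clamped to [0.05, 1], the regime in
#' which the fixed-point scatter iteration is a contraction.
#'
#' @inheritParams update_sigma
#' @param config a \code{\link{wmggmm_config}} (newton_rate, newton_tol,
#'   newton_max_iter).
#' @return shape in [0.05, 1] with attributes \code{"converged"} and
#'   \code{"score"} (final f value).
#' @export
update_beta <- function(cloud, comp, eta_k, w_k, config = wmggmm_config()) {
  X <- cloud_matrix(cloud)
  d <- ncol(X)
  y <- mahalanobis_sq(X, comp)
  r <- eta_k * w_k
  A <- sum(eta_k)
  Lw <- sum(eta_k * log(w_k))
  beta <- comp$shape
  xi <- config$newton_rate
  sc <- beta_score(beta, d, A, Lw, y, r)
  best_beta <- beta
  best_f <- abs(sc$f)
  conv <- FALSE
  for (it in seq_len(config$newton_max_iter)) {
    if (abs(sc$fp) < 1e-12) { xi <- xi / 2; next }
    beta_new <- beta - xi * sc$f / sc$fp
    beta_new <- min(max(beta_new, 0.05), 1)
    delta <- abs(beta_new - beta)
    sc_new <- beta_score(beta_new, d, A, Lw, y, r)
    # decay the rate when |f| grows (oscillation guard), relax it toward the
    # undamped step while the score keeps shrinking
    if (abs(sc_new$f) > abs(sc$f)) xi <- xi / 2 else xi <- min(1, xi * 1.5)
    beta <- beta_new
    sc <- sc_new
    if (abs(sc$f) < best_f) { best_beta <- beta; best_f <- abs(sc$f) }
    if (delta < config$newton_tol) { conv <- TRUE; break }
  }
  if (!conv) beta <- best_beta
  structure(beta, converged = conv, score = sc$f)
}

#' Expected complete-data log-likelihood (Q function)
#'
#' \deqn{Q = \sum_{i,k} \eta_{ik}\Big[\ln\pi_k + \ln\beta_k +
#' \tfrac{d}{2\beta_k}\ln \bar w_{ik} - \ln\Gamma(\tfrac{d}{2\beta_k}) -
#' \tfrac{d}{2\beta_k}\ln 2 - \tfrac{d}{2}\ln m_k - \tfrac12\ln|\Sigma_k| -
#' \bar w_{ik}\, y_{ik}^{\beta_k} / (2 m_k^{\beta_k})\Big]}
#' with the posterior mean weights \eqn{\bar w_{ik}} (Bayesian mode) or the
#' fixed weights \eqn{w_i} in their place.  Only non-empty components
#' contribute.
#'
#' @inheritParams e_z_step
#' @param eta N x K responsibility matrix.
#' @return scalar Q value.
#' @export
q_function <- function(cloud, model, wstate, eta,
                       config = wmggmm_config(), fixed_w = NULL) {
  cloud <- as_point_cloud(cloud)
  X <- cloud$points
  d <- cloud$dim
  total <- 0
  for (k in which(model$weights_mix > 0)) {
    comp <- model$components[[k]]
    beta <- comp$shape
    m <- comp$scale
    wk <- if (config$weight_mode == "bayesian") wstate$w_bar[, k] else {
      if (!is.null(fixed_w)) fixed_w else
        if (!is.null(cloud$weights)) cloud$weights else rep(1, cloud$n)
    }
    y <- mahalanobis_sq(X, comp)
    terms <- log(model$weights_mix[k]) + log(beta) +
      (d / (2 * beta)) * log(wk) - lgamma(d / (2 * beta)) -
      (d / (2 * beta)) * log(2) - (d / 2) * log(m) - comp$logdet / 2 -
      wk * y^beta / (2 * m^beta)
    total <- total + sum(eta[, k] * terms)
  }
  total
}

#' Observed-data log-likelihood of the weighted mixture
#'
#' \eqn{\sum_i \ln \sum_k \pi_k \bar p(x_i; \theta_k, a_i^{(0)}, b_i^{(0)})}
#' in Bayesian mode (weights marginalized under their prior), or the
#' weighted-density mixture likelihood in fixed mode.  This is the data-fit
#' term of the MML criterion: unlike the weighted complete-data Q it is
#' comparable across models with different numbers of components.
#'
#' @inheritParams e_z_step
#' @return scalar log-likelihood.
#' @export
observed_loglik <- function(cloud, model, wstate, config = wmggmm_config(),
                            fixed_w = NULL) {
  cloud <- as_point_cloud(cloud)
  X <- cloud$points
  active <- which(model$weights_mix > 0)
  lp <- matrix(-Inf, cloud$n, length(active))
  for (j in seq_along(active)) {
    k <- active[j]
    comp <- model$components[[k]]
    lk <- if (config$weight_mode == "bayesian") {
      dmggd_marginal(X, comp, wstate$a0, wstate$b0, log = TRUE)
    } else {
      w <- if (!is.null(fixed_w)) fixed_w else
        if (!is.null(cloud$weights)) cloud$weights else rep(1, cloud$n)
      dmggd_weighted(X, comp, w, log = TRUE)
    }
    lp[, j] <- log(model$weights_mix[k]) + lk
  }
  sum(pmax(logsumexp_rows(lp), -745))
}

#' Minimum message length score
#'
#' \deqn{\mathrm{MML} = \tfrac{M}{2}\sum_{k \in K^+}\log\pi_k - Q +
#' \tfrac{K^+(M+1)}{2}\big(1 + \log\tfrac{n}{12}\big)}
#' where \eqn{K^+} is the set of non-empty components and M the number of
#' free parameters per component.  Lower is better; empty components
#' contribute nothing.
#'
#' @param model a \code{\link{mixture_model}} (zeros mark empty components).
#' @param q_value data-fit term: the \code{\link{observed_loglik}} value
#'   (what \code{\link{wmggmm_fit}} uses, following the criterion's parent
#'   framework) or an expected complete-data log-likelihood.
#' @param n sample size.
#' @param M free parameters per component (default from the model dimension).
#' @return list of class \code{mml_score}: value, k_plus, M, n.
#' @export
mml_score <- function(model, q_value, n, M = params_per_component(model$dim)) {
  active <- model$weights_mix > 0
  k_plus <- sum(active)
  if (k_plus < 1) stop("MML score needs at least one non-empty component")
  value <- (M / 2) * sum(log(model$weights_mix[active])) - q_value +
    (k_plus * (M + 1) / 2) * (1 + log(n / 12))
  structure(list(value = value, k_plus = k_plus, M = M, n = n),
            class = "mml_score")
}

#' Fit a weighted MGGD mixture by component-wise EM with MML selection
#'
#' Runs the full algorithm: k-means + kernel-weight initialization with
#' \code{k_max} components, then component-wise sweeps in which each
#' component in turn gets an E-Z step (responsibilities), an E-W step
#' (Gamma weight posteriors), the annihilating mixing-coefficient update,
#' and -- if it survives -- fixed-point mean and scatter updates, a damped
#' Newton shape update and the closed-form scale update.  The MML score is
#' tracked after every sweep; the algorithm stops when its change falls below
#' \code{mml_tol}.  Components annihilated along the way are dropped from the
#' returned model.
#'
#' @param cloud a \code{\link{point_cloud}} or coordinate matrix.
#' @param config a \code{\link{wmggmm_config}}.
#' @return object of class \code{wmggmm_fit}: list with \code{model} (live
#'   components only), \code{wstate}, \code{eta}, \code{weights} (kernel
#'   weights), \code{report} (iterations, mml_trace, k_trace, convergence
#'   flags, n_underflow, seed) and \code{config}.
#' @export
wmggmm_fit <- function(cloud, config = wmggmm_config()) {
  cloud <- as_point_cloud(cloud)
  n <- cloud$n
  d <- cloud$dim
  M <- params_per_component(d)
  ini <- init_model(cloud, config)
  model <- ini$model
  wstate <- ini$wstate
  w0 <- ini$weights
  bayes <- config$weight_mode == "bayesian"
  if (bayes) wstate <- e_w_step(cloud, model, wstate, config$weight_clamp)

  mml_trace <- numeric(0)
  k_trace <- integer(0)
  phase_trace <- integer(0)
  phase_id <- 0L
  n_underflow <- 0L
  fp_flags <- TRUE
  mml_tol <- config$mml_tol
  snapshots <- list()
  sweeps <- 0L

  # One phase: component-wise EM sweeps from the given state until the MML
  # change falls below tolerance.  Returns the converged state and its MML.
  run_phase <- function(model, wstate) {
    mml_prev <- Inf
    mml <- NA_real_
    eta <- NULL
    phase_id <<- phase_id + 1L
    phase_sweeps <- 0L
    repeat {
      if (phase_sweeps >= config$em_max_iter ||
          sweeps >= 4L * config$em_max_iter) break
      phase_sweeps <- phase_sweeps + 1L
      sweeps <<- sweeps + 1L
      for (k in seq_len(model$K)) {
        if (model$weights_mix[k] <= 0) next
        eta <- e_z_step(cloud, model, wstate, config, fixed_w = w0)
        n_underflow <<- n_underflow + attr(eta, "n_underflow")
        active <- which(model$weights_mix > 0)
        k_plus <- length(active)
        if (bayes) wstate <- e_w_step(cloud, model, wstate,
                                      config$weight_clamp)
        model$weights_mix <- m_step_pi(eta, k_plus, M, active)
        if (model$weights_mix[k] > 0) {
          comp <- model$components[[k]]
          wk <- if (bayes) wstate$w_bar[, k] else w0
          mu <- update_mu(cloud, comp, eta[, k], wk,
                          config$fp_tol, config$fp_max_iter)
          fp_flags <<- fp_flags && attr(mu, "converged")
          comp <- mggd_component(as.numeric(mu), comp$scatter,
                                 comp$shape, comp$scale)
          Sg <- update_sigma(cloud, comp, eta[, k], wk,
                             config$fp_tol, config$fp_max_iter)
          fp_flags <<- fp_flags && attr(Sg, "converged")
          comp <- mggd_component(comp$mean, unclass_attr(Sg),
                                 comp$shape, comp$scale)
          bt <- update_beta(cloud, comp, eta[, k], wk, config)
          comp <- mggd_component(comp$mean, comp$scatter,
                                 as.numeric(bt), comp$scale)
          comp <- mggd_component(comp$mean, comp$scatter, comp$shape,
                                 update_m(cloud, comp, eta[, k], wk))
          model$components[[k]] <- comp
        }
      }
      eta <- e_z_step(cloud, model, wstate, config, fixed_w = w0)
      if (bayes) wstate <- e_w_step(cloud, model, wstate, config$weight_clamp)
      q <- q_function(cloud, model, wstate, eta, config, fixed_w = w0)
      mml <- mml_score(model, q, n, M)$value
      mml_trace <<- c(mml_trace, mml)
      k_trace <<- c(k_trace, sum(model$weights_mix > 0))
      phase_trace <<- c(phase_trace, phase_id)
      if (is.null(mml_tol)) mml_tol <<- 1e-4 * abs(mml)
      if (is.finite(mml_prev) && abs(mml - mml_prev) < mml_tol) break
      mml_prev <- mml
    }
    ll <- observed_loglik(cloud, model, wstate, config, fixed_w = w0)
    list(model = model, wstate = wstate, eta = eta, mml = mml,
         loglik = ll, mml_ll = mml_score(model, ll, n, M)$value,
         k_plus = sum(model$weights_mix > 0))
  }

  kill <- function(model, victim) {
    model$weights_mix[victim] <- 0
    model$weights_mix <- model$weights_mix / sum(model$weights_mix)
    model
  }

  # Outer loop: converge a phase, snapshot it, then force-annihilate one
  # component and continue, down to a single component; the minimum-MML
  # snapshot wins.  Because the cascade is path dependent, annihilation
  # branches over the two components whose removal costs the least
  # observed-data log-likelihood, converges both branches, and keeps the
  # lower-MML one.
  state <- run_phase(model, wstate)
  repeat {
    snapshots[[length(snapshots) + 1L]] <- state
    active <- which(state$model$weights_mix > 0)
    if (length(active) <= 1L || sweeps >= 4L * config$em_max_iter) break
    drop_ll <- vapply(active, function(k)
      observed_loglik(cloud, kill(state$model, k), state$wstate, config,
                      fixed_w = w0), 0)
    cand <- active[order(drop_ll, decreasing = TRUE)]
    cand <- cand[seq_len(min(2L, length(cand)))]
    branches <- lapply(cand, function(k)
      run_phase(kill(state$model, k), state$wstate))
    state <- branches[[which.min(vapply(branches, `[[`, 0, "mml"))]]
  }

  best <- snapshots[[which.min(vapply(snapshots, `[[`, 0, "mml"))]]
  model <- best$model
  wstate <- best$wstate
  eta <- best$eta
  keep <- which(model$weights_mix > 0)
  out_model <- mixture_model(model$weights_mix[keep] /
                               sum(model$weights_mix[keep]),
                             model$components[keep])
  out_wstate <- list(a0 = wstate$a0, b0 = wstate$b0,
                     a_post = wstate$a_post[, keep, drop = FALSE],
                     b_post = wstate$b_post[, keep, drop = FALSE],
                     w_bar = wstate$w_bar[, keep, drop = FALSE])
  structure(list(model = out_model, wstate = out_wstate,
                 eta = best$eta[, keep, drop = FALSE], weights = w0,
                 report = list(iterations = sweeps,
                               mml_trace = mml_trace, k_trace = k_trace,
                               phase_trace = phase_trace,
                               mml = best$mml,
                               snapshots = data.frame(
                                 k_plus = vapply(snapshots, `[[`, 0L, "k_plus"),
                                 mml = vapply(snapshots, `[[`, 0, "mml"),
                                 mml_ll = vapply(snapshots, `[[`, 0, "mml_ll"),
                                 loglik = vapply(snapshots, `[[`, 0, "loglik")),
                               k_plus = length(keep),
                               fp_converged = fp_flags,
                               n_underflow = n_underflow,
                               seed = config$seed),
                 config = config),
            class = "wmggmm_fit")
}

# Strip attributes added by the fixed-point updaters.
unclass_attr <- function(x) {
  attr(x, "converged") <- NULL
  x
}

#' @export
print.wmggmm_fit <- function(x, ...) {
  cat(sprintf("WMGGMM fit: K+ = %d components after %d sweeps (MML = %.2f)\n",
              x$report$k_plus, x$report$iterations, x$report$mml))
  print(x$model)
  invisible(x)
}
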