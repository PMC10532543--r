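#' Mixture specification for synthetic data generation
#'
#' Describes a generating MGGD mixture the way benchmark tables print it:
#' one full scatter matrix \eqn{C_k} per component (the identifiable product
#' \eqn{m_k \Sigma_k}), plus mean, shape and sample count.  Internally the
#' factorization \eqn{m_k = \det(C_k)^{1/d}}, \eqn{\Sigma_k = C_k/m_k}
#' (unit-determinant scatter) is used; the density only depends on the
#' product, so the convention is observationally irrelevant.
#'
#' @param pi_k numeric simplex vector of mixing coefficients.
#' @param means list of length-d mean vectors.
#' @param betas numeric vector of shape parameters.
#' @param scatters list of full scatter matrices \eqn{C_k} (SPD).
#' @param n_k integer vector of per-component sample counts.
#' @return list of class \code{mixture_spec} with the derived
#'   \code{\link{mixture_model}} in \code{$model}.
#' @export
mixture_spec <- function(pi_k, means, betas, scatters, n_k) {
  stopifnot(length(pi_k) == length(means),
            length(pi_k) == length(betas),
            length(pi_k) == length(scatters),
            length(pi_k) == length(n_k))
  if (abs(sum(pi_k) - 1) > 1e-10) stop("pi_k must sum to 1")
  if (any(n_k < 1)) stop("each n_k must be >= 1")
  d <- length(means[[1L]])
  comps <- lapply(seq_along(pi_k), function(k) {
    C <- as.matrix(scatters[[k]])
    m <- det(C)^(1 / d)
    mggd_component(means[[k]], C / m, shape = betas[k], scale = m)
  })
  structure(list(pi_k = pi_k, means = means, betas = betas,
                 scatters = scatters, n_k = as.integer(n_k), dim = d,
                 model = mixture_model(pi_k, comps)),
            class = "mixture_spec")
}

#' Benchmark mixture specifications
#'
#' \code{spec_four_component()}: four equally weighted components
#' (beta = 0.85, 300 points each) at means (1,1), (15,2), (1,18), (16,16)
#' with scatters [[3,1],[1,5]], [[2,0],[0,2]], [[3,-2],[-2,4]],
#' [[3,-1],[-1,3]].  \code{spec_three_component()}: components with weights
#' 0.25/0.25/0.50 (300/300/600 points) at (8,16), (15,2), (1,3) with
#' scatters [[3,-2],[-2,4]], [[2,0],[0,2]], [[3,1],[1,5]] and shapes
#' 0.60/0.85/0.85.
#'
#' @param n_total optional total sample size; per-component counts are
#'   scaled proportionally (default 1200).
#' @return a \code{\link{mixture_spec}}.
#' @export
spec_four_component <- function(n_total = 1200L) {
  n_k <- round(n_total * rep(0.25, 4))
  mixture_spec(pi_k = rep(0.25, 4),
               means = list(c(1, 1), c(15, 2), c(1, 18), c(16, 16)),
               betas = rep(0.85, 4),
               scatters = list(matrix(c(3, 1, 1, 5), 2),
                               matrix(c(2, 0, 0, 2), 2),
                               matrix(c(3, -2, -2, 4), 2),
                               matrix(c(3, -1, -1, 3), 2)),
               n_k = n_k)
}

#' @rdname spec_four_component
#' @export
spec_three_component <- function(n_total = 1200L) {
  pi_k <- c(0.25, 0.25, 0.50)
  mixture_spec(pi_k = pi_k,
               means = list(c(8, 16), c(15, 2), c(1, 3)),
               betas = c(0.60, 0.85, 0.85),
               scatters = list(matrix(c(3, -2, -2, 4), 2),
                               matrix(c(2, 0, 0, 2), 2),
                               matrix(c(3, 1, 1, 5), 2)),
               n_k = round(n_total * pi_k))
}

#' Generate a labelled dataset from a mixture specification
#'
#' Draws exactly \code{n_k[k]} points from each component (stratified, so the
#' label bookkeeping is exact) and concatenates them.
#'
#' @param spec a \code{\link{mixture_spec}}.
#' @param seed optional integer seed.
#' @return a \code{\link{point_cloud}} with integer component labels.
#' @export
make_mixture_dataset <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Xs <- lapply(seq_along(spec$n_k), function(k)
    rmggd(spec$n_k[k], spec$model$components[[k]])$points)
  point_cloud(do.call(rbind, Xs), labels = rep(seq_along(spec$n_k), spec$n_k))
}

#' Contaminate a cloud with uniform noise
#'
#' Appends \code{round(fraction * N)} points drawn uniformly in an
#' axis-aligned box (default the primary distribution area
#' \eqn{[-5.25, 5.25]^2}), labelled \code{"noise"}; original points are
#' untouched.  The fraction is relative to the clean count (proportional
#' addition), not to the contaminated total.
#'
#' @param cloud a \code{\link{point_cloud}}.
#' @param fraction noise fraction in [0, 1).
#' @param bounds 2 x d matrix: first row lower bounds, second row upper.
#' @param seed optional integer seed.
#' @return contaminated \code{\link{point_cloud}}.
#' @export
add_uniform_noise <- function(cloud, fraction,
                              bounds = rbind(c(-5.25, -5.25), c(5.25, 5.25)),
                              seed = NULL) {
  cloud <- as_point_cloud(cloud)
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  bounds <- as.matrix(bounds)
  if (any(bounds[2, ] <= bounds[1, ])) stop("empty noise bounds")
  if (fraction == 0) return(cloud)
  if (!is.null(seed)) set.seed(seed)
  n_noise <- round(fraction * cloud$n)
  if (n_noise == 0) return(cloud)
  Z <- vapply(seq_len(cloud$dim), function(j)
    stats::runif(n_noise, bounds[1, j], bounds[2, j]), numeric(n_noise))
  if (!is.matrix(Z)) Z <- matrix(Z, nrow = n_noise)
  labs <- cloud$labels
  if (is.null(labs)) labs <- rep("data", cloud$n)
  point_cloud(rbind(cloud$points, Z),
              labels = c(as.character(labs), rep("noise", n_noise)))
}

#' Generate a registration test pair with known ground truth
#'
#' The scene is an independent draw of \code{scene_n} points from the base
#' mixture; the model cloud is another independent draw of \code{model_n}
#' points transformed by the \emph{inverse} of the ground-truth transform, so
#' that registering model onto scene should recover \code{truth}.  Optional
#' uniform noise is appended to both clouds in the base frame (the model's
#' noise is inverse-transformed along with its points, emulating two noisy
#' scans of the same scene).
#'
#' @param spec a \code{\link{mixture_spec}} (per-component counts are scaled
#'   to the requested totals).
#' @param truth ground-truth \code{\link{rigid_transform}} (model -> scene).
#' @param scene_n,model_n sample sizes of the two clouds (default 1200/800,
#'   the sampling-rate-mismatch scenario).
#' @param noise_fraction uniform-noise fraction in [0, 1) for both clouds.
#' @param noise_bounds noise box, as in \code{\link{add_uniform_noise}}.
#' @param seed optional integer seed.
#' @return list: \code{scene}, \code{model_cloud}, \code{truth}.
#' @export
make_registration_pair <- function(spec, truth = rigid_transform(0.7, c(5, -3)),
                                   scene_n = 1200L, model_n = 800L,
                                   noise_fraction = 0,
                                   noise_bounds = rbind(c(-5.25, -5.25),
                                                        c(5.25, 5.25)),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scale_spec <- function(s, n_total) {
    n_k <- pmax(1L, round(n_total * s$pi_k))
    mixture_spec(s$pi_k, s$means, s$betas, s$scatters, n_k)
  }
  scene <- make_mixture_dataset(scale_spec(spec, scene_n))
  model0 <- make_mixture_dataset(scale_spec(spec, model_n))
  if (noise_fraction > 0) {
    scene <- add_uniform_noise(scene, noise_fraction, noise_bounds)
    model0 <- add_uniform_noise(model0, noise_fraction, noise_bounds)
  }
  model_cloud <- transform_points(model0, tf_inverse(truth))
  list(scene = scene, model_cloud = model_cloud, truth = truth)
}

# Near-centrally-symmetric mixture: two pairs of components mirrored through
# the origin (invariant under 180-degree rotation, since C is unchanged by
# conjugation with -I) plus one small symmetry-breaking component.
trap_spec <- function(n, asymmetry_n) {
  n_sym <- n - asymmetry_n
  n_pair <- round(n_sym / 4)
  n_k <- c(rep(n_pair, 3), n_sym - 3 * n_pair, asymmetry_n)
  pi_k <- n_k / sum(n_k)
  Ca <- matrix(c(1.5, 0, 0, 0.8), 2)
  Cb <- matrix(c(0.35, 0, 0, 0.35), 2)
  mixture_spec(pi_k,
               means = list(c(5, 0), c(-5, 0), c(0, 3.5), c(0, -3.5),
                            c(7, 7)),
               betas = rep(0.85, 5),
               scatters = list(Ca, Ca, Cb, Cb,
                               matrix(c(0.3, 0, 0, 0.3), 2)),
               n_k = n_k)
}

#' Generate a near-symmetric "trap" point cloud
#'
#' A cloud whose generating mixture is invariant under a 180-degree rotation
#' about its centroid except for one small component (default 5\% of the
#' points).  Registering two such clouds has a strong local optimum at the
#' true rotation plus 180 degrees, which only the asymmetric component
#' disambiguates -- the classic failure mode of near-symmetric scenes.
#'
#' @param n total number of points.
#' @param asymmetry_n points in the symmetry-breaking component (default
#'   5\% of n).
#' @param seed optional integer seed.
#' @return a \code{\link{point_cloud}} with component labels; the asymmetric
#'   component carries the largest label.
#' @export
make_symmetric_trap <- function(n = 1000L, asymmetry_n = round(0.05 * n),
                                seed = NULL) {
  if (asymmetry_n >= n / 4) stop("asymmetry_n must be small relative to n")
  make_mixture_dataset(trap_spec(n, asymmetry_n), seed = seed)
}

#' Registration pair for the symmetry-trap scenario
#'
#' @inheritParams make_symmetric_trap
#' @param truth ground-truth transform.
#' @param scene_n,model_n cloud sizes.
#' @return list as in \code{\link{make_registration_pair}}.
#' @export
make_trap_pair <- function(scene_n = 1000L, model_n = 1000L,
                           truth = rigid_transform(0.7, c(5, -3)),
                           seed = NULL) {
  make_registration_pair(trap_spec(scene_n, round(0.05 * scene_n)),
                         truth = truth, scene_n = scene_n,
                         model_n = model_n, seed = seed)
}
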