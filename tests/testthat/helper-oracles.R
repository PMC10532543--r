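# Shared oracles and fixtures, all generated in code.

# 2-D quadrature of f(x, y) over [lo, hi]^2 on an m x m midpoint grid.
quad2d <- function(f, lo, hi, m = 400L) {
  g <- seq(lo, hi, length.out = m + 1L)
  mid <- (g[-1L] + g[-(m + 1L)]) / 2
  h <- mid[2L] - mid[1L]
  X <- cbind(rep(mid, each = m), rep(mid, times = m))
  sum(f(X)) * h^2
}

# Two-sample energy statistic with permutation p-value.
energy_test <- function(X, Y, B = 99L, seed = 1L) {
  set.seed(seed)
  nx <- nrow(X); ny <- nrow(Y)
  Z <- rbind(X, Y)
  D <- as.matrix(stats::dist(Z))
  stat <- function(ix) {
    iy <- setdiff(seq_len(nx + ny), ix)
    2 * mean(D[ix, iy]) - mean(D[ix, ix]) - mean(D[iy, iy])
  }
  obs <- stat(seq_len(nx))
  perm <- replicate(B, stat(sample(nx + ny, nx)))
  (1 + sum(perm >= obs)) / (B + 1)
}

# A small well-separated two-component mixture used across tests.
toy_mixture <- function(beta = 1) {
  mixture_model(c(0.4, 0.6),
                list(mggd_component(c(-4, 0), diag(2), beta, 1),
                     mggd_component(c(4, 1), matrix(c(2, .5, .5, 1), 2),
                                    beta, 1.5)))
}

# Multivariate normal density, written independently of the package.
mvn_dens <- function(X, mu, C) {
  Ci <- solve(C)
  Xc <- sweep(X, 2, mu)
  y <- rowSums((Xc %*% Ci) * Xc)
  exp(-y / 2) / (2 * pi * sqrt(det(C)))
}

# Single-cluster cloud plus one far outlier.
cluster_with_outlier <- function(n = 100L, seed = 42L) {
  set.seed(seed)
  X <- matrix(stats::rnorm(2 * n, sd = 0.7), ncol = 2)
  point_cloud(rbind(X, c(25, 25)))
}
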