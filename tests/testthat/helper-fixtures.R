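# Small-scale generator configurations and shared oracles for the test suite.

tiny_cfg <- function(seed = 42, ...) {
  args <- list(
    seed = seed,
    n_landmarks = 25, n_ref_female = 8, n_ref_male = 9,
    n_participants = 40, n_fathers = 24,
    ratings_per_face_per_trait = 12,
    rater_pool = c(male = 20, female = 30, other = 5)
  )
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

random_config <- function(n_points, seed) {
  set.seed(seed)
  cbind(runif(n_points, 0, 512), runif(n_points, 0, 512))
}

# Independent grid-search oracle for the optimal-rotation Procrustes
# distance between two centred, unit-size configurations.
grid_search_distance <- function(a, b, step = 1e-4) {
  center_unit <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  ua <- center_unit(a)
  ub <- center_unit(b)
  m <- crossprod(ua, ub)
  theta <- seq(0, 2 * pi, by = step)
  # || ua R(theta) - ub ||^2 = 2 - 2 * (cos t * (m11 + m22) + sin t * (m21 - m12))
  d2 <- 2 - 2 * (cos(theta) * (m[1, 1] + m[2, 2]) +
                   sin(theta) * (m[2, 1] - m[1, 2]))
  sqrt(max(0, min(d2)))
}

# Independent fixed-grid quadrature oracle for the JZS model-vs-null Bayes
# factor, integrating over g via the substitution u = g / (1 + g).
jzs_grid_oracle <- function(n, p, r2, prior_scale = sqrt(2) / 2, nodes = 1e6) {
  if (p == 0) return(1)
  u <- (seq_len(nodes) - 0.5) / nodes
  g <- u / (1 - u)
  jac <- 1 / (1 - u)^2
  lf <- 0.5 * log(n * prior_scale^2 / 2) - lgamma(0.5) - 1.5 * log(g) -
    n * prior_scale^2 / (2 * g) +
    ((n - 1 - p) / 2) * log1p(g) - ((n - 1) / 2) * log1p(g * (1 - r2))
  sum(exp(lf) * jac) / nodes
}

apply_similarity <- function(m, angle, scale, shift) {
  r <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(scale * m %*% r, 2, shift, "+")
}
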