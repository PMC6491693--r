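# Fixture builders used across the suite. All randomness is drawn from the
# caller's RNG state so tests control seeds with set.seed().

# Dense random model: every loading free-form, diagonal positive phi.
random_model <- function(p = 6, q = 2, correlated = FALSE) {
  lambda <- matrix(runif(p * q, 0.3, 0.9), p, q)
  phi <- diag(runif(q, 0.5, 2), q)
  if (correlated && q > 1) {
    r <- runif(1, -0.3, 0.5)
    for (j in seq_len(q - 1)) for (k in (j + 1):q) {
      phi[j, k] <- phi[k, j] <- r * sqrt(phi[j, j] * phi[k, k])
    }
  }
  theta <- runif(p, 0.3, 1)
  cfa_model(lambda, phi, theta)
}

# Simple-structure model suitable for ML fitting: each indicator loads on
# exactly one factor, positive loadings, optional latent correlation.
random_structured_model <- function(q = 1, per_factor = 4,
                                    correlated = FALSE) {
  p <- q * per_factor
  loadings <- runif(q, 0.4, 0.8)
  phi <- runif(q, 0.6, 1.6)
  r <- if (correlated && q > 1) runif(1, 0.1, 0.4) else 0
  generate_model(p = p, q = q, loadings = loadings,
                 phi = phi, latent_cor = r,
                 theta = runif(p, 0.3, 0.8))
}

true_part_of_fit <- function(f) {
  est <- f$estimates
  est$lambda %*% est$phi %*% t(est$lambda)
}

# Independent scalar-loop oracle for the true part (diagonal phi only):
# sigma_tau_ij = sum_k lambda_ik phi_kk lambda_jk, no matrix products.
brute_force_true_part <- function(lambda, phi_diag) {
  p <- nrow(lambda)
  out <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    acc <- 0
    for (k in seq_along(phi_diag)) {
      acc <- acc + lambda[i, k] * phi_diag[k] * lambda[j, k]
    }
    out[i, j] <- acc
  }
  out
}
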