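# Synthetic factor models and sampled studies.
#
# Scores follow x = mu + Lambda xi + delta with xi ~ N(0, Phi) and
# delta ~ N(0, Theta): Gaussian latent and error scores match the ML
# fitter's distributional assumptions. Sample covariances use the n - 1
# denominator.

#' Generate a factor model with a known structure
#'
#' Builds a population model from per-factor loading values and indicator
#' sets (or an explicit loading matrix). Defaults emulate standardized
#' indicators: when `theta` is omitted, error variances are
#' `1 - diag(Lambda Phi Lambda')` so each manifest variable has unit
#' population variance.
#'
#' @param p Number of manifest variables.
#' @param q Number of factors.
#' @param loadings Either a p x q matrix used as-is, or a length-q vector of
#'   loading values, one per factor, placed on that factor's `indicators`.
#' @param indicators List of q integer vectors giving each factor's
#'   indicator rows; default: every factor loads on all p variables when
#'   `q = 1`, otherwise consecutive blocks of `p / q`.
#' @param phi Length-q vector of latent variances (default 1).
#' @param latent_cor Scalar correlation applied to all factor pairs, or a
#'   q x q correlation matrix.
#' @param theta Length-p vector of error variances; default
#'   `1 - diag(true part)` (must stay positive).
#' @param mu Length-p intercept vector (default zeros).
#' @return A [cfa_model()].
#' @examples
#' generate_model(p = 4, loadings = 0.2)  # four indicators loading 0.2
#' @export
generate_model <- function(p, q = 1, loadings = 0.5, indicators = NULL,
                           phi = 1, latent_cor = 0, theta = NULL,
                           mu = rep(0, p)) {
  if (is.matrix(loadings)) {
    if (nrow(loadings) != p || ncol(loadings) != q) {
      abort(sprintf("Loading matrix must be %d x %d.", p, q))
    }
    lambda <- loadings
  } else {
    loadings <- rep(loadings, length.out = q)
    if (is.null(indicators)) {
      indicators <- if (q == 1) list(seq_len(p))
      else {
        if (p %% q != 0) {
          abort("Provide `indicators` when p is not a multiple of q.")
        }
        split(seq_len(p), rep(seq_len(q), each = p / q))
      }
    }
    lambda <- matrix(0, p, q)
    for (k in seq_len(q)) lambda[indicators[[k]], k] <- loadings[k]
  }

  phi_vec <- rep(phi, length.out = q)
  if (is.matrix(latent_cor)) {
    Rq <- latent_cor
  } else {
    Rq <- matrix(latent_cor, q, q); diag(Rq) <- 1
  }
  Phi <- diag(sqrt(phi_vec), q) %*% Rq %*% diag(sqrt(phi_vec), q)
  ev <- eigen((Phi + t(Phi)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    abort(sprintf("Latent covariance is not positive definite (min eigenvalue %.3e).",
                  min(ev)))
  }

  if (is.null(theta)) {
    tp <- diag(lambda %*% Phi %*% t(lambda))
    theta <- 1 - tp
    if (any(theta <= 0)) {
      abort("Default unit-variance error variances are non-positive; supply `theta`.")
    }
  }
  cfa_model(lambda, Phi, theta, mu)
}

#' Draw a sampled study from a factor model
#'
#' Generates `n` score vectors `x = mu + Lambda xi + delta` with Gaussian
#' latent scores (`Cov(xi) = Phi`, via Cholesky) and independent Gaussian
#' errors (`Var(delta_i) = theta_ii`), and returns the raw scores, their
#' sample covariance (denominator `n - 1`) and the population covariance.
#' Reproducible: the same seed gives the identical study.
#'
#' @param model A [cfa_model()]; `phi` must be positive definite and all
#'   error variances non-negative.
#' @param n Number of observations (at least 2).
#' @param seed Integer seed.
#' @return A `synthetic_study`: `truth`, `population` ([implied_covariance()]
#'   of the truth), `sample` ([sample_cov()] with `n`), `scores` (n x p).
#' @export
sample_study <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "cfa_model"))
  if (n < 2) abort("`n` must be at least 2.")
  p <- n_manifest(model); q <- n_factors(model)
  if (any(diag(model$theta) < 0)) {
    abort("Sampling requires non-negative error variances.")
  }
  ev <- eigen(model$phi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0) abort("Sampling requires positive semidefinite `phi`.")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  L <- chol(model$phi + diag(1e-12, q))
  xi <- matrix(rnorm(n * q), n, q) %*% L
  delta <- matrix(rnorm(n * p), n, p) %*% diag(sqrt(diag(model$theta)), p)
  mu <- if (is.null(model$mu)) rep(0, p) else model$mu
  x <- sweep(xi %*% t(model$lambda) + delta, 2, mu, `+`)
  colnames(x) <- rownames(model$lambda)

  S <- cov(x)
  structure(list(truth = model,
                 population = implied_covariance(model),
                 sample = sample_cov(S, n = n),
                 scores = x,
                 seed = as.integer(seed)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> n = %d, p = %d, seed = %d\n",
              x$sample$n, ncol(x$scores), x$seed))
  invisible(x)
}

#' Monte-Carlo recovery of scaled variance parameters
#'
#' Repeats sample -> ML fit -> rescale and summarises how well each
#' factor's scaled variance is recovered: mean estimate, bias and RMSE
#' against the population value (the truth rescaled by the same plan).
#' Non-converged replicates are counted and excluded from the summaries.
#'
#' @param model The population [cfa_model()] (all-zero loadings on every
#'   factor are rejected as degenerate).
#' @param spec A [cfa_spec()] matching the model's structure; its
#'   identification is used for fitting.
#' @param method,per_factor Scaling applied to each fitted solution, as in
#'   [build_plan()].
#' @param replicates Number of Monte-Carlo replicates.
#' @param n Sample size per replicate.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return A tibble with one row per factor: population scaled variance,
#'   mean estimate, bias, RMSE, and the non-convergence count as attribute
#'   `"n_nonconverged"`.
#' @export
recovery_study <- function(model, spec, method = "sum_squares",
                           per_factor = NULL, replicates = 50,
                           n = 5000, seed = 1L) {
  stopifnot(inherits(model, "cfa_model"), inherits(spec, "cfa_spec"))
  if (any(apply(model$lambda, 2, function(col) all(col == 0)))) {
    abort("Degenerate truth: a factor has all-zero loadings.")
  }
  q <- n_factors(model)
  pop_plan <- build_plan(model, method, per_factor)
  pop_scaled <- diag(rescale(model, pop_plan)$phi_star)

  draws <- matrix(NA_real_, replicates, q)
  n_fail <- 0L
  for (r in seq_len(replicates)) {
    study <- sample_study(model, n = n, seed = as.integer(seed) + r)
    f <- fit_cfa(study$sample, spec)
    if (!f$converged) { n_fail <- n_fail + 1L; next }
    plan_r <- build_plan(f$estimates, method, per_factor)
    draws[r, ] <- diag(rescale(f$estimates, plan_r)$phi_star)
  }
  ok <- stats::complete.cases(draws)
  out <- tibble::tibble(
    factor = colnames(model$lambda),
    population = unname(pop_scaled),
    mean_estimate = unname(colMeans(draws[ok, , drop = FALSE])),
    bias = mean_estimate - population,
    rmse = sqrt(colMeans(sweep(draws[ok, , drop = FALSE], 2, pop_scaled)^2))
  )
  attr(out, "n_nonconverged") <- n_fail
  attr(out, "replicates") <- replicates
  out
}
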