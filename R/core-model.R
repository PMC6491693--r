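# Factor-model containers and the model-implied covariance machinery.
#
# A CFA model is the triple (Lambda, Phi, Theta): a p x q loading matrix,
# a q x q symmetric latent variance/covariance matrix and a p x p diagonal
# error-covariance matrix. The model-implied covariance is
# Sigma = Lambda Phi Lambda' + Theta; the summand Lambda Phi Lambda' is the
# "true part", the object that rescaling must leave unchanged.

SYMMETRY_TOL <- 1e-10

#' Construct a confirmatory factor-analysis model
#'
#' Bundles a loading matrix, a latent variance/covariance matrix and a
#' diagonal error-covariance matrix into a validated model object. Latent
#' variance parameters and error variances are *parameters*, not sample
#' variances: estimation can drive them negative, so negative values are
#' stored and flagged (Heywood case) rather than rejected.
#'
#' @param lambda Numeric p x q loading matrix (a numeric vector is taken as
#'   a one-factor p x 1 matrix). Row names are manifest-variable names,
#'   column names factor names; defaults are generated when absent.
#' @param phi Numeric q x q symmetric latent covariance matrix, or a length-q
#'   vector of latent variances (diagonal `phi`).
#' @param theta Numeric p x p diagonal error-covariance matrix, or a
#'   length-p vector of error variances.
#' @param mu Optional length-p vector of intercepts (used only when
#'   generating raw scores).
#' @return An object of class `cfa_model` with elements `lambda`, `phi`,
#'   `theta`, `mu`, and logical flags `negative_phi` and `heywood`.
#' @examples
#' m <- cfa_model(lambda = c(0.5, 0.8, 0.4), phi = 1, theta = rep(0.5, 3))
#' implied_covariance(m)$values
#' @export
cfa_model <- function(lambda, phi, theta, mu = NULL) {
  if (is.vector(lambda) && is.numeric(lambda)) {
    lambda <- matrix(lambda, ncol = 1)
  }
  if (!is.matrix(lambda) || !is.numeric(lambda)) {
    abort("`lambda` must be a numeric matrix or vector.")
  }
  p <- nrow(lambda)
  q <- ncol(lambda)
  if (p < 1 || q < 1) abort("`lambda` needs at least one row and column.")
  if (!all(is.finite(lambda))) abort("`lambda` contains non-finite entries.")

  if (is.vector(phi) && is.numeric(phi) && length(phi) %in% c(1L, q)) {
    phi <- diag(rep(phi, length.out = q), nrow = q)
  }
  if (!is.matrix(phi) || nrow(phi) != q || ncol(phi) != q) {
    abort(sprintf("`phi` must be a %d x %d matrix (q = %d factors).", q, q, q))
  }
  if (!all(is.finite(phi))) abort("`phi` contains non-finite entries.")
  if (max(abs(phi - t(phi))) > SYMMETRY_TOL) {
    abort(sprintf("`phi` is asymmetric beyond tolerance %g.", SYMMETRY_TOL))
  }
  phi <- (phi + t(phi)) / 2

  if (is.vector(theta) && is.numeric(theta) && length(theta) %in% c(1L, p)) {
    theta <- diag(rep(theta, length.out = p), nrow = p)
  }
  if (!is.matrix(theta) || nrow(theta) != p || ncol(theta) != p) {
    abort(sprintf("`theta` must be %d x %d (p = %d manifest variables).", p, p, p))
  }
  if (!all(is.finite(theta))) abort("`theta` contains non-finite entries.")
  off <- theta; diag(off) <- 0
  if (any(off != 0)) abort("`theta` must be diagonal (off-diagonals exactly zero).")

  if (!is.null(mu)) {
    if (!is.numeric(mu) || length(mu) != p) {
      abort(sprintf("`mu` must be a numeric vector of length %d.", p))
    }
  }

  if (is.null(rownames(lambda))) rownames(lambda) <- paste0("x", seq_len(p))
  if (is.null(colnames(lambda))) colnames(lambda) <- paste0("f", seq_len(q))
  dimnames(phi) <- list(colnames(lambda), colnames(lambda))
  dimnames(theta) <- list(rownames(lambda), rownames(lambda))

  out <- structure(
    list(lambda = lambda, phi = phi, theta = theta, mu = mu,
         negative_phi = any(diag(phi) <= 0),
         heywood = any(diag(theta) < 0)),
    class = "cfa_model"
  )
  out
}

#' @export
print.cfa_model <- function(x, ...) {
  p <- nrow(x$lambda); q <- ncol(x$lambda)
  cat(sprintf("<cfa_model> %d manifest variable(s), %d factor(s)\n", p, q))
  cat("Loadings (lambda):\n")
  print(round(x$lambda, 4))
  cat("Latent covariance (phi):\n")
  print(round(x$phi, 4))
  cat("Error variances (diag theta):\n")
  print(round(diag(x$theta), 4))
  if (x$negative_phi) cat("Note: non-positive latent variance parameter present.\n")
  if (x$heywood) cat("Note: negative error variance present (Heywood case).\n")
  invisible(x)
}

n_manifest <- function(x) UseMethod("n_manifest")
#' @export
n_manifest.cfa_model <- function(x) nrow(x$lambda)
#' @export
n_manifest.scaled_solution <- function(x) nrow(x$lambda_star)

n_factors <- function(x) UseMethod("n_factors")
#' @export
n_factors.cfa_model <- function(x) ncol(x$lambda)
#' @export
n_factors.scaled_solution <- function(x) ncol(x$lambda_star)

# True part Lambda Phi Lambda' of a model or a scaled solution,
# symmetrised exactly so it equals its transpose as stored.
true_part_of <- function(x) {
  if (inherits(x, "cfa_model")) {
    tp <- x$lambda %*% x$phi %*% t(x$lambda)
  } else if (inherits(x, "scaled_solution")) {
    tp <- x$lambda_star %*% x$phi_star %*% t(x$lambda_star)
  } else {
    abort("Expected a `cfa_model` or `scaled_solution`.")
  }
  (tp + t(tp)) / 2
}

#' Model-implied covariance matrix
#'
#' Computes `Sigma = Lambda Phi Lambda' + Theta` together with its true part
#' `Lambda Phi Lambda'` (the systematic component whose constancy under
#' rescaling the whole framework rests on).
#'
#' @param model A [cfa_model()].
#' @return An object of class `implied_cov`: a list with `values` (Sigma)
#'   and `true_part` (Lambda Phi Lambda'), both exactly symmetric p x p
#'   matrices.
#' @examples
#' m <- cfa_model(lambda = c(1, 1), phi = 1, theta = c(1, 1))
#' implied_covariance(m)$values  # 2 on the diagonal, 1 off it
#' @export
implied_covariance <- function(model) {
  stopifnot(inherits(model, "cfa_model"))
  tp <- true_part_of(model)
  structure(list(values = tp + model$theta, true_part = tp),
            class = "implied_cov")
}

#' @export
print.implied_cov <- function(x, ...) {
  cat(sprintf("<implied_cov> %d x %d\n", nrow(x$values), ncol(x$values)))
  print(round(x$values, 4))
  invisible(x)
}

#' Single entry of the true part by scalar summation
#'
#' Evaluates entry (i, j) of `Lambda Phi Lambda'` as the explicit scalar sum
#' `lambda_i1 phi_11 lambda_j1 + ... + lambda_iq phi_qq lambda_jq`. This is
#' the entrywise form that the constancy proof manipulates; it is only
#' defined for diagonal `Phi` (no latent covariances), and refuses otherwise.
#'
#' @param model A [cfa_model()] with diagonal `phi`.
#' @param i,j Row/column indices in `1..p`.
#' @return The scalar true-part entry.
#' @seealso [implied_covariance()] for the general (non-diagonal `phi`) case.
#' @export
true_part_entry <- function(model, i, j) {
  stopifnot(inherits(model, "cfa_model"))
  p <- n_manifest(model)
  if (!(i >= 1 && i <= p && j >= 1 && j <= p)) {
    abort(sprintf("Indices must lie in 1..%d.", p))
  }
  off <- model$phi; diag(off) <- 0
  if (any(off != 0)) {
    abort(paste("`true_part_entry()` requires diagonal `phi`;",
                "use `implied_covariance()` for correlated factors."))
  }
  sum(model$lambda[i, ] * diag(model$phi) * model$lambda[j, ])
}

#' Constancy distance between two factor solutions
#'
#' Maximum absolute entrywise difference between the true parts
#' `Lambda Phi Lambda'` of two solutions. Two solutions related by a valid
#' rescaling (`Lambda* = c Lambda`, `Phi* = Phi / c^2` per factor) have
#' distance zero up to floating-point error; any scaling that breaks the
#' `c` vs `1/c^2` pairing gives a strictly positive distance.
#'
#' @param a,b A [cfa_model()] or [rescale()] result (`scaled_solution`),
#'   with the same number of manifest variables.
#' @return Non-negative scalar, the max-norm distance of the true parts.
#' @export
constancy_distance <- function(a, b) {
  ta <- true_part_of(a)
  tb <- true_part_of(b)
  if (!all(dim(ta) == dim(tb))) {
    abort(sprintf("Models disagree on p: %d vs %d manifest variables.",
                  nrow(ta), nrow(tb)))
  }
  max(abs(ta - tb))
}
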