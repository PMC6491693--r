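# Minimal maximum-likelihood CFA fitter.
#
# The discrepancy is the standard ML fit function
#   F(S, Sigma) = log|Sigma| + tr(S Sigma^-1) - log|S| - p,
# minimised over the free parameters of (Lambda, Phi, Theta) with BFGS and
# the analytic gradient dF = tr[ Sigma^-1 (Sigma - S) Sigma^-1 dSigma ].
# Identification is imposed structurally: marker -> one loading fixed at 1;
# reference group -> latent variances fixed at 1; effect coding -> one
# loading per factor reparameterised as p_c minus the sum of the others,
# so the sum constraint holds to machine precision.

#' Sample covariance matrix with metadata
#'
#' Wraps a symmetric matrix with its sample size and a correlation flag.
#' A correlation matrix is analysed as if it were a covariance matrix (the
#' usual practice for published MTMM matrices); chi-square-based fit
#' indices then carry the usual caveat, recorded on the object.
#'
#' @param values Symmetric numeric p x p matrix (asymmetry beyond 1e-8 is an
#'   error). Column names become variable names.
#' @param n Sample size (needed for chi-square based fit statistics).
#' @param is_correlation Logical; `TRUE` if `values` is a correlation matrix.
#' @return A `sample_cov` object.
#' @export
sample_cov <- function(values, n = NULL, is_correlation = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (nrow(values) != ncol(values)) abort("`values` must be square.")
  if (max(abs(values - t(values))) > 1e-8) {
    abort("`values` is asymmetric beyond tolerance 1e-8.")
  }
  values <- (values + t(values)) / 2
  if (is.null(colnames(values))) {
    colnames(values) <- rownames(values) <- paste0("x", seq_len(ncol(values)))
  }
  if (!is.null(n)) {
    n <- as.integer(n)
    if (n < 2) abort("`n` must be at least 2.")
  }
  structure(list(values = values, n = n,
                 is_correlation = isTRUE(is_correlation)),
            class = "sample_cov")
}

as_sample_cov <- function(x, n = NULL) {
  if (inherits(x, "sample_cov")) return(x)
  if (inherits(x, "implied_cov")) return(sample_cov(x$values, n))
  if (is.matrix(x)) return(sample_cov(x, n))
  abort("Expected a matrix, `implied_cov` or `sample_cov`.")
}

#' Substitute the diagonal of a covariance matrix
#'
#' Replaces the main diagonal with supplied values, leaving every
#' off-diagonal entry bit-identical. Used to adjust a published correlation
#' matrix so that error variances stay positive and line up with known
#' reliabilities: in the spirit of a ridge adjustment, this changes error
#' components of the variances but not the systematic components. The
#' original diagonal is recorded in the `"diagonal_adjustment"` attribute.
#'
#' @param R A [sample_cov()] (or plain symmetric matrix).
#' @param new_diagonal Numeric vector of length p with positive entries.
#' @return A `sample_cov` with the substituted diagonal.
#' @export
adjust_diagonal <- function(R, new_diagonal) {
  R <- as_sample_cov(R)
  p <- ncol(R$values)
  if (length(new_diagonal) != p) {
    abort(sprintf("`new_diagonal` has length %d; expected %d.",
                  length(new_diagonal), p))
  }
  if (any(!is.finite(new_diagonal)) || any(new_diagonal <= 0)) {
    abort("`new_diagonal` entries must be positive and finite.")
  }
  out <- R
  old <- diag(out$values)
  diag(out$values) <- new_diagonal
  attr(out$values, "diagonal_adjustment") <- list(from = old, to = new_diagonal)
  out
}

#' Maximum-likelihood discrepancy function
#'
#' `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p`; zero exactly when the
#' implied covariance reproduces `S`.
#'
#' @param S A [sample_cov()] (or plain symmetric matrix).
#' @param sigma An [implied_covariance()] result or a p x p matrix; must be
#'   positive definite.
#' @return The scalar discrepancy.
#' @export
ml_discrepancy <- function(S, sigma) {
  S <- as_sample_cov(S)$values
  if (inherits(sigma, "implied_cov")) sigma <- sigma$values
  p <- ncol(S)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    abort(sprintf(
      "Implied covariance is not positive definite (min eigenvalue %.3e, condition %.3e).",
      min(ev), max(ev) / max(min(ev), .Machine$double.eps)))
  }
  chS <- tryCatch(chol(S), error = function(e)
    abort("`S` must be positive definite for the ML discrepancy."))
  logdet_sigma <- 2 * sum(log(diag(ch)))
  logdet_S <- 2 * sum(log(diag(chS)))
  sigma_inv <- chol2inv(ch)
  logdet_sigma + sum(S * sigma_inv) - logdet_S - p
}

# ---------------------------------------------------------------------------
# Model specification

#' Specify a CFA model for estimation
#'
#' The loading pattern is a p x q matrix with `NA` for free parameters and
#' numbers for fixed values (0 marks a structural zero). `phi` and `theta`
#' follow the same convention (`phi` symmetric; `theta` a length-p vector
#' of diagonal entries). Defaults: all `phi` diagonals free, off-diagonals
#' fixed at 0, all error variances free.
#'
#' Each factor must be identified by exactly one mechanism:
#' * `"marker"`: the loading at `markers[k]` (row index) is fixed at 1.
#' * `"reference_group"`: the latent variance `phi[k, k]` is fixed at
#'   `target` (1 by default).
#' * `"effect_coding"`: the loadings of factor k are constrained to sum to
#'   `p_c[k]`, enforced by exact reparameterisation of one free loading.
#'
#' @param loadings p x q pattern matrix (`NA` free / numeric fixed).
#' @param identification `"marker"`, `"reference_group"` or
#'   `"effect_coding"`.
#' @param phi Optional q x q pattern matrix; default free variances,
#'   zero covariances.
#' @param theta Optional length-p pattern vector; default all free.
#' @param markers Integer vector (length q or 1) of marker row indices.
#' @param p_c Numeric vector (length q or 1) of criterion numbers.
#' @param target Fixed latent variance for reference-group identification.
#' @return A `cfa_spec` object.
#' @export
cfa_spec <- function(loadings,
                     identification = c("marker", "reference_group",
                                        "effect_coding"),
                     phi = NULL, theta = NULL,
                     markers = NULL, p_c = NULL, target = 1) {
  identification <- match.arg(identification)
  if (!is.matrix(loadings)) loadings <- matrix(loadings, ncol = 1)
  p <- nrow(loadings); q <- ncol(loadings)
  if (is.null(phi)) {
    phi <- matrix(0, q, q); diag(phi) <- NA_real_
  }
  if (!is.matrix(phi) || any(dim(phi) != q)) {
    abort(sprintf("`phi` pattern must be %d x %d.", q, q))
  }
  mism <- which(!is.na(phi) & !is.na(t(phi)) & phi != t(phi))
  if (length(mism) || any(is.na(phi) != is.na(t(phi)))) {
    abort("`phi` pattern must be symmetric.")
  }
  if (is.null(theta)) theta <- rep(NA_real_, p)
  if (length(theta) != p) abort(sprintf("`theta` pattern must have length %d.", p))

  if (is.null(rownames(loadings))) rownames(loadings) <- paste0("x", seq_len(p))
  if (is.null(colnames(loadings))) colnames(loadings) <- paste0("f", seq_len(q))

  dependent <- rep(NA_integer_, q)
  if (identification == "marker") {
    if (is.null(markers)) abort("Marker identification needs `markers`.")
    markers <- rep(as.integer(markers), length.out = q)
    for (k in seq_len(q)) {
      if (markers[k] < 1 || markers[k] > p) {
        abort(sprintf("Marker index %d out of range for factor %d.", markers[k], k))
      }
      if (!is.na(loadings[markers[k], k]) && loadings[markers[k], k] == 0) {
        abort(sprintf("Marker for factor %d points at a structural zero.", k))
      }
      loadings[markers[k], k] <- 1
    }
  } else if (identification == "reference_group") {
    for (k in seq_len(q)) phi[k, k] <- target
  } else { # effect coding
    if (is.null(p_c)) abort("Effect-coding identification needs `p_c`.")
    p_c <- rep(as.numeric(p_c), length.out = q)
    if (any(p_c <= 0)) abort("`p_c` must be positive.")
    for (k in seq_len(q)) {
      free_rows <- which(is.na(loadings[, k]))
      if (!length(free_rows)) {
        abort(sprintf("Factor %d has no free loading to carry the sum constraint.", k))
      }
      dependent[k] <- free_rows[length(free_rows)]
    }
  }

  structure(list(loadings = loadings, phi = phi, theta = theta,
                 identification = identification,
                 markers = if (identification == "marker") markers else NULL,
                 p_c = if (identification == "effect_coding") p_c else NULL,
                 dependent = dependent, target = target),
            class = "cfa_spec")
}

#' Derive an estimation spec from a model's structure
#'
#' Frees every loading that is nonzero in `model`, fixes structural zeros,
#' frees latent covariances that are nonzero, and frees all error variances;
#' then applies the requested identification. Convenient for simulation
#' studies where the truth defines the pattern.
#'
#' @param model A [cfa_model()].
#' @inheritParams cfa_spec
#' @param ... Passed to [cfa_spec()] (`markers`, `p_c`, `target`).
#' @return A `cfa_spec`.
#' @export
spec_from_model <- function(model, identification, ...) {
  stopifnot(inherits(model, "cfa_model"))
  pat <- ifelse(model$lambda != 0, NA_real_, 0)
  dimnames(pat) <- dimnames(model$lambda)
  q <- n_factors(model)
  phi_pat <- matrix(0, q, q)
  diag(phi_pat) <- NA_real_
  phi_pat[model$phi != 0] <- NA_real_
  cfa_spec(pat, identification = identification, phi = phi_pat, ...)
}

n_free_params <- function(spec) {
  q <- ncol(spec$loadings)
  free_lam <- sum(is.na(spec$loadings)) -
    if (spec$identification == "effect_coding") q else 0
  free_phi <- sum(is.na(spec$phi[lower.tri(spec$phi, diag = TRUE)]))
  free_lam + free_phi + sum(is.na(spec$theta))
}

# Parameter layout: index table mapping the free-parameter vector to matrix
# slots. Dependent (effect-coded) loadings are excluded from the vector.
par_layout <- function(spec) {
  p <- nrow(spec$loadings); q <- ncol(spec$loadings)
  lam <- which(is.na(spec$loadings), arr.ind = TRUE)
  if (spec$identification == "effect_coding") {
    dep <- cbind(spec$dependent, seq_len(q))
    keep <- !(paste(lam[, 1], lam[, 2]) %in% paste(dep[, 1], dep[, 2]))
    lam <- lam[keep, , drop = FALSE]
  }
  phi_idx <- which(is.na(spec$phi) & lower.tri(spec$phi, diag = TRUE),
                   arr.ind = TRUE)
  theta_idx <- which(is.na(spec$theta))
  list(lam = lam, phi = phi_idx, theta = theta_idx,
       n = nrow(lam) + nrow(phi_idx) + length(theta_idx))
}

par_names <- function(spec, layout) {
  vn <- rownames(spec$loadings); fn <- colnames(spec$loadings)
  c(sprintf("lambda[%s,%s]", vn[layout$lam[, 1]], fn[layout$lam[, 2]]),
    sprintf("phi[%s,%s]", fn[layout$phi[, 1]], fn[layout$phi[, 2]]),
    sprintf("theta[%s]", vn[layout$theta]))
}

# Free-parameter vector -> (Lambda, Phi, theta-diagonal) matrices.
par_to_matrices <- function(par, spec, layout) {
  lambda <- spec$loadings
  phi <- spec$phi
  theta <- spec$theta
  n_lam <- nrow(layout$lam); n_phi <- nrow(layout$phi)
  if (n_lam) lambda[layout$lam] <- par[seq_len(n_lam)]
  if (n_phi) {
    vals <- par[n_lam + seq_len(n_phi)]
    phi[layout$phi] <- vals
    phi[layout$phi[, c(2, 1), drop = FALSE]] <- vals
  }
  if (length(layout$theta)) {
    theta[layout$theta] <- par[n_lam + n_phi + seq_along(layout$theta)]
  }
  if (spec$identification == "effect_coding") {
    for (k in seq_len(ncol(lambda))) {
      d <- spec$dependent[k]
      lambda[d, k] <- spec$p_c[k] - sum(lambda[-d, k])
    }
  }
  list(lambda = lambda, phi = phi, theta = theta)
}

# Discrepancy and analytic gradient in the free parameters.
make_objective <- function(S, spec, layout) {
  p <- ncol(S)
  fn <- function(par) {
    m <- par_to_matrices(par, spec, layout)
    sigma <- m$lambda %*% m$phi %*% t(m$lambda) + diag(m$theta, p)
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdet <- 2 * sum(log(diag(ch)))
    sigma_inv <- chol2inv(ch)
    val <- logdet + sum(S * sigma_inv) -
      attr(S, "logdet_S") - p
    if (!is.finite(val)) 1e10 else val
  }
  gr <- function(par) {
    m <- par_to_matrices(par, spec, layout)
    sigma <- m$lambda %*% m$phi %*% t(m$lambda) + diag(m$theta, p)
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, length(par)))
    sigma_inv <- chol2inv(ch)
    G <- sigma_inv %*% (sigma - S) %*% sigma_inv  # dF = tr(G dSigma)
    dLam <- 2 * G %*% m$lambda %*% m$phi          # full dF/dLambda
    if (spec$identification == "effect_coding") {
      # lambda[d,k] = p_c - sum(others): each free loading in column k also
      # moves the dependent one by -1.
      for (k in seq_len(ncol(dLam))) {
        d <- spec$dependent[k]
        dLam[, k] <- dLam[, k] - dLam[d, k]
        dLam[d, k] <- 0
      }
    }
    dPhiFull <- t(m$lambda) %*% G %*% m$lambda
    g_lam <- if (nrow(layout$lam)) dLam[layout$lam] else numeric(0)
    g_phi <- if (nrow(layout$phi)) {
      vapply(seq_len(nrow(layout$phi)), function(r) {
        jj <- layout$phi[r, 1]; kk <- layout$phi[r, 2]
        if (jj == kk) dPhiFull[jj, jj] else 2 * dPhiFull[jj, kk]
      }, numeric(1))
    } else numeric(0)
    g_theta <- if (length(layout$theta)) diag(G)[layout$theta] else numeric(0)
    c(g_lam, g_phi, g_theta)
  }
  list(fn = fn, gr = gr)
}

start_values <- function(S, spec, layout) {
  s_diag <- diag(S)
  lam0 <- 0.5 * sqrt(s_diag[layout$lam[, 1]])
  phi0 <- ifelse(layout$phi[, 1] == layout$phi[, 2], 1, 0)
  theta0 <- 0.5 * s_diag[layout$theta]
  c(lam0, phi0, theta0)
}

#' Fit a CFA model by maximum likelihood
#'
#' Minimises [ml_discrepancy()] over the free parameters of a [cfa_spec()]
#' with BFGS and an analytic gradient, restarting until the gradient norm
#' falls below `1e-7` (or `max_restarts` is exhausted). Heywood estimates
#' (negative error variances) are returned with a flag, never bounded.
#' When `S` carries a sample size, chi-square-based fit indices are
#' populated via [fit_indices()].
#'
#' @param S A [sample_cov()] (or symmetric matrix).
#' @param spec A [cfa_spec()].
#' @param n Sample size (overrides the one stored in `S`).
#' @param se If `TRUE`, compute standard errors from the inverse numerical
#'   Hessian of the discrepancy scaled by `2/(n-1)`.
#' @param max_iter Iteration cap for each BFGS run.
#' @param max_restarts BFGS restarts from the current solution used to
#'   polish convergence.
#' @return A `cfa_fit` object: `estimates` ([cfa_model()]), `discrepancy`,
#'   `df`, fit indices, `converged`, `iterations`, `gradient_norm`,
#'   optionally a `parameters` tibble with standard errors and z values.
#' @export
fit_cfa <- function(S, spec, n = NULL, se = FALSE,
                    max_iter = 2000, max_restarts = 5) {
  S <- as_sample_cov(S, n)
  if (!is.null(n)) S$n <- as.integer(n)
  stopifnot(inherits(spec, "cfa_spec"))
  p <- ncol(S$values)
  if (nrow(spec$loadings) != p) {
    abort(sprintf("Spec has %d manifest variables; S has %d.",
                  nrow(spec$loadings), p))
  }
  df <- p * (p + 1) / 2 - n_free_params(spec)
  if (df < 0) {
    abort(sprintf("Model is not identified: df = %d < 0.", df))
  }

  layout <- par_layout(spec)
  Smat <- S$values
  attr(Smat, "logdet_S") <- as.numeric(determinant(Smat)$modulus)
  obj <- make_objective(Smat, spec, layout)
  par <- start_values(Smat, spec, layout)

  total_iter <- 0L
  res <- NULL
  for (r in seq_len(max_restarts + 1)) {
    res <- optim(par, obj$fn, obj$gr, method = "BFGS",
                 control = list(maxit = max_iter, reltol = 1e-15))
    total_iter <- total_iter + res$counts[["function"]]
    par <- res$par
    gnorm <- sqrt(sum(obj$gr(par)^2))
    if (gnorm < 1e-7) break
  }
  gnorm <- sqrt(sum(obj$gr(par)^2))
  converged <- is.finite(res$value) && gnorm < 1e-7

  m <- par_to_matrices(par, spec, layout)
  est <- cfa_model(m$lambda, m$phi, m$theta)

  params <- NULL
  if (se) {
    if (is.null(S$n)) abort("Standard errors require a sample size `n`.")
    H <- num_hessian(obj$gr, par)
    cov_par <- tryCatch(solve(H) * 2 / (S$n - 1), error = function(e) NULL)
    ses <- if (is.null(cov_par)) rep(NA_real_, length(par))
           else sqrt(pmax(diag(cov_par), 0))
    params <- tibble::tibble(
      term = par_names(spec, layout),
      estimate = par,
      std.error = ses,
      statistic = par / ses
    )
  }

  fit <- structure(
    list(estimates = est, spec = spec, S = S,
         discrepancy = res$value, df = df,
         chi_square = NA_real_, normed_chi_square = NA_real_,
         rmsea = NA_real_, srmr = NA_real_, cfi = NA_real_, gfi = NA_real_,
         converged = converged, iterations = total_iter,
         gradient_norm = gnorm, parameters = params),
    class = "cfa_fit")
  if (!is.null(S$n)) fit <- fit_indices(fit, S)
  fit
}

# Central-difference Hessian from the analytic gradient.
num_hessian <- function(gr, par, h = 1e-5) {
  k <- length(par)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    hj <- h * (1 + abs(par[j]))
    up <- par; up[j] <- up[j] + hj
    dn <- par; dn[j] <- dn[j] - hj
    H[, j] <- (gr(up) - gr(dn)) / (2 * hj)
  }
  (H + t(H)) / 2
}

#' Populate chi-square-based fit indices
#'
#' Standard definitions: `chi^2 = (n-1) F`; RMSEA from
#' `sqrt(max(chi^2 - df, 0) / (df (n-1)))` (reported as 0 with a note when
#' `df = 0`); SRMR as the root mean square standardized residual over the
#' lower triangle including the diagonal; CFI against the independence
#' baseline (fitted in closed form: implied covariance `diag(S)`); GFI from
#' the weighted residual trace form.
#'
#' @param fit A [fit_cfa()] result.
#' @param S The [sample_cov()] analysed (defaults to the one stored in
#'   `fit`); its `n` must be set.
#' @param baseline Optional baseline `cfa_fit`; the independence model is
#'   used when absent.
#' @return The `cfa_fit` with index fields filled in.
#' @export
fit_indices <- function(fit, S = fit$S, baseline = NULL) {
  stopifnot(inherits(fit, "cfa_fit"))
  S <- as_sample_cov(S)
  if (is.null(S$n)) abort("Fit indices require a sample size `n`.")
  n <- S$n; p <- ncol(S$values)
  F_val <- fit$discrepancy
  df <- fit$df
  chi2 <- (n - 1) * F_val

  if (is.null(baseline)) {
    # Independence model: Sigma_b = diag(S) is the closed-form ML solution.
    chS <- chol(S$values)
    F_b <- sum(log(diag(S$values))) - 2 * sum(log(diag(chS)))
    df_b <- p * (p - 1) / 2
  } else {
    F_b <- baseline$discrepancy
    df_b <- baseline$df
  }
  chi2_b <- (n - 1) * F_b

  sigma <- implied_covariance(fit$estimates)$values
  resid <- S$values - sigma
  d <- sqrt(diag(S$values))
  std_resid <- resid / tcrossprod(d)
  lower <- std_resid[lower.tri(std_resid, diag = TRUE)]
  srmr <- sqrt(mean(lower^2))

  if (df > 0) {
    rmsea <- sqrt(max(chi2 - df, 0) / (df * (n - 1)))
  } else {
    rmsea <- 0
    attr(rmsea, "note") <- "df = 0; RMSEA undefined, reported as 0"
  }
  denom <- max(chi2_b - df_b, chi2 - df, 0)
  cfi <- if (denom == 0) 1 else 1 - max(chi2 - df, 0) / denom
  sigma_inv <- solve(sigma)
  W <- sigma_inv %*% resid
  V <- sigma_inv %*% S$values
  gfi <- 1 - sum(diag(W %*% W)) / sum(diag(V %*% V))

  fit$chi_square <- chi2
  fit$normed_chi_square <- if (df > 0) chi2 / df else NA_real_
  fit$rmsea <- rmsea
  fit$srmr <- srmr
  fit$cfi <- cfi
  fit$gfi <- gfi
  fit$S <- S
  fit
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("<cfa_fit> %s identification; %s\n",
              x$spec$identification,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  discrepancy F = %.6g, df = %d, gradient norm = %.2e\n",
              x$discrepancy, x$df, x$gradient_norm))
  if (!is.na(x$chi_square)) {
    cat(sprintf("  chi^2(%d) = %.3f, chi^2/df = %.3f, RMSEA = %.3f, SRMR = %.3f, CFI = %.3f, GFI = %.3f\n",
                x$df, x$chi_square, x$normed_chi_square, x$rmsea, x$srmr,
                x$cfi, x$gfi))
  }
  print(x$estimates)
  invisible(x)
}
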