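# Comparison scaling: criterion number 1 turns each latent variance into
# the variance the factor explains in the indicators (lambda'lambda * phi),
# making contributions of e.g. trait vs. method factors directly comparable
# -- the factor-analytic analogue of standardized regression weights.

#' Variance explained by one factor
#'
#' `lambda' lambda * phi`, identical to the trace of `lambda phi lambda'`.
#' This is the value the latent variance takes after squared-loadings
#' scaling with criterion number 1.
#'
#' @param column Numeric loading vector of one factor.
#' @param phi Latent variance parameter (default 1).
#' @return The explained variance.
#' @export
explained_variance <- function(column, phi = 1) {
  stopifnot(is.numeric(column), is.numeric(phi), length(phi) == 1)
  if (!all(is.finite(column)) || !is.finite(phi)) {
    abort("Inputs must be finite.")
  }
  sum(column^2) * phi
}

#' Per-factor variance contributions via comparison scaling
#'
#' Applies squared-loadings scaling with criterion number 1 to every factor,
#' so each rescaled variance equals the factor's explained variance and the
#' factors can be ranked by contribution. The underlying rescaled solution
#' preserves the model-implied covariance. A factor with an all-zero loading
#' column has no defined constant; it is kept in the report with a
#' `degenerate` flag (constant 1, contribution 0) rather than dropped.
#'
#' Contributions are computed from the diagonal variance parameters only;
#' rescaled latent covariances (shared variance between correlated factors)
#' are attached as the `"shared"` attribute, and the rescaled solution as
#' `"solution"`.
#'
#' @param model A [cfa_model()].
#' @return A `contribution_report` tibble with columns `factor`, `phi`,
#'   `constant`, `scaled_variance`, `rank` (1 = largest contribution, ties
#'   broken by input order) and `degenerate`; the total across factors is
#'   attribute `"total"`.
#' @examples
#' m <- cfa_model(cbind(trait = rep(0.7, 3), method = rep(0.3, 3)),
#'                phi = c(1, 1), theta = rep(0.4, 3))
#' comparison_scaling(m)
#' @export
comparison_scaling <- function(model) {
  stopifnot(inherits(model, "cfa_model"))
  q <- n_factors(model)
  fnames <- colnames(model$lambda)
  degenerate <- vapply(seq_len(q), function(k) all(model$lambda[, k] == 0),
                       logical(1))
  constants <- vapply(seq_len(q), function(k) {
    if (degenerate[k]) 1 else sum_squares_constant(model$lambda[, k], 1)
  }, numeric(1))
  if (any(degenerate)) {
    warn(sprintf("Factor(s) %s have all-zero loadings; flagged as degenerate.",
                 paste(fnames[degenerate], collapse = ", ")))
  }
  plan <- structure(list(method = "sum_squares",
                         per_factor = setNames(rep(1, q), fnames),
                         constants = setNames(constants, fnames)),
                    class = "scaling_plan")
  sol <- rescale(model, plan)

  report <- tibble::tibble(
    factor = fnames,
    phi = diag(model$phi),
    constant = constants,
    scaled_variance = ifelse(degenerate, 0, diag(sol$phi_star)),
    degenerate = degenerate
  )
  report$rank <- rank(-report$scaled_variance, ties.method = "first")

  shared <- NULL
  if (q > 1) {
    idx <- which(upper.tri(sol$phi_star), arr.ind = TRUE)
    shared <- tibble::tibble(
      factor_1 = fnames[idx[, 1]], factor_2 = fnames[idx[, 2]],
      scaled_covariance = sol$phi_star[idx]
    )
    shared <- dplyr::filter(shared, .data$scaled_covariance != 0)
  }

  structure(report,
            class = c("contribution_report", class(report)),
            total = sum(report$scaled_variance),
            shared = shared,
            solution = sol)
}

#' @export
print.contribution_report <- function(x, ...) {
  cat("Per-factor variance contributions (criterion number 1):\n")
  NextMethod()
  cat(sprintf("Total across factors: %.4f\n", attr(x, "total")))
  sh <- attr(x, "shared")
  if (!is.null(sh) && nrow(sh) > 0) {
    cat("Shared variance (rescaled latent covariances):\n")
    print(sh)
  }
  invisible(x)
}

#' Largest eigenvalue of a one-factor true part
#'
#' For a single factor the true part `lambda phi lambda'` is rank one with
#' nonzero eigenvalue `lambda' lambda * phi`; comparison scaling therefore
#' reports values on the eigenvalue scale for unidimensional models. This
#' helper computes that eigenvalue by eigendecomposition so the identity
#' can be checked numerically.
#'
#' @param column Numeric loading vector.
#' @param phi Positive latent variance.
#' @return The largest eigenvalue of `lambda phi lambda'`.
#' @export
rank1_eigen_check <- function(column, phi = 1) {
  stopifnot(is.numeric(column), is.finite(phi), phi > 0)
  tp <- phi * tcrossprod(column)
  max(eigen(tp, symmetric = TRUE, only.values = TRUE)$values)
}

#' @rdname comparison_scaling
#' @param object A `contribution_report`.
#' @param ... Unused.
#' @export
autoplot.contribution_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$factor <- factor(df$factor, levels = df$factor[order(df$rank)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor,
                                   y = .data$scaled_variance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Scaled variance (criterion number 1)",
                  title = "Latent-variable contributions to responding") +
    ggplot2::theme_minimal()
}
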