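# broom-style tidiers and ggplot2 autoplot methods.

#' Tidy a fitted CFA model
#'
#' One row per model parameter (free and fixed): loadings, latent
#' variances/covariances and error variances, with standard errors and z
#' statistics when the fit computed them (`se = TRUE` in [fit_cfa()]).
#'
#' @param x A [fit_cfa()] result.
#' @param ... Unused.
#' @return A tibble with columns `term`, `matrix`, `row`, `col`,
#'   `estimate`, and (when available) `std.error`, `statistic`.
#' @export
tidy.cfa_fit <- function(x, ...) {
  est <- x$estimates
  vn <- rownames(est$lambda); fn <- colnames(est$lambda)
  lam_idx <- which(est$lambda != 0 | is.na(x$spec$loadings), arr.ind = TRUE)
  lam <- tibble::tibble(
    term = sprintf("lambda[%s,%s]", vn[lam_idx[, 1]], fn[lam_idx[, 2]]),
    matrix = "lambda", row = vn[lam_idx[, 1]], col = fn[lam_idx[, 2]],
    estimate = est$lambda[lam_idx])
  phi_idx <- which(lower.tri(est$phi, diag = TRUE) &
                     (est$phi != 0 | is.na(x$spec$phi)), arr.ind = TRUE)
  phi <- tibble::tibble(
    term = sprintf("phi[%s,%s]", fn[phi_idx[, 1]], fn[phi_idx[, 2]]),
    matrix = "phi", row = fn[phi_idx[, 1]], col = fn[phi_idx[, 2]],
    estimate = est$phi[phi_idx])
  theta <- tibble::tibble(
    term = sprintf("theta[%s]", vn),
    matrix = "theta", row = vn, col = vn,
    estimate = diag(est$theta))
  out <- dplyr::bind_rows(lam, phi, theta)
  if (!is.null(x$parameters)) {
    out <- dplyr::left_join(out,
                            dplyr::select(x$parameters, "term", "std.error",
                                          "statistic"),
                            by = "term")
  }
  out
}

#' Glance at a fitted CFA model
#'
#' @param x A [fit_cfa()] result.
#' @param ... Unused.
#' @return A one-row tibble: discrepancy, chi-square, df, normed
#'   chi-square, RMSEA, SRMR, CFI, GFI, convergence diagnostics and sample
#'   size.
#' @export
glance.cfa_fit <- function(x, ...) {
  tibble::tibble(
    discrepancy = x$discrepancy,
    chi_square = x$chi_square,
    df = x$df,
    normed_chi_square = x$normed_chi_square,
    rmsea = as.numeric(x$rmsea),
    srmr = x$srmr,
    cfi = x$cfi,
    gfi = x$gfi,
    converged = x$converged,
    iterations = x$iterations,
    gradient_norm = x$gradient_norm,
    n = if (is.null(x$S$n)) NA_integer_ else x$S$n
  )
}

#' Tidy a rescaled factor solution
#'
#' @param x A [rescale()] result.
#' @param ... Unused.
#' @return A tibble with one row per factor: scaling constant, original and
#'   rescaled latent variance.
#' @export
tidy.scaled_solution <- function(x, ...) {
  tibble::tibble(
    factor = colnames(x$lambda_star),
    method = x$plan$method,
    parameter = unname(x$plan$per_factor),
    constant = unname(x$plan$constants),
    phi = diag(x$source$phi),
    phi_star = diag(x$phi_star)
  )
}

#' Plot a criterion-sensitivity grid
#'
#' Scaled variance against the criterion specification, one line per
#' loading value, faceted by number of manifest variables.
#'
#' @param object A long [criterion_sensitivity_table()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.criterion_sensitivity <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_c, y = .data$scaled_variance,
                                   colour = factor(.data$loading))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~p, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "criterion number p_c", y = "scaled variance",
                  colour = "loading") +
    ggplot2::theme_minimal()
}
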