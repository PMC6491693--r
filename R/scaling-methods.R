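# Scaling constants and rescaling.
#
# Every scaling method chooses a positive constant c per factor and applies
# lambda* = c lambda, phi* = phi / c^2 (off-diagonal latent covariances are
# divided by c_j c_k). The true part Lambda Phi Lambda' is unchanged by
# construction; the methods differ only in how c is picked.

#' Scaling constant for the marker-variable method
#'
#' Identification by fixing one loading to 1: the constant is the reciprocal
#' of the chosen marker loading, so that after rescaling the marker loading
#' is exactly one. Requires a strictly positive marker loading; a
#' non-positive marker does not admit a positive constant and the caller
#' should pick another indicator.
#'
#' @param column Numeric loading vector for one factor.
#' @param marker_index Index of the marker indicator within `column`.
#' @return The scaling constant `1 / column[marker_index]`.
#' @export
marker_constant <- function(column, marker_index) {
  stopifnot(is.numeric(column), length(marker_index) == 1)
  if (marker_index < 1 || marker_index > length(column)) {
    abort(sprintf("`marker_index` must lie in 1..%d.", length(column)))
  }
  lam <- column[marker_index]
  if (!is.finite(lam) || lam <= 0) {
    abort(sprintf(
      "Marker loading at index %d is %s; a marker must be strictly positive. Choose another indicator.",
      marker_index, format(lam)))
  }
  1 / lam
}

#' Scaling constant for the reference-group method
#'
#' Identification by fixing the latent variance: `c = sqrt(phi / target)`,
#' so that the rescaled variance `phi / c^2` equals `target` (1 by default,
#' the standardized latent variable). When the target equals the original
#' variance the constant is one.
#'
#' @param phi Original latent variance parameter (must be positive).
#' @param target Desired rescaled variance (default 1).
#' @return The scaling constant.
#' @export
reference_constant <- function(phi, target = 1) {
  if (!is.finite(phi) || phi <= 0) {
    abort("`phi` must be a positive finite number for reference-group scaling.")
  }
  if (!is.finite(target) || target <= 0) {
    abort("`target` must be a positive finite number.")
  }
  sqrt(phi / target)
}

#' Scaling constant for the effect-coding method
#'
#' Criterion-based scaling of the loading *sum*: `c = p_c / sum(column)`,
#' so the rescaled loadings sum to the criterion number `p_c` (classically
#' the number of manifest variables, making the latent variance an average
#' of indicator variances).
#'
#' @param column Numeric loading vector for one factor.
#' @param p_c Criterion number (positive).
#' @return The scaling constant.
#' @export
effect_coding_constant <- function(column, p_c) {
  stopifnot(is.numeric(column))
  if (!is.finite(p_c) || p_c <= 0) abort("`p_c` must be positive.")
  s <- sum(column)
  if (!is.finite(s) || s <= 1e-12) {
    abort(sprintf(
      "Loading sum %s is non-positive or degenerate; effect-coding scaling is undefined.",
      format(s)))
  }
  p_c / s
}

#' Scaling constant for the squared-loadings criterion method
#'
#' Criterion-based scaling of the *sum of squared* loadings:
#' `c = sqrt(p_c / (lambda' lambda))`, so the rescaled squared loadings sum
#' to `p_c`. With `p_c = 1` the rescaled variance equals the explained
#' variance `lambda' lambda * phi` (see [comparison_scaling()]).
#'
#' @inheritParams effect_coding_constant
#' @return The scaling constant.
#' @export
sum_squares_constant <- function(column, p_c) {
  stopifnot(is.numeric(column))
  if (!is.finite(p_c) || p_c <= 0) abort("`p_c` must be positive.")
  ss <- sum(column^2)
  if (ss <= 0) {
    abort("All-zero loading column; squared-loadings scaling is undefined.")
  }
  sqrt(p_c / ss)
}

#' Scaled variance parameter
#'
#' The rescaled latent variance `phi / c^2` for a scaling constant `c > 0`.
#'
#' @param phi Original variance parameter (may be negative; the sign is
#'   inherited by the scaled value).
#' @param c Positive scaling constant.
#' @return `phi / c^2`.
#' @export
scaled_variance <- function(phi, c) {
  if (!is.finite(c) || c <= 0) abort("`c` must be a positive finite number.")
  phi / c^2
}

#' Build a per-factor scaling plan
#'
#' Computes one scaling constant per factor of a model by the chosen method.
#' `per_factor` supplies the method's parameter for each factor: the marker
#' index (`marker`), the target variance (`reference_group`, default 1), or
#' the criterion number `p_c` (`effect_coding`, `sum_squares`). A scalar is
#' recycled across factors.
#'
#' @param model A [cfa_model()].
#' @param method One of `"marker"`, `"reference_group"`, `"effect_coding"`,
#'   `"sum_squares"`.
#' @param per_factor Numeric vector of per-factor parameters (length q or 1).
#' @return A `scaling_plan`: method, per-factor parameters and positive
#'   constants, named by factor.
#' @examples
#' m <- cfa_model(matrix(c(0.5, 0.8, 0.4), 3, 1), phi = 1, theta = 0.5)
#' build_plan(m, "marker", 1)
#' build_plan(m, "sum_squares", 1)
#' @export
build_plan <- function(model, method = c("marker", "reference_group",
                                         "effect_coding", "sum_squares"),
                       per_factor = NULL) {
  stopifnot(inherits(model, "cfa_model"))
  method <- match.arg(method)
  q <- n_factors(model)
  if (is.null(per_factor)) {
    if (method == "reference_group") per_factor <- 1
    else abort("`per_factor` must supply one parameter per factor.")
  }
  if (!length(per_factor) %in% c(1L, q)) {
    abort(sprintf("`per_factor` must have length 1 or %d.", q))
  }
  per_factor <- rep(per_factor, length.out = q)
  fnames <- colnames(model$lambda)

  constants <- vapply(seq_len(q), function(k) {
    col <- model$lambda[, k]
    tryCatch(
      switch(method,
        marker          = marker_constant(col, as.integer(per_factor[k])),
        reference_group = reference_constant(model$phi[k, k], per_factor[k]),
        effect_coding   = effect_coding_constant(col, per_factor[k]),
        sum_squares     = sum_squares_constant(col, per_factor[k])
      ),
      error = function(e) {
        abort(sprintf("Factor %s ('%s'): %s", k, fnames[k], conditionMessage(e)))
      })
  }, numeric(1))
  names(constants) <- fnames

  structure(list(method = method, per_factor = setNames(per_factor, fnames),
                 constants = constants),
            class = "scaling_plan")
}

#' @export
print.scaling_plan <- function(x, ...) {
  cat(sprintf("<scaling_plan> method: %s\n", x$method))
  print(tibble::tibble(factor = names(x$constants),
                       parameter = unname(x$per_factor),
                       constant = unname(x$constants)))
  invisible(x)
}

#' Rescale a factor solution by a scaling plan
#'
#' Applies `Lambda* = Lambda diag(c)` and `Phi*_jk = Phi_jk / (c_j c_k)`.
#' The error covariance is untouched and the true part
#' `Lambda Phi Lambda'` is preserved exactly, so the rescaled solution
#' implies the same covariance matrix as the input.
#'
#' @param model A [cfa_model()].
#' @param plan A [build_plan()] result, or a positive numeric vector of
#'   constants (length q or 1) used directly.
#' @return A `scaled_solution`: `lambda_star`, `phi_star`, the `plan`, and
#'   the `source` model.
#' @export
rescale <- function(model, plan) {
  stopifnot(inherits(model, "cfa_model"))
  q <- n_factors(model)
  if (is.numeric(plan)) {
    plan <- structure(list(method = "manual",
                           per_factor = rep(NA_real_, q),
                           constants = setNames(rep(plan, length.out = q),
                                                colnames(model$lambda))),
                      class = "scaling_plan")
  }
  stopifnot(inherits(plan, "scaling_plan"))
  cc <- plan$constants
  if (length(cc) != q) abort(sprintf("Plan has %d constants; model has %d factors.",
                                     length(cc), q))
  if (any(!is.finite(cc)) || any(cc <= 0)) {
    abort("All scaling constants must be positive and finite.")
  }
  lambda_star <- sweep(model$lambda, 2, cc, `*`)
  phi_star <- model$phi / tcrossprod(cc)
  phi_star <- (phi_star + t(phi_star)) / 2
  dimnames(lambda_star) <- dimnames(model$lambda)
  dimnames(phi_star) <- dimnames(model$phi)
  structure(list(lambda_star = lambda_star, phi_star = phi_star,
                 plan = plan, source = model),
            class = "scaled_solution")
}

#' @export
print.scaled_solution <- function(x, ...) {
  cat(sprintf("<scaled_solution> method: %s\n", x$plan$method))
  cat("Rescaled loadings (lambda*):\n"); print(round(x$lambda_star, 4))
  cat("Rescaled latent covariance (phi*):\n"); print(round(x$phi_star, 4))
  invisible(x)
}

#' Convert a scaled solution back to a model
#'
#' Bundles the rescaled loadings and latent covariance with the (unchanged)
#' error covariance of the source model, so a rescaled solution can be fed
#' back into any function expecting a [cfa_model()].
#'
#' @param x A `scaled_solution`.
#' @return A [cfa_model()].
#' @export
as_cfa_model <- function(x) {
  stopifnot(inherits(x, "scaled_solution"))
  cfa_model(x$lambda_star, x$phi_star, x$source$theta, x$source$mu)
}

#' Sensitivity of the scaled variance to the criterion number
#'
#' Tabulates the squared-loadings criterion method over grids of equal
#' loading values, numbers of manifest variables and criterion numbers.
#' A criterion given as a character fraction (`"1/1"`, `"1/2"`, `"1/4"`)
#' is interpreted as a proportion of p (so `p_c = r * p`); a numeric
#' criterion is an absolute `p_c`. Each cell is
#' `phi * p * loading^2 / p_c`, computed through [sum_squares_constant()]
#' and [scaled_variance()].
#'
#' @param loading_values Equal-loading values, one column per value.
#' @param p_values Numbers of manifest variables.
#' @param criteria List or vector of criteria: numbers (absolute `p_c`) or
#'   strings like `"1/2"` (proportion of `p`).
#' @param phi Original variance parameter (default 1).
#' @param wide If `TRUE`, return one row per (criterion, p) with one column
#'   per loading value; otherwise a long tibble.
#' @return A tibble with columns `criterion`, `p`, `p_c`, and either
#'   `loading`/`scaled_variance` (long) or one column per loading (wide).
#' @examples
#' criterion_sensitivity_table(c(0.2, 0.4, 0.6), c(4, 8, 12),
#'                             c("1/1", "1/2", "1/4"))
#' @export
criterion_sensitivity_table <- function(loading_values = c(0.2, 0.4, 0.6),
                                        p_values = c(4, 8, 12),
                                        criteria = c("1/1", "1/2", "1/4"),
                                        phi = 1, wide = FALSE) {
  stopifnot(is.numeric(loading_values), is.numeric(p_values))
  crit <- tibble::tibble(criterion = vapply(criteria, as.character, character(1)))
  grid <- tidyr::crossing(crit, p = as.numeric(p_values),
                          loading = as.numeric(loading_values))
  grid <- dplyr::mutate(grid,
    p_c = unname(purrr::map2_dbl(.data$criterion, .data$p, parse_criterion)),
    scaled_variance = purrr::pmap_dbl(
      list(.data$loading, .data$p, .data$p_c),
      function(lam, p, p_c) {
        col <- rep(lam, p)
        if (all(col == 0)) return(0)
        scaled_variance(phi, sum_squares_constant(col, p_c))
      }))
  grid <- dplyr::arrange(grid,
                         match(.data$criterion, vapply(criteria, as.character,
                                                       character(1))),
                         .data$p, .data$loading)
  if (wide) {
    grid <- tidyr::pivot_wider(grid, names_from = "loading",
                               values_from = "scaled_variance",
                               names_prefix = "loading_")
  } else {
    class(grid) <- c("criterion_sensitivity", class(grid))
  }
  grid
}

# "1/2" -> p_c = p/2; plain number -> absolute p_c.
parse_criterion <- function(criterion, p) {
  if (grepl("/", criterion, fixed = TRUE)) {
    parts <- as.numeric(strsplit(criterion, "/", fixed = TRUE)[[1]])
    if (length(parts) != 2 || any(!is.finite(parts)) || parts[2] == 0) {
      abort(sprintf("Cannot parse criterion proportion '%s'.", criterion))
    }
    p_c <- (parts[1] / parts[2]) * p
  } else {
    p_c <- as.numeric(criterion)
  }
  if (!is.finite(p_c) || p_c <= 0) {
    abort(sprintf("Criterion number must be positive (got %s).", format(p_c)))
  }
  p_c
}
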