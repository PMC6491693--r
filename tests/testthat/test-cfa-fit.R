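test_that("ML discrepancy has its closed-form values", {
  set.seed(131)
  m <- random_model(4, 1)
  sigma <- implied_covariance(m)
  expect_equal(ml_discrepancy(sigma$values, sigma), 0)

  # S = I (p = 2), Sigma = diag(2, 2): log|Sigma| + tr(S Sigma^-1) - 0 - 2
  expect_equal(ml_discrepancy(diag(2), diag(2, 2)), 2 * log(2) - 1)

  expect_error(ml_discrepancy(diag(2), matrix(c(1, 2, 2, 1), 2, 2)),
               "positive definite")
})

test_that("a just-identified one-factor model reproduces the sample exactly", {
  set.seed(141)
  truth <- generate_model(p = 3, loadings = 0.7, phi = 1)
  S <- sample_study(truth, n = 60, seed = 9)$sample
  spec <- spec_from_model(truth, "marker", markers = 1)
  f <- fit_cfa(S, spec)
  expect_lt(abs(f$discrepancy), 1e-8)
  expect_equal(f$df, 0)
})

test_that("population covariances are recovered under each identification", {
  set.seed(151)
  truth <- generate_model(p = 6, loadings = 0.65, phi = 1.4,
                          theta = runif(6, 0.3, 0.8))
  pop <- implied_covariance(truth)$values

  # marker: free loadings recover lambda / lambda_1, phi recovers phi lambda_1^2
  fm <- fit_cfa(pop, spec_from_model(truth, "marker", markers = 1))
  expect_true(fm$converged)
  expect_equal(unname(fm$estimates$lambda[, 1]),
               truth$lambda[, 1] / truth$lambda[1, 1], tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(fm$estimates$phi[1, 1],
               truth$phi[1, 1] * truth$lambda[1, 1]^2, tolerance = 1e-4)

  # reference group: loadings recover lambda sqrt(phi)
  fr <- fit_cfa(pop, spec_from_model(truth, "reference_group"))
  expect_equal(unname(fr$estimates$lambda[, 1]),
               truth$lambda[, 1] * sqrt(truth$phi[1, 1]), tolerance = 1e-4,
               ignore_attr = TRUE)

  # effect coding with p_c = p: constancy-equal to the marker solution
  fe <- fit_cfa(pop, spec_from_model(truth, "effect_coding", p_c = 6))
  expect_equal(sum(fe$estimates$lambda), 6, tolerance = 1e-10)
  expect_lt(constancy_distance(fe$estimates, fm$estimates), 1e-6)
  # error variances are identification-invariant
  expect_equal(diag(fe$estimates$theta), diag(fm$estimates$theta),
               tolerance = 1e-5)
})

test_that("post-hoc rescaling agrees with the estimation-time constraint", {
  set.seed(161)
  truth <- random_structured_model(q = 2, per_factor = 3, correlated = TRUE)
  pop <- implied_covariance(truth)$values
  p_c <- c(3, 3)
  # route 1: estimate under effect coding directly
  direct <- fit_cfa(pop, spec_from_model(truth, "effect_coding", p_c = p_c))
  # route 2: estimate under reference group, rescale afterwards
  ref <- fit_cfa(pop, spec_from_model(truth, "reference_group"))
  posthoc <- rescale(ref$estimates, build_plan(ref$estimates, "effect_coding", p_c))
  expect_equal(unname(posthoc$lambda_star), unname(direct$estimates$lambda),
               tolerance = 1e-5)
  expect_equal(unname(posthoc$phi_star), unname(direct$estimates$phi),
               tolerance = 1e-5)
})

test_that("fit indices follow the standard definitions", {
  set.seed(171)
  truth <- generate_model(p = 5, loadings = 0.6)
  pop <- implied_covariance(truth)$values
  spec <- spec_from_model(truth, "marker", markers = 1)

  # perfect fit limits
  f0 <- fit_cfa(sample_cov(pop, n = 200), spec)
  expect_equal(f0$chi_square, 0, tolerance = 1e-8)
  expect_equal(as.numeric(f0$rmsea), 0)
  expect_equal(f0$cfi, 1)
  expect_equal(f0$gfi, 1, tolerance = 1e-8)

  # chi-square is (n - 1) F
  fake <- f0; fake$discrepancy <- 0.1; fake$df <- 16L
  fi <- fit_indices(fake, sample_cov(pop, n = 100))
  expect_equal(fi$chi_square, 9.9)
  expect_equal(fi$normed_chi_square, 9.9 / 16)

  # misfit scenario checked against an independent re-implementation
  S <- sample_study(truth, n = 150, seed = 5)$sample
  f <- fit_cfa(S, spec)
  n <- 150; p <- 5
  sigma <- implied_covariance(f$estimates)$values
  chi2_o <- (n - 1) * f$discrepancy
  F_b_o <- log(prod(diag(S$values))) - log(det(S$values))
  chi2_b_o <- (n - 1) * F_b_o
  rmsea_o <- sqrt(max(chi2_o - f$df, 0) / (f$df * (n - 1)))
  acc <- 0; cnt <- 0
  for (i in 1:p) for (j in 1:i) {
    acc <- acc + ((S$values[i, j] - sigma[i, j]) /
                    sqrt(S$values[i, i] * S$values[j, j]))^2
    cnt <- cnt + 1
  }
  srmr_o <- sqrt(acc / cnt)
  cfi_o <- 1 - max(chi2_o - f$df, 0) /
    max(chi2_b_o - p * (p - 1) / 2, chi2_o - f$df, 0)
  expect_equal(f$chi_square, chi2_o)
  expect_equal(as.numeric(f$rmsea), rmsea_o, tolerance = 1e-10)
  expect_equal(f$srmr, srmr_o, tolerance = 1e-10)
  expect_equal(f$cfi, cfi_o, tolerance = 1e-10)
})

test_that("diagonal adjustment changes only the diagonal", {
  set.seed(181)
  R <- diag(9)
  R[lower.tri(R)] <- runif(36, 0.1, 0.5)
  R <- (R + t(R)) / 2; diag(R) <- 1
  S <- sample_cov(R, is_correlation = TRUE)
  adj <- adjust_diagonal(S, mtmm_adjusted_diagonal)
  expect_equal(diag(adj$values),
               c(1.145, 1.140, 1.145, 1.005, 0.965, 0.965, 0.940, 1.010, 0.980),
               ignore_attr = TRUE)
  off <- function(m) m[row(m) != col(m)]
  expect_identical(off(adj$values), off(S$values))
  # identity substitution leaves the matrix unchanged
  same <- adjust_diagonal(S, diag(S$values))
  expect_equal(same$values, S$values, ignore_attr = TRUE)
  expect_error(adjust_diagonal(S, rep(1, 3)), "length")
})

test_that("z statistics are invariant to the criterion number", {
  set.seed(191)
  truth <- generate_model(p = 5, loadings = 0.6, phi = 1.2,
                          theta = runif(5, 0.4, 0.8))
  S <- sample_study(truth, n = 400, seed = 77)$sample
  f1 <- fit_cfa(S, spec_from_model(truth, "effect_coding", p_c = 1), se = TRUE)
  f3 <- fit_cfa(S, spec_from_model(truth, "effect_coding", p_c = 3), se = TRUE)
  expect_true(f1$converged && f3$converged)
  expect_equal(f1$parameters$statistic, f3$parameters$statistic,
               tolerance = 1e-6)
})

test_that("specification errors are caught before optimisation", {
  # p = 2 one-factor marker model has more parameters than moments
  pat <- matrix(NA_real_, 2, 1)
  spec <- cfa_spec(pat, "marker", markers = 1)
  expect_error(fit_cfa(diag(2), spec), "not identified")
  expect_error(cfa_spec(pat, "effect_coding"), "p_c")
  expect_error(cfa_spec(pat, "marker"), "markers")
})

test_that("tidy and glance expose estimates and fit summaries", {
  set.seed(201)
  truth <- generate_model(p = 4, loadings = 0.7)
  S <- sample_study(truth, n = 300, seed = 3)$sample
  f <- fit_cfa(S, spec_from_model(truth, "marker", markers = 1), se = TRUE)
  td <- tidy(f)
  expect_true(all(c("term", "matrix", "estimate", "std.error", "statistic")
                  %in% names(td)))
  expect_equal(sum(td$matrix == "theta"), 4)
  gl <- glance(f)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$df, 2)
  expect_true(gl$converged)
  expect_equal(gl$n, 300L)
})
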