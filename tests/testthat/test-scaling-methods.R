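test_that("per-method constants match their defining identities", {
  # marker: c = 1/lambda_marker
  expect_equal(marker_constant(c(0.5, 0.8, 0.4), 1), 2)
  expect_equal(marker_constant(c(1.0, 0.7), 1), 1)
  expect_error(marker_constant(c(-0.3, 0.6), 1), "positive")
  expect_error(marker_constant(c(0.5, 0.6), 5), "lie in")

  # reference group: c = sqrt(phi/target)
  expect_equal(reference_constant(1, 1), 1)
  expect_equal(reference_constant(4, 1), 2)
  expect_equal(reference_constant(0.25, 1), 0.5)
  expect_error(reference_constant(-1, 1), "positive")
  expect_error(reference_constant(1, 0), "positive")

  # effect coding: c = p_c / sum(lambda)
  expect_equal(effect_coding_constant(rep(1, 4), 4), 1)
  expect_equal(effect_coding_constant(c(0.5, 1.0, 1.5), 3), 1)
  expect_equal(effect_coding_constant(rep(0.2, 4), 4), 5)
  expect_error(effect_coding_constant(c(0.5, -0.5), 2), "degenerate|non-positive")

  # squared loadings: c = sqrt(p_c / lambda'lambda)
  expect_equal(sum_squares_constant(rep(0.2, 4), 4), 5)
  expect_equal(scaled_variance(1, sum_squares_constant(rep(0.2, 4), 4)), 0.04)
  expect_equal(scaled_variance(1, sum_squares_constant(rep(0.6, 12), 1)), 4.32)
  expect_equal(sum_squares_constant(c(1, 1), 2), 1)
  expect_error(sum_squares_constant(rep(0, 3), 1), "zero")

  # scaled variance phi / c^2
  expect_equal(scaled_variance(1, 5), 0.04)
  expect_equal(scaled_variance(2.7, 1), 2.7)
  expect_equal(scaled_variance(2, 2), 0.5)
  expect_error(scaled_variance(1, -1), "positive")
})

test_that("build_plan dispatches per factor and annotates failures", {
  set.seed(51)
  m1 <- cfa_model(c(0.5, 0.7, 0.6), phi = 2, theta = rep(0.5, 3))
  plan <- build_plan(m1, "sum_squares", 1)
  expect_equal(unname(plan$constants), sqrt(1 / sum(m1$lambda^2)))

  lam2 <- cbind(a = c(0.5, 0.8, 0.4, 0.6), b = c(0.3, 0.9, 0.7, 0.2))
  m2 <- cfa_model(lam2, phi = c(1, 1), theta = rep(0.5, 4))
  plan2 <- build_plan(m2, "marker", c(1, 3))
  expect_equal(unname(plan2$constants), c(1 / 0.5, 1 / 0.7))

  lam3 <- lam2; lam3[1, 1] <- 0
  m3 <- cfa_model(lam3, phi = c(1, 1), theta = rep(0.5, 4))
  expect_error(build_plan(m3, "marker", c(1, 3)), "Factor 1")
})

test_that("rescale applies the constants and leaves the true part untouched", {
  # identity plan
  set.seed(61)
  m <- random_model(4, 2, correlated = TRUE)
  sol_id <- rescale(m, c(1, 1))
  expect_equal(sol_id$lambda_star, m$lambda)
  expect_equal(sol_id$phi_star, m$phi)

  # marker on one factor: lambda* = (1, 1.6), phi* = phi lambda_1^2
  m1 <- cfa_model(c(0.5, 0.8), phi = 1, theta = c(0.5, 0.5))
  sol <- rescale(m1, build_plan(m1, "marker", 1))
  expect_equal(unname(sol$lambda_star[, 1]), c(1.0, 1.6))
  expect_equal(sol$phi_star[1, 1], 0.25)

  # correlated factors: phi*_jk = phi_jk / (c_j c_k); fixed 4 x 2 Lambda
  lam <- cbind(c(0.6, 0.5, 0.0, 0.0), c(0.0, 0.0, 0.7, 0.4))
  phi <- matrix(c(1, 0.4, 0.4, 1), 2, 2)
  m2 <- cfa_model(lam, phi, rep(0.5, 4))
  sol2 <- rescale(m2, c(2, 4))
  expect_equal(sol2$phi_star[1, 2], 0.4 / 8)
  # explicit multiplication oracle for the preserved product
  oracle <- lam %*% phi %*% t(lam)
  got <- sol2$lambda_star %*% sol2$phi_star %*% t(sol2$lambda_star)
  expect_lt(max(abs(got - oracle)), 1e-12)

  expect_error(rescale(m2, c(2, -1)), "positive")
})

test_that("each method's post-condition holds after rescaling", {
  set.seed(71)
  methods <- c("marker", "reference_group", "effect_coding", "sum_squares")
  for (rep in 1:125) {
    p <- sample(3:10, 1); q <- sample(1:3, 1)
    m <- random_model(p, q, correlated = q > 1 && runif(1) < 0.5)
    for (method in methods) {
      par <- switch(method,
        marker = sample(p, q, replace = TRUE),
        reference_group = runif(q, 0.5, 2),
        effect_coding = runif(q, 0.5, 2 * p),
        sum_squares = runif(q, 0.5, 2 * p))
      sol <- rescale(m, build_plan(m, method, par))
      expect_lt(constancy_distance(m, sol), 1e-10)
      for (k in seq_len(q)) {
        val <- switch(method,
          marker = sol$lambda_star[par[k], k] - 1,
          reference_group = sol$phi_star[k, k] - par[k],
          effect_coding = sum(sol$lambda_star[, k]) - par[k],
          sum_squares = sum(sol$lambda_star[, k]^2) - par[k])
        expect_lt(abs(val), 1e-12)
      }
    }
  }
})

test_that("round-trip rescaling restores the original solution", {
  set.seed(81)
  for (rep in 1:20) {
    m <- random_model(sample(3:8, 1), sample(1:3, 1), correlated = TRUE)
    plan <- build_plan(m, "sum_squares", runif(1, 0.5, 5))
    sol <- rescale(m, plan)
    back <- rescale(as_cfa_model(sol), 1 / plan$constants)
    expect_lt(max(abs(back$lambda_star - m$lambda)), 1e-12)
    expect_lt(max(abs(back$phi_star - m$phi)), 1e-12)
  }
})

test_that("the scaled variance falls as the criterion number grows", {
  set.seed(91)
  lam <- runif(7, 0.2, 0.9)
  phi <- 1.3
  grid <- seq(0.5, 10, length.out = 20)
  phi_sc <- vapply(grid, function(p_c) {
    scaled_variance(phi, sum_squares_constant(lam, p_c))
  }, numeric(1))
  expect_true(all(diff(phi_sc) < 0))
  # and p_c,A > p_c,B implies phi_sc,A < phi_sc,B pairwise
  expect_true(all(outer(phi_sc, phi_sc, `<`)[outer(grid, grid, `>`)]))
})

test_that("proportional criteria make the scaled variance independent of p", {
  for (r in c(1, 1 / 2, 1 / 4)) {
    for (lam in c(0.2, 0.4, 0.6)) {
      vals <- vapply(c(4, 8, 12), function(p) {
        scaled_variance(1, sum_squares_constant(rep(lam, p), r * p))
      }, numeric(1))
      expect_equal(max(vals) - min(vals), 0, tolerance = 1e-14)
    }
  }
})

test_that("criterion table accepts proportions and absolute numbers", {
  tab <- criterion_sensitivity_table(c(0, 0.4), c(4, 6), list("1/2", 5), phi = 2)
  expect_s3_class(tab, "tbl_df")
  # zero loadings give zero cells
  expect_true(all(tab$scaled_variance[tab$loading == 0] == 0))
  # "1/2" with odd p is accepted as a real criterion
  odd <- criterion_sensitivity_table(0.4, 5, "1/2")
  expect_equal(odd$p_c, 2.5)
  expect_equal(odd$scaled_variance, 5 * 0.16 / 2.5)
  expect_error(criterion_sensitivity_table(0.4, 4, "-2"), "positive")
  # wide layout has one column per loading value
  wide <- criterion_sensitivity_table(c(0.2, 0.4), 4, "1/1", wide = TRUE)
  expect_named(wide, c("criterion", "p", "p_c", "loading_0.2", "loading_0.4"))
})
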