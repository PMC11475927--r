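test_that("passing_bablok recovers exact linear relations", {
  # identity data; n = 4 is too small for CI ranks at alpha = 0.05
  fit <- suppressWarnings(passing_bablok(1:4, 1:4))
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_true(is.na(fit$proportional_bias))

  # exact y = 2x + 1: every pairwise slope is 2, zero-width slope set
  fit2 <- passing_bablok(1:5, 2 * (1:5) + 1)
  expect_equal(fit2$slope, 2)
  expect_equal(fit2$intercept, 1)
  expect_equal(fit2$ci_slope, c(2, 2))
  expect_true(fit2$proportional_bias)
  expect_true(fit2$constant_bias)
})

test_that("slope is the shifted median of all pairwise slopes", {
  x <- 1:5
  y <- c(2.1, 3.9, 6.2, 8.0, 9.9)
  fit <- passing_bablok(x, y)
  oracle <- oracle_pb_fit(x, y)
  expect_equal(fit$slope, oracle$slope)          # 1.9583...
  expect_equal(fit$intercept, oracle$intercept)  # 0.1417...
  expect_equal(round(fit$slope, 3), 1.958)
  expect_equal(round(fit$intercept, 3), 0.142)
  expect_equal(fit$n_slopes, 10)
  # estimate lies inside its own confidence interval
  expect_lte(fit$ci_slope[1], fit$slope)
  expect_gte(fit$ci_slope[2], fit$slope)
})

test_that("estimator equals the brute-force oracle on random small scatters", {
  set.seed(1234)
  for (rep in 1:100) {
    sc <- random_scatter(sample(3:8, 1))
    oracle <- oracle_pb_fit(sc$x, sc$y)
    if (!oracle$valid) {
      # negatively related scatter: the estimator is undefined
      expect_error(passing_bablok(sc$x, sc$y), "negatively related")
      next
    }
    fit <- suppressWarnings(passing_bablok(sc$x, sc$y))
    expect_equal(fit$slope, oracle$slope)
    expect_equal(fit$intercept, oracle$intercept)
    expect_equal(fit$n_slopes, oracle$n_slopes)
  }
})

test_that("fit is scale-equivariant and rejects degenerate input", {
  set.seed(5)
  x <- runif(12, 1, 4)
  y <- 0.4 + 1.2 * x + rnorm(12, 0, 0.2)
  fit <- passing_bablok(x, y)
  scaled <- passing_bablok(2.5 * x, 2.5 * y)
  expect_equal(scaled$slope, fit$slope)
  expect_equal(scaled$intercept, 2.5 * fit$intercept)

  expect_error(passing_bablok(1:2, 1:2), "at least 3")
  expect_error(passing_bablok(c(2, 2, 2), 1:3), "constant")
  expect_error(passing_bablok(1:3, 1:3, alpha = 1.2), "alpha")
})

test_that("relative discrepancy is bounded, symmetric, and scale-free", {
  s <- relative_discrepancy(c(2, 2, 2), c(2, 3, 4))
  expect_equal(s$d, c(0, 1 / 3, 1 / 2))
  expect_equal(s$median, 1 / 3)

  expect_equal(relative_discrepancy(2, 4)$d, 0.5)
  expect_equal(relative_discrepancy(2, 2)$d, 0)
  expect_equal(relative_discrepancy(0, 0)$d, 0)  # 0/0 pair defined as 0

  set.seed(8)
  x <- runif(20, 0, 5)
  y <- runif(20, 0, 5)
  fwd <- relative_discrepancy(x, y)
  expect_true(all(fwd$d >= 0 & fwd$d <= 1))
  expect_equal(relative_discrepancy(y, x)$d, fwd$d)      # symmetric
  expect_equal(relative_discrepancy(3 * x, 3 * y)$d, fwd$d)  # scale-free
  expect_error(relative_discrepancy(-1, 2), "non-negative")
})

test_that("quantitative_panel flags injected biases on noise-free cohorts", {
  # identical methods: slope 1, intercept 0, all d = 0
  sim0 <- biased_pair_cohort(a = 0, b = 1)
  panel0 <- quantitative_panel(sim0$dataset, "ref:test")
  expect_equal(panel0$slope, 1)
  expect_equal(panel0$intercept, 0)
  expect_equal(panel0$d_median, 0)
  expect_false(panel0$proportional_bias)
  expect_false(panel0$constant_bias)

  # constant offset +0.5, no noise
  simc <- biased_pair_cohort(a = 0.5, b = 1)
  panelc <- quantitative_panel(simc$dataset, "ref:test")
  expect_true(panelc$constant_bias)
  expect_false(panelc$proportional_bias)
  expect_equal(panelc$intercept, 0.5)

  # proportional factor 1.3, no noise
  simp <- biased_pair_cohort(a = 0, b = 1.3)
  panelp <- quantitative_panel(simp$dataset, "ref:test")
  expect_true(panelp$proportional_bias)
  expect_false(panelp$constant_bias)
  expect_equal(panelp$slope, 1.3)

  expect_error(quantitative_panel(sim0$dataset, "ref:nope"),
               "Unknown method")
})

test_that("bias flags converge to the truth as noise vanishes", {
  for (noise in c(0.2, 0.05, 0.01)) {
    sim <- biased_pair_cohort(a = 0.4, b = 1, noise = noise,
                              n_patients = 15, seed = 300 + noise * 100)
    panel <- quantitative_panel(sim$dataset, "ref:test")
    if (noise <= 0.05) {
      expect_true(panel$constant_bias)
      expect_false(panel$proportional_bias)
    }
    expect_lt(abs(panel$intercept - 0.4), 0.2)
  }
})
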