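test_that("landscape generator is deterministic and honors frozen dynamics", {
  lp <- landscape_params(nrows = 40, ncols = 40, seed = 5)
  s1 <- generate_landscape_series(lp, 3)
  s2 <- generate_landscape_series(lp, 3)
  for (d in 1:3) expect_identical(s1[[d]]$values, s2[[d]]$values)
  # zero conversion rates freeze the landscape
  lp0 <- landscape_params(nrows = 30, ncols = 30,
                          conversions = c("1->2" = 0), seed = 5)
  s0 <- generate_landscape_series(lp0, 4)
  for (d in 2:4) expect_identical(s0[[d]]$values, s0[[1]]$values)
})

test_that("marginal class areas match requested proportions within 2%", {
  lp <- landscape_params(nrows = 120, ncols = 120, seed = 3)
  lu <- generate_landscape_series(lp, 1)[[1]]
  n <- length(lu$values)
  for (code in names(lp$proportions)) {
    got <- sum(lu$values == as.numeric(code)) / n
    expect_lt(abs(got - lp$proportions[[code]]), 0.02)
  }
  # remainder is dry farmland (code 2)
  expect_lt(abs(sum(lu$values == 2) / n - (1 - sum(lp$proportions))), 0.02)
})

test_that("the stated layout emerges: forest east, built center, grass west", {
  lp <- landscape_params(nrows = 80, ncols = 90, seed = 2)
  lu <- generate_landscape_series(lp, 1)[[1]]$values
  third <- ncol(lu) %/% 3
  west <- lu[, seq_len(third)]
  center <- lu[, (third + 1):(2 * third)]
  east <- lu[, (2 * third + 1):ncol(lu)]
  expect_gt(mean(east == 3), 3 * mean(west == 3))       # woodland eastward
  expect_gt(mean(west == 7), 3 * mean(east == 7))       # grassland westward
  expect_gt(mean(center == 14), mean(west == 14))       # urban central
})

test_that("Bernoulli conversion reproduces its expected transition rate", {
  # all-grassland map, grassland -> dry farmland at 0.1 per step
  lp <- landscape_params(nrows = 100, ncols = 100,
                         proportions = c("7" = 1),
                         conversions = c("7->2" = 0.1), seed = 4)
  ser <- generate_landscape_series(lp, 2)
  leg <- default_parameter_tables()$legend
  tm <- transition_matrix(ser[[1]], ser[[2]], leg)
  rate <- tm$areas["7", "2"] / sum(tm$areas["7", ])
  # binomial tolerance: 4 sd of p(1-p)/n
  expect_lt(abs(rate - 0.1), 4 * sqrt(0.1 * 0.9 / 1e4))
})

test_that("sem table draws match the truth's implied covariance", {
  tr <- sem_truth(seed = 6)
  tab <- generate_sem_table(tr, n = 50000)
  S <- cov(tab)
  expect_lt(max(abs(S - tr$Sigma)), 0.02)
  # all variables unit variance under the truth
  expect_equal(unname(diag(tr$Sigma)), rep(1, 8), tolerance = 1e-12)
  # zero structural coefficients decouple the indicator blocks
  tr0 <- sem_truth(structural = data.frame(from = "NDVI", to = "HQ",
                                           coef = 0, stringsAsFactors = FALSE),
                   latent_cov = 0, seed = 6)
  tab0 <- generate_sem_table(tr0, n = 20000)
  S0 <- cov(tab0)
  expect_lt(abs(S0["elevation", "precipitation"]), 0.03)
  expect_lt(abs(S0["nightlight", "HQ"]), 0.03)
})

test_that("covariate stack is deterministic with built-in contrasts", {
  lp <- landscape_params(nrows = 50, ncols = 50, seed = 7)
  lu <- generate_landscape_series(lp, 1)[[1]]
  tr <- sem_truth()
  a <- generate_covariate_stack(lu, tr, seed = 9)
  b <- generate_covariate_stack(lu, tr, seed = 9)
  for (nm in names(a)) expect_identical(a[[nm]]$values, b[[nm]]$values)
  # NDVI contrast: all-forest vs all-urban landscape, same seed
  forest <- hq_grid(matrix(3, 40, 40))
  urban <- hq_grid(matrix(14, 40, 40))
  ndvi_f <- generate_covariate_stack(forest, tr, seed = 1)$ndvi
  ndvi_u <- generate_covariate_stack(urban, tr, seed = 1)$ndvi
  expect_gt(mean(ndvi_f$values), mean(ndvi_u$values))
})

test_that("infeasible proportions are rejected", {
  expect_error(landscape_params(proportions = c("3" = 0.8, "7" = 0.4)))
  lp <- landscape_params(nrows = 3, ncols = 3, proportions = c("3" = 0.99))
  expect_silent(generate_landscape_series(lp, 1))
})
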