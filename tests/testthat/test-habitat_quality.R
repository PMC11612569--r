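test_that("threat presence marks source cells and cross-checks class areas", {
  leg <- tiny_legend()
  lu <- hq_grid(matrix(c(9, 1, 1, 9), 2, 2))
  p <- threat_presence(lu, tiny_threat(), leg)
  expect_equal(p$values, matrix(c(1, 0, 0, 1), 2, 2))
  # all-habitat landscape: no sources
  p0 <- threat_presence(hq_grid(matrix(1, 3, 3)), tiny_threat(), leg)
  expect_true(all(p0$values == 0))
  # count of ones equals the class-area count
  set.seed(3)
  lu2 <- random_landuse(20, 20, p_na = 0.1)
  p2 <- threat_presence(lu2, tiny_threat(), leg)
  ap <- area_percentages(lu2, leg)
  n_valid <- sum(!is.na(lu2$values))
  expect_equal(sum(p2$values, na.rm = TRUE),
               ap$percent[ap$group == "urban"] / 100 * n_valid)
})

test_that("decay kernels hit their closed-form anchor points", {
  lin <- tiny_threat(d_rmax = 2, decay = "linear")
  expn <- tiny_threat(d_rmax = 2, decay = "exponential")
  expect_equal(decay_factor(0, lin), 1)
  expect_equal(decay_factor(0, expn), 1)
  expect_equal(decay_factor(2, lin), 0)
  expect_equal(decay_factor(2, expn), exp(-2.99))
  expect_equal(decay_factor(1, lin), 0.5)
  expect_equal(decay_factor(1, expn), exp(-2.99 / 2))
  # truncation strictly beyond d_rmax
  expect_equal(decay_factor(2.0001, expn), 0)
  expect_equal(decay_factor(5, lin), 0)
  expect_error(decay_factor(-0.1, lin), "non-negative")
})

test_that("single-source degradation matches the hand evaluation", {
  # 3x3, urban source at center, exponential, d_rmax = 2 cells, S = 0.5
  leg <- landuse_legend(
    data.frame(code = c(1, 9), name = c("hab", "urb"), H = c(0.8, 0.8)),
    matrix(c(0.5, 0.5), 2, 1, dimnames = list(NULL, "urban")))
  lu <- hq_grid(matrix(c(1, 1, 1, 1, 9, 1, 1, 1, 1), 3, 3), cell_size = 1)
  D <- degradation(lu, list(tiny_threat(d_rmax = 2)), leg)
  expect_equal(D$values[2, 2], 0.5)                         # self, d = 0
  expect_equal(D$values[2, 1], exp(-2.99 / 2) * 0.5)        # edge-adjacent
  expect_equal(D$values[1, 1], exp(-2.99 * sqrt(2) / 2) * 0.5)  # corner
})

test_that("degradation is invariant to rescaling all threat weights", {
  set.seed(11)
  leg <- tiny_legend(S1 = 0.6, S9 = 0.2)
  lu <- random_landuse(15, 15)
  t1 <- list(tiny_threat(weight = 0.9),
             threat_spec("urban2", 9, 3, 0.3, "linear"))
  t2 <- lapply(t1, function(tr) { tr$weight <- tr$weight * 7.3; tr })
  leg2 <- landuse_legend(leg$classes,
                         cbind(leg$sensitivity,
                               urban2 = leg$sensitivity[, "urban"]))
  expect_equal(degradation(lu, t1, leg2)$values,
               degradation(lu, t2, leg2)$values, tolerance = 1e-14)
})

test_that("kernel degradation equals the brute-force quadruple loop", {
  set.seed(5)
  p <- default_parameter_tables()
  for (rep in 1:2) {
    lp <- landscape_params(nrows = 15, ncols = 18, cell_size = 1, seed = rep)
    lu <- generate_landscape_series(lp, 1)[[1]]
    lu$values[sample(length(lu$values), 10)] <- NA
    D <- degradation(lu, p$threats, p$legend)
    ref <- brute_degradation(lu, p$threats, p$legend)
    expect_lt(max(abs(D$values - ref), na.rm = TRUE), 1e-12)
  }
})

test_that("zero sensitivity or zero sources give D = 0 and Q = H", {
  set.seed(2)
  leg0 <- tiny_legend(S1 = 0, S9 = 0)
  lu <- random_landuse(10, 10)
  D <- degradation(lu, list(tiny_threat()), leg0)
  expect_true(all(D$values == 0))
  Q <- quality(lu, D, leg0)
  expect_equal(Q$values, matrix(suitability(leg0, lu$values), 10, 10))
  # landscape with no source cells at all
  lu1 <- hq_grid(matrix(1, 8, 8))
  D1 <- degradation(lu1, list(tiny_threat()), tiny_legend())
  expect_true(all(D1$values == 0))
})

test_that("quality obeys its closed forms and monotonicity in D", {
  leg <- tiny_legend()
  cfg <- hq_config(z = 2.5, k = 0.5)
  lu <- hq_grid(matrix(1, 1, 3))
  # D = 0 -> Q = H; D = k -> Q = H/2
  D <- hq_grid(matrix(c(0, 0.5, 2), 1, 3))
  Q <- quality(lu, D, leg, cfg)
  expect_equal(Q$values[1, 1], 0.8)
  expect_equal(Q$values[1, 2], 0.4)
  # H = 0 absorbs any D
  lu9 <- hq_grid(matrix(9, 1, 3))
  leg9 <- landuse_legend(data.frame(code = 9, name = "urb", H = 0),
                         matrix(0.3, 1, 1, dimnames = list(NULL, "urban")))
  expect_true(all(quality(lu9, D, leg9, cfg)$values == 0))
  # monotone non-increasing in D (property over random pairs)
  set.seed(4)
  for (i in 1:50) {
    d <- sort(runif(2, 0, 5))
    q <- quality(hq_grid(matrix(1, 1, 2)),
                 hq_grid(matrix(d, 1, 2)), leg, cfg)$values
    expect_gte(q[1, 1], q[1, 2])
  }
})

test_that("k = \"half_max\" halves quality at half the max degradation", {
  leg <- tiny_legend()
  lu <- hq_grid(matrix(1, 1, 3))
  D <- hq_grid(matrix(c(0, 1, 2), 1, 3))
  Q <- quality(lu, D, leg, hq_config(k = "half_max"))
  expect_equal(Q$values[1, 2], 0.4)  # D = max(D)/2 -> H/2
})

test_that("shrinking d_rmax never increases degradation anywhere", {
  set.seed(9)
  leg <- tiny_legend(S1 = 0.7, S9 = 0.4)
  lu <- random_landuse(12, 12)
  for (decay in c("linear", "exponential")) {
    D_big <- degradation(lu, list(tiny_threat(d_rmax = 4, decay = decay)), leg)
    D_small <- degradation(lu, list(tiny_threat(d_rmax = 2, decay = decay)), leg)
    expect_true(all(D_small$values <= D_big$values + 1e-12))
  }
})

test_that("grade classification uses left-closed 0.2-wide bins", {
  q <- hq_grid(matrix(c(0.534, 0.2, 0.9, 0, 1, 0.7999), 2, 3))
  cl <- classify_quality(q)
  expect_equal(cl$grid$values[1, 1], 3)  # 0.534 -> medium
  expect_equal(cl$grid$values[2, 1], 2)  # 0.2 -> lower (left-closed)
  expect_equal(cl$grid$values[1, 2], 5)  # 0.9 -> highest
  expect_equal(cl$grid$values[2, 2], 1)  # 0 -> lowest
  expect_equal(cl$grid$values[1, 3], 5)  # 1.0 included in highest
  expect_equal(cl$grid$values[2, 3], 4)  # just under 0.8 -> higher
  expect_equal(sum(cl$table$percent), 100, tolerance = 1e-9)
  uni <- classify_quality(hq_grid(matrix(0.9, 3, 3)))
  expect_equal(uni$table$percent[uni$table$grade == "highest"], 100)
  expect_error(classify_quality(hq_grid(matrix(c(0.5, 1.2), 1, 2))),
               "outside")
})

test_that("change maps split improved/unchanged/degraded correctly", {
  a <- hq_grid(matrix(0.4, 4, 4))
  same <- change_map(a, a)
  expect_equal(same$table$percent[same$table$trend == "unchanged"], 100)
  up <- change_map(a, hq_grid(matrix(0.6, 4, 4)), eps = 0.01)
  expect_equal(up$table$percent[up$table$trend == "improved"], 100)
  # half +0.1, half -0.1
  b <- a; b$values[, 1:2] <- 0.5; b$values[, 3:4] <- 0.3
  half <- change_map(a, b, eps = 0.01)
  expect_equal(half$table$percent,
               c(50, 0, 50)[match(half$table$trend,
                                  c("improved", "unchanged", "degraded"))])
  expect_equal(sum(half$table$percent), 100, tolerance = 1e-9)
})
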