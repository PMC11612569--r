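test_that("Moran's I is exactly -1 on a checkerboard (rook, row-standardized)", {
  g <- hq_grid(checkerboard(6, 6))
  m <- morans_i(g, spatial_weights("rook", row_standardized = TRUE))
  expect_equal(m$I, -1, tolerance = 1e-12)
  expect_equal(m$expectation, -1 / (36 - 1))
  expect_lt(m$z, -2)
})

test_that("clustered half-planes give positive I; expectation is -1/(n-1)", {
  v <- matrix(0, 8, 8); v[, 5:8] <- 10
  m <- morans_i(hq_grid(v))
  expect_gt(m$I, 0)
  set.seed(10)
  g <- hq_grid(matrix(rnorm(35), 5, 7))
  g$values[c(2, 9)] <- NA
  m2 <- morans_i(g)
  expect_equal(m2$expectation, -1 / (m2$n - 1))
  expect_equal(m2$n, 33)
})

test_that("Moran's I agrees with the brute-force pair sum", {
  set.seed(21)
  for (rep in 1:3) {
    v <- matrix(rnorm(20 * 25), 20, 25)
    if (rep > 1) v[runif(length(v)) < 0.1] <- NA
    for (scheme in c("rook", "queen")) for (rs in c(TRUE, FALSE)) {
      got <- morans_i(hq_grid(v), spatial_weights(scheme, row_standardized = rs))
      expect_equal(got$I, brute_moran(v, scheme, rs), tolerance = 1e-12)
    }
  }
})

test_that("Moran's I and its randomization z match ape::Moran.I", {
  skip_if_not_installed("ape")
  set.seed(31)
  v <- matrix(rnorm(12 * 12), 12, 12)
  g <- hq_grid(v)
  # ape row-standardizes its weight matrix internally, so compare that case
  got <- morans_i(g, spatial_weights("queen", row_standardized = TRUE))
  ed <- habiquant:::lattice_edges(!is.na(v), "queen")
  W <- matrix(0, ed$n, ed$n)
  W[cbind(ed$i, ed$j)] <- 1
  ref <- ape::Moran.I(as.vector(v), W, scaled = FALSE)
  expect_equal(got$I, ref$observed, tolerance = 1e-10)
  expect_equal(got$expectation, ref$expected, tolerance = 1e-12)
  expect_equal(sqrt(got$variance), ref$sd, tolerance = 1e-8)
})

test_that("constant surfaces are rejected", {
  g <- hq_grid(matrix(5, 4, 4))
  expect_error(morans_i(g), "zero variance")
  expect_error(gi_star(g), "zero variance")
})

test_that("a planted high block is a 99% hotspot; background is not", {
  v <- matrix(0, 15, 15)
  v[7:9, 7:9] <- 10
  hs <- gi_star(hq_grid(v))
  expect_equal(hs$class_grid$values[8, 8], 3)   # block center: hotspot99
  expect_equal(hs$class_grid$values[1, 1], 0)   # far corner: not significant
  expect_equal(hs$class_grid$values[15, 15], 0)
  expect_equal(sum(hs$table$percent), 100, tolerance = 1e-9)
  # z-scores equal the brute-force Gi* formula
  ref <- brute_gi_z(v)
  expect_lt(max(abs(hs$z_grid$values - ref)), 1e-10)
})

test_that("negating the surface swaps hot and cold spots symmetrically", {
  set.seed(13)
  v <- matrix(rnorm(18 * 18), 18, 18)
  v[2:4, 2:4] <- v[2:4, 2:4] + 4
  v[12:14, 12:14] <- v[12:14, 12:14] - 4
  a <- gi_star(hq_grid(v))
  b <- gi_star(hq_grid(-v))
  expect_equal(a$class_grid$values, -b$class_grid$values)
  expect_equal(a$z_grid$values, -b$z_grid$values, tolerance = 1e-10)
  expect_equal(a$table$percent, rev(b$table$percent))
})

test_that("Moran's I is invariant to positive affine transforms", {
  set.seed(17)
  v <- matrix(rnorm(100), 10, 10)
  m1 <- morans_i(hq_grid(v))
  m2 <- morans_i(hq_grid(3.7 * v + 12))
  expect_equal(m1$I, m2$I, tolerance = 1e-12)
  expect_equal(m1$z, m2$z, tolerance = 1e-10)
})

test_that("nodata cells are removed from the weights graph", {
  v <- matrix(c(1, NA, 2, NA, 5, NA, 3, NA, 4), 3, 3)
  # only corners + center valid; rook: no valid pairs -> error
  expect_error(morans_i(hq_grid(v), spatial_weights("rook")),
               "no neighbor pairs")
  m <- morans_i(hq_grid(v), spatial_weights("queen"))
  expect_equal(m$n, 5)
})
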