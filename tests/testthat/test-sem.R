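test_that("rank-normalization standardizes, preserves order, fixes skew", {
  set.seed(8)
  x <- exp(rnorm(1000, 0, 1.5))           # heavily right-skewed
  z <- rank_normalize(x)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  expect_equal(order(x), order(z))        # monotone
  expect_gt(abs(sample_skewness(x)), 2)
  expect_lt(abs(sample_skewness(z)), 0.1)
  # NA positions preserved; degenerate inputs rejected
  x2 <- c(1, NA, 3, 2)
  expect_true(is.na(rank_normalize(x2)[2]))
  expect_error(rank_normalize(c(1, 2)), "at least 3")
  expect_error(rank_normalize(rep(4, 10)), "tied")
})

test_that("implied covariance composes measurement and structure", {
  m <- path_model(c("L =~ a + b"))
  pt <- habiquant:::param_table(m)
  # loadings (1, 0.5), latent variance 2, residuals 1 -> cov(a,b) = 0.5*2
  pt$value[pt$type == "loading" & pt$to == "b"] <- 0.5
  pt$value[pt$type == "var" & pt$to == "L"] <- 2
  pt$value[pt$type == "var" & pt$to %in% c("a", "b")] <- 1
  Sig <- implied_covariance(m, pt)
  expect_equal(Sig["a", "b"], 1)
  expect_equal(Sig["a", "a"], 3)    # 1^2 * 2 + 1
  expect_equal(Sig["b", "b"], 1.5)  # 0.5^2 * 2 + 1
  expect_equal(Sig, t(Sig), tolerance = 1e-12)
  # zero loadings and paths -> diagonal of residual variances
  pt0 <- pt
  pt0$value[pt0$type == "loading"] <- 0
  Sig0 <- implied_covariance(m, pt0)
  expect_equal(Sig0, diag(c(a = 1, b = 1)) , tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a saturated model fits perfectly", {
  set.seed(12)
  n <- 500
  x1 <- rnorm(n); x2 <- 0.5 * x1 + rnorm(n); x3 <- 0.3 * x1 - 0.4 * x2 + rnorm(n)
  S <- cov(data.frame(x1 = x1, x2 = x2, x3 = x3))
  m <- path_model(c("x2 ~ x1", "x3 ~ x1 + x2"))
  fit <- fit_ml(S, n, m)
  expect_equal(fit$fit$df, 0)
  expect_lt(fit$fit$chisq, 1e-6)
  expect_equal(fit$fit$CFI, 1)
  expect_lt(fit$fit$SRMR, 1e-6)
  # regression estimates equal OLS on a saturated recursive model
  ols <- unname(coef(lm(x3 ~ x1 + x2))[-1])
  est <- fit$params
  expect_equal(est$value[est$type == "reg" & est$from == "x1" & est$to == "x3"],
               ols[1], tolerance = 1e-4)
})

test_that("model syntax is validated", {
  expect_error(path_model("L =~ a"), "fewer than 2")
  expect_error(path_model(c("L =~ a + b", "M =~ a + c")), "more than one")
  expect_error(path_model(c("a ~ b", "b ~ a")), "cycle")
  m <- path_model(hq_driver_model())
  expect_setequal(m$latents, c("Topography", "Climate", "HumanDisturbance"))
  expect_equal(length(m$observed), 8)
})

test_that("effect decomposition enumerates paths and matches the matrix series", {
  # single-edge graph: direct = total, no indirect terms
  e1 <- data.frame(from = "x", to = "y", coef = 0.7)
  d1 <- effect_decomposition(e1, "x", "y")
  expect_equal(d1$direct, 0.7)
  expect_equal(nrow(d1$indirect), 0)
  expect_equal(d1$total, 0.7)
  # random acyclic graphs: path enumeration vs (I-B)^-1 - I
  set.seed(19)
  vars <- c("A", "B", "C", "D", "E")
  for (rep in 1:10) {
    edges <- expand.grid(from = vars, to = vars, stringsAsFactors = FALSE)
    edges <- edges[match(edges$from, vars) < match(edges$to, vars), ]
    edges <- edges[runif(nrow(edges)) < 0.6, ]
    if (!nrow(edges)) next
    edges$coef <- round(rnorm(nrow(edges), 0, 0.4), 3)
    tot <- total_effects_matrix(edges)
    for (dr in vars[vars %in% edges$from]) {
      if (!"E" %in% edges$to) next
      dec <- effect_decomposition(edges, dr, "E")
      ref <- if ("E" %in% rownames(tot) && dr %in% colnames(tot))
        tot["E", dr] else 0
      expect_equal(dec$total, ref, tolerance = 1e-12)
      expect_equal(dec$total, dec$direct + sum(dec$indirect$contribution))
    }
  }
  expect_error(effect_decomposition(
    data.frame(from = c("a", "b"), to = c("b", "a"), coef = c(1, 1)),
    "a", "b"), "cycle")
})

test_that("ML fit recovers a known generating model at n = 5000", {
  tr <- sem_truth(seed = 2)
  tab <- generate_sem_table(tr, n = 5000)
  fit <- fit_ml(cov(tab), 5000, tr$model, seed = 1)
  expect_true(fit$converged)
  est <- fit$params
  regs <- merge(est[est$type == "reg", c("from", "to", "std")],
                tr$structural, by = c("from", "to"))
  expect_equal(nrow(regs), nrow(tr$structural))
  expect_lt(max(abs(regs$std - regs$coef)), 0.05)
  lds <- est[est$type == "loading", ]
  for (k in seq_len(nrow(lds)))
    expect_equal(lds$std[k], unname(tr$loadings[lds$to[k]]), tolerance = 0.05)
  # discrepancy at the optimum no worse than at the start (optimizer sanity)
  expect_lt(fit$discrepancy, 0.05)
})

test_that("fit errors on bad inputs", {
  m <- path_model(c("x2 ~ x1"))
  S <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = list(c("x1", "x2"), c("x1", "x2")))
  expect_error(fit_ml(S, 2, m), "sample size")
  S2 <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = dimnames(S))
  expect_error(fit_ml(S2, 100, m), "positive-definite")
  expect_error(fit_ml(S[1, 1, drop = FALSE], 100, m), "lacks variable")
})
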