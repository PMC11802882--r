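test_that("pooled t-test matches the textbook formula and base R", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- independent_t(a, b)
  # pooled variance 1, se = sqrt(2/3)
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$d, res$t * sqrt(1 / 3 + 1 / 3), tolerance = 1e-12)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  expect_equal(independent_t(c(1, 2), c(1, 2))$t, 0)
  expect_equal(independent_t(c(1, 2), c(1, 2))$p, 1)
  expect_error(independent_t(c(1, 1), c(1, 1)), "pooled variance")
})

test_that("one-tailed p honors the pre-registered direction", {
  set.seed(10)
  a <- rnorm(30, 0.5); b <- rnorm(30)
  two <- independent_t(a, b, sided = "two")
  one <- independent_t(a, b, sided = "one", direction = "greater")
  expect_equal(one$p, two$p / 2, tolerance = 1e-12)
  expect_lte(one$p, 0.5)
  wrong <- independent_t(a, b, sided = "one", direction = "less")
  expect_equal(wrong$p, 1 - one$p, tolerance = 1e-12)
})

test_that("one-tailed t-test is calibrated under the null", {
  set.seed(2024)
  rej <- 0L
  for (i in 1:2000) {
    p <- independent_t(rnorm(50), rnorm(50), sided = "one",
                       direction = "greater")$p
    if (p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / 2000, 0.04)
  expect_lte(rej / 2000, 0.06)
})

test_that("Pearson correlation matches cor.test and recovers planted rho", {
  x <- rnorm(20)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  y <- x + rnorm(20)
  ref <- cor.test(x, y)
  got <- pearson_r(x, y)
  expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_equal(got$df, 18)
  expect_error(pearson_r(x, rep(1, 20)), "constant")
  set.seed(11)
  n <- 10000
  u <- rnorm(n); v <- 0.3 * u + sqrt(1 - 0.09) * rnorm(n)
  expect_lt(abs(pearson_r(u, v)$r - 0.3), 0.03)
})

test_that("covariate-adjusted group F matches the unadjusted test when orthogonal", {
  set.seed(12)
  n <- 200
  g <- rep(c("x", "y"), each = n / 2)
  out <- rnorm(n) + 0.8 * (g == "x")
  d <- data.frame(out = out, g = g, cov = rnorm(n))
  adj <- ancova_group_effect(d, "out", "g", "cov")
  un <- ancova_group_effect(d, "out", "g")
  expect_equal(adj$F, un$F, tolerance = 0.15)
  expect_lt(adj$p, 0.001)
  # outcome driven entirely by a group-correlated covariate: the
  # adjusted group F collapses while the unadjusted one is large
  cov2 <- rnorm(n, mean = ifelse(g == "x", 1, 0))
  d2 <- data.frame(out = cov2 + rnorm(n, 0, 0.1), g = g, cov = cov2)
  f_un <- ancova_group_effect(d2, "out", "g")$F
  f_adj <- ancova_group_effect(d2, "out", "g", "cov")$F
  expect_gt(f_un, 30)
  expect_lt(f_adj, 10)
  # known partial effect stays detectable after adjustment
  z <- rnorm(n)
  d3 <- data.frame(out = 0.6 * (g == "x") + 0.5 * z + rnorm(n),
                   g = g, z = z)
  expect_lt(ancova_group_effect(d3, "out", "g", "z")$p, 0.01)
  # rank deficiency is an error naming the aliased term
  d4 <- data.frame(out = out, g = g, dup = as.integer(g == "x"))
  expect_error(ancova_group_effect(d4, "out", "g", "dup"), "aliased")
})

test_that("simultaneous regression recovers known slopes and rejects collinearity", {
  set.seed(13)
  n <- 10000
  x1 <- rnorm(n); x2 <- rnorm(n)
  d <- data.frame(y = 1 + 0.4 * x1 - 0.7 * x2 + rnorm(n),
                  x1 = x1, x2 = x2)
  cf <- simultaneous_regression(d, "y", c("x1", "x2"))
  expect_equal(cf$estimate[cf$term == "x1"], 0.4, tolerance = 0.05)
  expect_equal(cf$estimate[cf$term == "x2"], -0.7, tolerance = 0.05)
  d$x3 <- d$x1
  expect_error(simultaneous_regression(d, "y", c("x1", "x3")),
               "collinear")
  # orthogonal predictors: coefficients equal simple-regression slopes
  simple1 <- coef(lm(y ~ x1, d))[2]
  expect_equal(cf$estimate[cf$term == "x1"], unname(simple1),
               tolerance = 0.02)
})
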