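test_that("exact MWU matches hand enumeration on separated samples", {
  res <- mwu_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)  # 2 * 1/20
  expect_equal(res$statistic, 0)
  expect_equal(res$method, "exact")
})

test_that("fully tied samples give p = 1", {
  res <- mwu_exact(c(5, 5, 5), c(5, 5, 5))
  expect_equal(res$p_value, 1)
  expect_true(res$ties)
})

test_that("exact MWU equals full enumeration for all n, m <= 7 with ties", {
  withr::with_seed(13, {
    for (n in 1:7) for (m in 1:7) {
      x <- sample(1:5, n, replace = TRUE)        # heavy ties
      y <- sample(1:5, m, replace = TRUE)
      expect_equal(mwu_exact(x, y)$p_value, mwu_brute_force(x, y),
                   tolerance = 1e-12)
      x2 <- rnorm(n); y2 <- rnorm(m)             # continuous, no ties
      expect_equal(mwu_exact(x2, y2)$p_value, mwu_brute_force(x2, y2),
                   tolerance = 1e-12)
    }
  })
})

test_that("exact MWU agrees with wilcox.test on untied data", {
  withr::with_seed(29, {
    for (i in 1:10) {
      x <- rnorm(6); y <- rnorm(6)
      expect_equal(mwu_exact(x, y)$p_value,
                   stats::wilcox.test(x, y, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  })
})

test_that("exact MWU p-values are symmetric and rank-invariant", {
  withr::with_seed(41, {
    for (i in 1:10) {
      x <- sample(1:8, 6, replace = TRUE); y <- sample(1:8, 6, replace = TRUE)
      expect_equal(mwu_exact(x, y)$p_value, mwu_exact(y, x)$p_value)
      # strictly monotone transform of the pooled data preserves ranks
      g <- function(v) exp(v) + 3 * v
      expect_equal(mwu_exact(x, y)$p_value, mwu_exact(g(x), g(y))$p_value)
    }
  })
})

test_that("MWU input validation and method selection work", {
  expect_error(mwu_exact(numeric(0), 1:3), class = "mwacool_data_error")
  expect_error(mwu_exact(c(1, NA), 1:3), class = "mwacool_data_error")
  big <- mwu_exact(rnorm(30), rnorm(30))
  expect_equal(big$method, "normal")
  small <- mwu_exact(rnorm(3), rnorm(3))
  expect_equal(small$method, "exact")
  # normal approximation is close to exact at moderate sizes
  withr::with_seed(55, {
    x <- rnorm(15); y <- rnorm(15, 0.5)
    pe <- mwu_exact(x, y, method = "exact")$p_value
    pn <- mwu_exact(x, y, method = "normal")$p_value
    expect_equal(pe, pn, tolerance = 0.05)
  })
})

test_that("Kruskal-Wallis reproduces the hand-computed H and edge cases", {
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  # H = 12/(N(N+1)) * sum(R_i^2/n_i) - 3(N+1), rank sums 3, 7, 11
  expect_equal(kw$statistic, 12 / 42 * (9 / 2 + 49 / 2 + 121 / 2) - 21,
               tolerance = 1e-12)
  expect_equal(kw$statistic, 4.571, tolerance = 1e-3)
  const <- kruskal_wallis(list(rep(2, 4), rep(2, 4), rep(2, 4)))
  expect_equal(const$statistic, 0)
  expect_equal(const$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), class = "mwacool_data_error")
  expect_error(kruskal_wallis(list(1:3, numeric(0))),
               class = "mwacool_data_error")
})

test_that("two-group Kruskal-Wallis matches the squared MWU normal deviate", {
  withr::with_seed(77, {
    x <- rnorm(20); y <- rnorm(20, 0.8)
    kw <- kruskal_wallis(list(x, y))
    # z without continuity correction; H = z^2 for two untied groups
    n <- 20; m <- 20; N <- 40
    u <- sum(rank(c(x, y))[1:20]) - n * (n + 1) / 2
    z <- (u - n * m / 2) / sqrt(n * m * (N + 1) / 12)
    expect_equal(kw$p_value, stats::pchisq(z^2, 1, lower.tail = FALSE),
                 tolerance = 1e-3)
  })
})

test_that("verdict bands honour the Bonferroni-adjusted levels exactly", {
  expect_equal(bonferroni_verdict(0.002), "significant")
  expect_equal(bonferroni_verdict(0.008), "significant")  # at the level
  expect_equal(bonferroni_verdict(0.03), "trend")
  expect_equal(bonferroni_verdict(0.05), "trend")         # at the band edge
  expect_equal(bonferroni_verdict(0.0500001), "not_significant")
  expect_equal(bonferroni_verdict(0.5), "not_significant")
  expect_equal(bonferroni_verdict(0.01, n_comparisons = 1), "significant")
  expect_error(bonferroni_verdict(1.5), class = "mwacool_data_error")
})

test_that("LOESS reproduces linear and constant signals and smooths noise", {
  x <- seq(0, 10, length.out = 50)
  lin <- loess_fit(x, 2 * x + 1, span = 0.4, degree = 1)
  expect_equal(lin$fitted$y, 2 * lin$fitted$x + 1, tolerance = 1e-9)
  const <- loess_fit(x, rep(3, 50), span = 1, degree = 2)
  expect_equal(const$fitted$y, rep(3, 100), tolerance = 1e-9)
  withr::with_seed(8, {
    xs <- sort(runif(200, 0, 2 * pi))
    noise <- rnorm(200, 0, 0.3)
    fit <- loess_fit(xs, sin(xs) + noise, span = 0.3,
                     x_grid = xs)
    rmse <- sqrt(mean((fit$fitted$y - sin(xs))^2))
    expect_lt(rmse, 0.3)
  })
  expect_error(loess_fit(1:2, 1:2), class = "mwacool_data_error")
  expect_error(loess_fit(1:10, 1:10, span = 0), class = "mwacool_parameter_error")
  expect_error(loess_fit(1:10, 1:10, degree = 3), class = "mwacool_parameter_error")
})

test_that("tidy and glance methods return one-row summaries", {
  mt <- mwu_exact(c(1, 2, 3), c(4, 5, 6))
  td <- tidy(mt)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$p.value, 0.1)
  expect_equal(td$verdict, "not_significant")
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(tidy(kw)$statistic, kw$statistic)
  lf <- loess_fit(1:20, rnorm(20))
  expect_equal(nrow(tidy(lf)), 100)
  expect_equal(glance(lf)$span, 0.5)
})
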