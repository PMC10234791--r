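test_that("winsorisation clips only beyond k SDs of the original moments", {
  set.seed(1)
  x <- rnorm(20)
  x <- (x - mean(x)) / sd(x)  # all |z| < 3 after studentizing 20 draws
  expect_identical(winsorize(x), x)
  expect_identical(winsorize(rep(2, 10)), rep(2, 10))  # SD = 0 rule

  y <- c(x, 10 * sd(x) + mean(x) * 0)
  y_w <- winsorize(y, k = 3)
  expect_equal(y_w[21], mean(y) + 3 * sd(y))  # original-moment threshold
  expect_identical(y_w[1:20], y[1:20])
})

test_that("winsorisation passes NA through and preserves unclipped ranks", {
  set.seed(2)
  x <- c(rnorm(30), NA, 8, -9)
  w <- winsorize(x, k = 2)
  expect_identical(is.na(w), is.na(x))
  unclipped <- which(!is.na(x) & x == w)
  expect_identical(rank(x[unclipped]), rank(w[unclipped]))
  m <- mean(x, na.rm = TRUE); s <- sd(x, na.rm = TRUE)
  expect_true(all(w >= m - 2 * s - 1e-12 & w <= m + 2 * s + 1e-12,
                  na.rm = TRUE))
  # a value never moves by more than (|z| - k) SDs
  moved <- abs(x - w)
  z <- abs(x - m) / s
  expect_true(all(moved <= pmax(0, z - 2) * s + 1e-12, na.rm = TRUE))
})

test_that("pearson matches the textbook formula and handles edge cases", {
  x <- c(2, 4, 5, 7, 9, 10, 12, 13, 15, 18)
  y <- c(1, 3, 2, 6, 8, 7, 11, 14, 13, 16)
  res <- pearson(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_equal(res$df, 8)
  t_stat <- r_oracle * sqrt(8 / (1 - r_oracle^2))
  expect_equal(res$p, 2 * pt(-abs(t_stat), 8), tolerance = 1e-12)

  expect_equal(pearson(x, x)$r, 1)
  x0 <- c(-1, 1, -1, 1)
  y0 <- c(-1, -1, 1, 1)  # orthogonal, centered
  expect_equal(pearson(x0, y0)$r, 0)
  expect_error(pearson(x, rep(1, 10)), class = "facecue_degenerate_error")
  # pairwise-complete cases only
  xm <- c(x, NA); ym <- c(y, 5)
  expect_equal(pearson(xm, ym)$n, 10)
})

test_that("single-predictor standardized beta equals pearson r", {
  set.seed(7)
  d <- tibble::tibble(x = rnorm(40), y = rnorm(40) + 0.5 * x)
  fit <- standardized_ols(d, "y", "x")
  expect_equal(tidy(fit)$beta, pearson(d$x, d$y)$r, tolerance = 1e-10)
  expect_lte(abs(tidy(fit)$beta), 1 + 1e-9)
  expect_equal(tidy(fit)$df, 38)
  expect_equal(sign(tidy(fit)$beta), sign(tidy(fit)$t))
})

test_that("standardized OLS matches the normal-equations oracle", {
  # fixed 12-case fixture
  d <- tibble::tibble(
    x1 = c(1.2, -0.4, 2.1, 0.3, -1.5, 0.8, 1.9, -0.2, 0.5, -1.1, 2.4, 0.1),
    x2 = c(0.5, 1.7, -0.8, 0.9, 0.2, -1.3, 0.4, 2.2, -0.6, 1.0, 0.7, -0.9),
    y = c(3.1, 0.4, 5.2, 1.8, -2.5, 1.2, 4.4, 0.9, 1.1, -1.8, 6.0, 0.3)
  )
  fit <- standardized_ols(d, "y", c("x1", "x2"))
  z <- as.data.frame(lapply(d, function(v) (v - mean(v)) / sd(v)))
  xm <- cbind(1, as.matrix(z[c("x1", "x2")]))
  beta_oracle <- solve(crossprod(xm), crossprod(xm, z$y))
  resid <- z$y - xm %*% beta_oracle
  sigma2 <- sum(resid^2) / (12 - 3)
  se_oracle <- sqrt(diag(solve(crossprod(xm))) * sigma2)
  expect_equal(tidy(fit)$beta, beta_oracle[2:3], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(tidy(fit)$t, beta_oracle[2:3] / se_oracle[2:3],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(tidy(fit)$df, rep(9L, 2))
})

test_that("exact and degenerate designs behave as specified", {
  x1 <- c(-1.5, -0.5, 0.5, 1.5, -1, 1, 0, 2)
  x2 <- c(1, -1, 1, -1, 1, -1, 1, -1)  # orthogonal to x1 by construction
  x2 <- x2 - sum(x2 * x1) / sum(x1^2) * x1
  d <- tibble::tibble(x1 = x1, x2 = x2, y = x1)
  # y is exactly x1, so summary.lm warns about the perfect fit
  fit <- suppressWarnings(standardized_ols(d, "y", c("x1", "x2")))
  expect_equal(tidy(fit)$beta, c(1, 0), tolerance = 1e-10)

  d$x3 <- d$x1 * 2
  expect_error(standardized_ols(d, "y", c("x1", "x3")),
               class = "facecue_degenerate_error")
  d$y0 <- 1
  expect_error(standardized_ols(d, "y0", "x1"),
               class = "facecue_degenerate_error")
})

test_that("JZS Bayes factors match the fine-grid quadrature oracle", {
  cases <- list(list(n = 30, p = 1, r2 = 0.05), list(n = 100, p = 1, r2 = 0.25),
                list(n = 259, p = 2, r2 = 0.01), list(n = 156, p = 2, r2 = 0.2),
                list(n = 50, p = 3, r2 = 0.4))
  for (cs in cases) {
    got <- jzs_bf_r2(cs$n, cs$p, cs$r2)
    want <- jzs_grid_oracle(cs$n, cs$p, cs$r2)
    expect_lt(abs(got - want) / want, 1e-3)
  }
})

test_that("effect-level Bayes factors point the right way", {
  set.seed(11)
  n <- 259
  d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- 0.3 * d$x2 + rnorm(n)  # x1 is null
  expect_lt(jzs_bf(d, "y", c("x1", "x2"), focal = "x1"), 1)
  expect_gt(jzs_bf(d, "y", c("x1", "x2"), focal = "x2"), 100)

  # strong fixed effect: bf10 large and monotone in n on nested samples
  set.seed(12)
  x <- rnorm(100)
  y <- 0.5 * x + rnorm(100) * sqrt(1 - 0.25)
  dd <- tibble::tibble(x = x, y = y)
  bfs <- vapply(c(40, 70, 100), function(m) {
    jzs_bf(dd[seq_len(m), ], "y", "x", focal = "x")
  }, 1)
  expect_gt(bfs[3], 100)
  expect_true(all(diff(bfs) > 0))
})

test_that("bf10 decreases strictly with p for a fixed model and n", {
  set.seed(13)
  n <- 80
  stats <- purrr::map_dfr(1:40, function(i) {
    d <- tibble::tibble(x = rnorm(n), y = rnorm(n))
    fit <- tidy(standardized_ols(d, "y", "x"))
    tibble::tibble(p = fit$p, bf = jzs_bf(d, "y", "x", focal = "x"))
  })
  expect_equal(cor(stats$p, stats$bf, method = "spearman"), -1)
})

test_that("power-analysis sample size matches its targets and an exhaustive scan", {
  expect_equal(required_n(f2 = 0.027, power = 0.80, alpha = 0.05, df1 = 1),
               293)
  expect_lt(required_n(f2 = 0.15), required_n(f2 = 0.027))

  # exhaustive-scan oracle over N = 10..200 for a medium effect
  k <- 2
  pw <- vapply(10:200, function(n) {
    df2 <- n - k - 1
    pf(qf(0.95, 1, df2), 1, df2, ncp = 0.15 * n, lower.tail = FALSE)
  }, 1)
  oracle_n <- (10:200)[which(pw >= 0.8)[1]]
  expect_equal(required_n(f2 = 0.15, power = 0.8, alpha = 0.05, df1 = 1,
                          n_predictors = 2), oracle_n)
  expect_error(required_n(f2 = 1e-9, n_max = 5000),
               class = "facecue_power_error")
})
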