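test_that("simple regression recovers exact and noisy linear relationships", {
  x <- 1:10
  y <- 2 * x + 1
  fit <- suppressWarnings(fit_simple_regression(x, y))  # noise-free fit
  expect_equal(unname(fit$slopes[1]), 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-10)

  set.seed(77)
  x <- runif(200)
  y <- 30 + 50 * x + rnorm(200, 0, 10)
  fit <- fit_simple_regression(x, y)
  o <- oracle_simple_ols(x, y)
  expect_equal(unname(fit$slopes[1]), o$slope, tolerance = 1e-8)
  expect_equal(fit$intercept, o$intercept, tolerance = 1e-8)
  expect_equal(fit$r_squared, o$r2, tolerance = 1e-8)
  expect_equal(fit$residual_sd, o$residual_sd, tolerance = 1e-8)
  se <- o$residual_sd / sqrt(sum((x - mean(x))^2))
  expect_lt(abs(fit$slopes[1] - 50), 2 * se)
  # r^2 equals the squared sample correlation
  expect_equal(fit$r_squared, cor(x, y)^2, tolerance = 1e-10)
  # prediction half-width at the mean follows the closed form
  expect_equal(fit$pi95_halfwidth_at_mean,
               qt(0.975, 198) * fit$residual_sd * sqrt(1 + 1 / 200),
               tolerance = 1e-10)

  expect_error(fit_simple_regression(rep(1, 10), rnorm(10)), "constant")
  expect_error(fit_simple_regression(1:2, 1:2), "at least 3")
})

test_that("phase subsetting restricts the fit to the requested limb", {
  set.seed(5)
  x <- runif(60); y <- 10 + 5 * x + rnorm(60)
  ph <- rep(c("inflation", "deflation"), 30)
  f_inf <- fit_simple_regression(x, y, phase = ph, subset = "inflation")
  expect_equal(f_inf$n, 30)
  o <- oracle_simple_ols(x[ph == "inflation"], y[ph == "inflation"])
  expect_equal(unname(f_inf$slopes[1]), o$slope, tolerance = 1e-10)
})

test_that("log linearization is base-10 and rejects non-positive input", {
  expect_equal(log_linearize(100), 2)
  expect_equal(log_linearize(1), 0)
  expect_error(log_linearize(0), "positive")
  expect_error(log_linearize(c(10, -3)), "positive")
})

test_that("backward elimination removes noise covariates and keeps real ones", {
  dat <- simulate_regression_data(500, seed = 42, extra_noise_covariate = TRUE)
  res <- fit_multivariate(dat[, c("cov", "grade", "noise")], dat$percent_air)
  expect_true("noise" %in% res$trace$removed)
  expect_setequal(names(res$fit$slopes), c("cov", "grade"))
  expect_true(all(res$trace$p_value > 0.05))

  # strong covariates only: nothing is removed
  res2 <- fit_multivariate(dat[, c("cov", "grade")], dat$percent_air)
  expect_equal(nrow(res2$trace), 0)

  # alpha = 1 removes nothing even with the noise covariate present
  res3 <- fit_multivariate(dat[, c("cov", "grade", "noise")], dat$percent_air,
                           alpha = 1)
  expect_equal(nrow(res3$trace), 0)

  # alpha = 0 eliminates everything down to the intercept, with a warning
  expect_warning(
    res4 <- fit_multivariate(dat[, c("cov", "grade", "noise")],
                             dat$percent_air, alpha = 0),
    "intercept-only")
  expect_length(res4$fit$slopes, 0)
  expect_equal(nrow(res4$trace), 3)

  # a single covariate surviving elimination equals the simple fit
  res5 <- fit_multivariate(dat[, "cov", drop = FALSE], dat$percent_air)
  simple <- fit_simple_regression(dat$cov, dat$percent_air)
  expect_equal(unname(res5$fit$slopes[1]), unname(simple$slopes[1]),
               tolerance = 1e-12)
  expect_equal(res5$fit$intercept, simple$intercept, tolerance = 1e-12)
})

test_that("null covariates are retained at roughly the alpha rate", {
  kept <- vapply(1:200, function(i) {
    dat <- simulate_regression_data(120, seed = 5000 + i,
                                    extra_noise_covariate = TRUE)
    res <- suppressWarnings(
      fit_multivariate(dat[, c("cov", "grade", "noise")], dat$percent_air))
    "noise" %in% names(res$fit$slopes)
  }, logical(1))
  expect_gt(mean(kept), 0.01)
  expect_lt(mean(kept), 0.11)
})

test_that("predictions honour OLS identities and interval geometry", {
  dat <- simulate_regression_data(150, seed = 9)
  res <- fit_multivariate(dat[, c("cov", "grade")], dat$percent_air, alpha = 1)
  at_mean <- data.frame(cov = mean(dat$cov), grade = mean(dat$grade))
  pr <- predict_air_proportion(res$fit, at_mean)
  expect_equal(pr$point_estimate, mean(dat$percent_air), tolerance = 1e-10)
  expect_true(pr$pi95_low <= pr$point_estimate &&
                pr$point_estimate <= pr$pi95_high)
  expect_gte(pr$pi95_low_display, 0)
  expect_lte(pr$pi95_high_display, 100)

  # noise-free line: interval width collapses to zero
  x <- seq(0, 1, length.out = 20)
  fit0 <- suppressWarnings(
    fit_simple_regression(x, 10 + 40 * x, covariate_name = "cov"))
  pr0 <- predict_air_proportion(fit0, data.frame(cov = 0.5))
  expect_equal(pr0$pi95_high - pr0$pi95_low, 0, tolerance = 1e-8)

  expect_error(predict_air_proportion(res$fit, data.frame(cov = 1)),
               "missing covariate")
})

test_that("Kruskal-Wallis reproduces the hand-ranked H and handles edge cases", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  # hand computation: rank sums 6, 15, 24 -> H = 12/(9*10) * 279/3... = 7.2
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)
  expect_equal(kw$df, 2)
  expect_equal(kw$p_value, pchisq(7.2, 2, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_equal(kruskal_wallis(list(c(1, 2), c(1, 2)))$statistic, 0,
               tolerance = 1e-12)
  expect_error(kruskal_wallis(list(c(1, 2))), "two groups")
  expect_error(kruskal_wallis(list(c(1, 2), numeric(0))), "non-empty")
})

test_that("paired t-test matches the textbook formula", {
  a <- c(2, 1, 3, 2); b <- c(1, 2, 2, 3)   # differences 1,-1,1,-1
  r <- paired_t_test(a, b)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)
  expect_error(paired_t_test(c(2, 3, 4), c(1, 2, 3)), "zero-variance")

  set.seed(12)
  x <- rnorm(30, 5, 2); y <- x + rnorm(30, 0.5, 1)
  r2 <- paired_t_test(x, y)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(r2$statistic, t_hand, tolerance = 1e-10)
  expect_equal(r2$p_value, 2 * pt(-abs(t_hand), length(d) - 1),
               tolerance = 1e-10)
})
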