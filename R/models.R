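#' Simple linear regression of percent air on one imaging statistic
#'
#' Ordinary least squares of the CT-measured percent air on a single
#' covariate, optionally restricted to the inflation or deflation limb.
#' Callers are expected to supply type-1/2 observations only, as the
#' grading scale saturates outside that range.
#'
#' @param x covariate values.
#' @param y percent air (0-100), same length.
#' @param phase optional character vector of phases (`"inflation"`,
#'   `"deflation"`, `"suction"`) used with `subset`.
#' @param subset `"all"`, `"inflation"` or `"deflation"`.
#' @param covariate_name label for the covariate in the fit.
#' @return an object of class `aeration_fit`: a list with `intercept`,
#'   `slopes` (named), `r_squared`, `coefficient_p_values`, `residual_sd`,
#'   `n`, `pi95_halfwidth_at_mean` (the 95% prediction half-width at the
#'   covariate mean, `t[0.975, n-2] * s * sqrt(1 + 1/n)`),
#'   `pi95_halfwidth_mean` (mean half-width over the training points) and
#'   the underlying `lm` fit.
#' @export
fit_simple_regression <- function(x, y, phase = NULL,
                                  subset = c("all", "inflation", "deflation"),
                                  covariate_name = deparse(substitute(x))) {
  subset <- match.arg(subset)
  covariate_name <- covariate_name   # force before x is modified below
  if (length(x) != length(y)) stop_domain("x and y must have equal length")
  keep <- if (subset == "all") rep(TRUE, length(x)) else {
    if (is.null(phase)) stop_domain("phase vector required for subsetting")
    phase == subset
  }
  keep <- keep & is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop_domain("need at least 3 observations after subsetting")
  if (stats::sd(x) == 0) stop_domain("covariate is constant (singular design)")
  df <- data.frame(x = x, y = y)
  fit <- stats::lm(y ~ x, data = df)
  make_aeration_fit(fit, covariate_names = covariate_name, subset = subset)
}

make_aeration_fit <- function(fit, covariate_names, subset = "all") {
  sm <- summary(fit)
  cf <- stats::coef(fit)
  n <- length(stats::fitted(fit))
  p <- length(cf)
  s <- sm$sigma
  slopes <- cf[-1L]
  if (length(slopes)) names(slopes) <- covariate_names
  pvals <- sm$coefficients[, "Pr(>|t|)"]
  halfwidth_at_mean <- if (n > p)
    stats::qt(0.975, n - p) * s * sqrt(1 + 1 / n) else NA_real_
  # mean half-width over training points (leverage-aware)
  halfwidth_mean <- if (n > p) {
    h <- stats::hatvalues(fit)
    mean(stats::qt(0.975, n - p) * s * sqrt(1 + h))
  } else NA_real_
  structure(list(
    intercept = unname(cf[1L]),
    slopes = slopes,
    r_squared = sm$r.squared,
    coefficient_p_values = pvals,
    residual_sd = s,
    n = n,
    subset = subset,
    pi95_halfwidth_at_mean = halfwidth_at_mean,
    pi95_halfwidth_mean = halfwidth_mean,
    lm_fit = fit
  ), class = "aeration_fit")
}

#' @export
print.aeration_fit <- function(x, ...) {
  cat(sprintf("<aeration_fit> n = %d (%s), r^2 = %.3f, residual sd = %.2f\n",
              x$n, x$subset, x$r_squared, x$residual_sd))
  cat(sprintf("  intercept %.3f; slopes: %s\n", x$intercept,
              paste(sprintf("%s = %.4g", names(x$slopes), x$slopes),
                    collapse = ", ")))
  cat(sprintf("  95%% prediction half-width at covariate mean: %.2f\n",
              x$pi95_halfwidth_at_mean))
  invisible(x)
}

#' Base-10 log transform for log-linearization
#'
#' The relationship between the parallel-axis spectral area and percent air
#' is logarithmic, so that covariate is linearized on a log scale before
#' regression.
#'
#' @param values positive values (power units).
#' @return `log10(values)`.
#' @export
log_linearize <- function(values) {
  if (any(!is.finite(values) | values <= 0))
    stop_domain("log linearization requires strictly positive values")
  log10(values)
}

#' Multivariate regression with stepwise backward elimination
#'
#' Fits percent air on all supplied imaging covariates, then iteratively
#' removes the covariate with the largest p-value while that p-value
#' exceeds `alpha`, refitting after each removal.
#'
#' @param features data frame of covariates (e.g. `mpi`, `cov`,
#'   `auc_parallel_log`, `auc_perpendicular`, `grade`); grade enters as a
#'   numeric covariate.
#' @param y percent air (0-100).
#' @param alpha retention threshold for coefficient p-values
#'   (default 0.05).
#' @return a list with `fit` (an `aeration_fit`; intercept-only with a
#'   warning if every covariate is eliminated) and `trace` (a data frame
#'   of removed covariates and their p-values at removal, in order).
#' @export
fit_multivariate <- function(features, y, alpha = 0.05) {
  features <- as.data.frame(features)
  if (nrow(features) != length(y))
    stop_domain("features and y must have equal length")
  if (nrow(features) <= ncol(features) + 2L)
    stop_domain("too few observations for the number of covariates")
  vars <- names(features)
  trace <- data.frame(removed = character(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  repeat {
    if (length(vars) == 0L) {
      fit <- stats::lm(y ~ 1, data = data.frame(y = y))
      warning("all covariates eliminated; returning intercept-only fit")
      out <- make_aeration_fit(fit, covariate_names = character(0))
      return(list(fit = out, trace = trace))
    }
    dat <- cbind(features[vars], y = y)
    fit <- stats::lm(stats::reformulate(vars, "y"), data = dat)
    pv <- summary(fit)$coefficients[, "Pr(>|t|)"]
    pv <- pv[names(pv) != "(Intercept)"]
    worst <- which.max(pv)
    if (pv[worst] > alpha) {
      trace <- rbind(trace, data.frame(removed = names(pv)[worst],
                                       p_value = unname(pv[worst]),
                                       stringsAsFactors = FALSE))
      vars <- setdiff(vars, names(pv)[worst])
    } else {
      out <- make_aeration_fit(fit, covariate_names = vars)
      return(list(fit = out, trace = trace))
    }
  }
}

#' Predict percent air with a 95% prediction interval
#'
#' Point estimate and 95% prediction interval from an [fit_simple_regression()]
#' or [fit_multivariate()] fit, using the full OLS interval with the
#' leverage term at the supplied covariate point. Raw interval bounds are
#' returned alongside display bounds clamped to `[0, 100]` percent.
#'
#' @param fit an `aeration_fit`.
#' @param features data frame (or named list) containing every covariate of
#'   the fit.
#' @return data frame with `point_estimate`, `pi95_low`, `pi95_high` (raw)
#'   and `pi95_low_display`, `pi95_high_display` (clamped to 0-100).
#' @export
predict_air_proportion <- function(fit, features) {
  if (!inherits(fit, "aeration_fit")) stop_domain("fit must be an aeration_fit")
  needed <- names(fit$slopes)
  features <- as.data.frame(features)
  if (!all(needed %in% names(features)))
    stop_domain(sprintf("missing covariate(s): %s",
                        paste(setdiff(needed, names(features)), collapse = ", ")))
  newdata <- features[, needed, drop = FALSE]
  # fit_simple_regression stores the covariate under the model name "x"
  if (identical(names(stats::coef(fit$lm_fit))[-1L], "x") &&
      length(needed) == 1L)
    names(newdata) <- "x"
  pr <- stats::predict(fit$lm_fit, newdata = newdata,
                       interval = "prediction", level = 0.95)
  data.frame(
    point_estimate = pr[, "fit"],
    pi95_low = pr[, "lwr"],
    pi95_high = pr[, "upr"],
    pi95_low_display = clamp(pr[, "lwr"], 0, 100),
    pi95_high_display = clamp(pr[, "upr"], 0, 100)
  )
}

#' Kruskal-Wallis rank test across groups
#'
#' H statistic on mid-ranks with the standard tie correction and a
#' chi-square approximation on k-1 degrees of freedom.
#'
#' @param groups list of at least two non-empty numeric vectors.
#' @return a list of class `group_comparison` with `statistic` (H),
#'   `p_value`, `df` and per-group summaries.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))$statistic  # 7.2
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_domain("need at least two groups")
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop_domain("every group must be non-empty")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  ht <- stats::kruskal.test(values, g)
  structure(list(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    df = unname(ht$parameter),
    group_summaries = data.frame(
      group = seq_along(groups),
      n = vapply(groups, length, integer(1)),
      median = vapply(groups, stats::median, numeric(1))
    )
  ), class = "group_comparison")
}

#' Paired t-test
#'
#' Two-sided paired t-test: `t = mean(d) / (sd(d) / sqrt(n))` on the
#' pairwise differences, with n-1 degrees of freedom.
#'
#' @param a,b paired measurement vectors of equal length (>= 2).
#' @return a list of class `group_comparison` with `statistic` (t),
#'   `p_value`, `df` and the mean difference.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop_domain("a and b must be paired vectors of length >= 2")
  d <- a - b
  if (stats::sd(d) == 0)
    stop_domain("paired t statistic undefined: zero-variance differences")
  ht <- stats::t.test(a, b, paired = TRUE)
  structure(list(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    df = unname(ht$parameter),
    mean_difference = unname(ht$estimate)
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> statistic = %.4g, df = %g, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Simulate a tabular regression cohort with a known linear map
#'
#' Generates (CoV, grade) covariates over the type-1/2 range and percent
#' air from a known linear model plus Gaussian noise; used for parameter
#' recovery, prediction-interval coverage and elimination operating
#' characteristics.
#'
#' @param n observations.
#' @param beta0 intercept (percent air).
#' @param beta_cov,beta_grade true coefficients.
#' @param sigma residual standard deviation (percent air).
#' @param seed integer seed.
#' @param extra_noise_covariate add a pure-noise covariate `noise` with
#'   true coefficient 0.
#' @return data frame with columns `cov`, `grade`, (optionally `noise`)
#'   and `percent_air`.
#' @export
simulate_regression_data <- function(n, beta0 = 10, beta_cov = 40,
                                     beta_grade = 12, sigma = 10,
                                     seed = 1L,
                                     extra_noise_covariate = FALSE) {
  with_seed(seed, {
    cov <- stats::runif(n, 0.2, 1.6)
    grade <- sample(c(1, 2), n, replace = TRUE)
    mu <- beta0 + beta_cov * cov + beta_grade * grade
    y <- mu + stats::rnorm(n, 0, sigma)
    out <- data.frame(cov = cov, grade = grade, percent_air = y)
    if (extra_noise_covariate) out$noise <- stats::rnorm(n)
    out
  })
}
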