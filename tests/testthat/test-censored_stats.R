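test_that("ros_summary reduces to sample statistics without censoring", {
  set.seed(31)
  v <- rlnorm(20, 1, 0.8)
  s <- ros_summary(v, rep(FALSE, 20))
  expect_equal(s$geometric_mean, exp(mean(log(v))), tolerance = 1e-12)
  expect_equal(s$arithmetic_mean, mean(v), tolerance = 1e-12)
  expect_identical(s$n_censored, 0L)

  s2 <- ros_summary(rep(4.4, 5), rep(FALSE, 5))
  expect_equal(s2$geometric_mean, 4.4)
  expect_equal(s2$arithmetic_mean, 4.4)
})

test_that("ROS means lie between the substitution bounds at 20% censoring", {
  set.seed(32)
  true <- rlnorm(30, 0, 1)
  lim <- quantile(true, 0.2, names = FALSE)
  cens <- true < lim
  value <- ifelse(cens, lim, true)
  s <- ros_summary(value, cens)
  # oracle bounds: censored values substituted at their limit vs at ~zero
  hi_arith <- mean(value)
  lo_arith <- mean(ifelse(cens, 0, value))
  expect_gte(hi_arith, s$arithmetic_mean)
  expect_lte(lo_arith, s$arithmetic_mean)
  hi_geo <- exp(mean(log(value)))
  lo_geo <- exp(mean(log(ifelse(cens, 1e-12, value))))
  expect_gte(hi_geo, s$geometric_mean)
  expect_lte(lo_geo, s$geometric_mean)
  # imputed values respect their limits
  expect_true(all(s$imputed <= lim))
})

test_that("ros_summary handles multiple limits and refuses degeneracies", {
  value <- c(0.5, 0.5, 1.2, 1.8, 2.0, 3.1, 1.0, 5.5)
  cens <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  s <- ros_summary(value, cens)
  expect_equal(s$n_censored, 3L)
  expect_true(s$geometric_mean > 0 && s$arithmetic_mean >= s$geometric_mean)

  expect_error(ros_summary(c(1, 2), c(FALSE, FALSE)), "at least 3")
  expect_error(ros_summary(c(1, 2, 3), c(TRUE, TRUE, TRUE)), "all observations")
  expect_error(ros_summary(c(1, 1, 1, 1, 2), c(TRUE, TRUE, TRUE, TRUE, FALSE)),
               "80%")
  expect_error(ros_summary(c(-1, 2, 3), rep(FALSE, 3)), "positive")
})

test_that("censored MLE equals OLS with zero censoring", {
  set.seed(41)
  x <- runif(40, 1, 4)
  y <- 0.7 * x + 1 + rnorm(40, 0, 0.5)
  fit <- censored_linregress(y, x)
  ols <- oracle_ols(y, x)
  expect_equal(fit$slope, unname(ols["slope"]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(ols["intercept"]), tolerance = 1e-6)
  expect_identical(fit$n_censored, 0L)
})

test_that("noiseless linear data recovers the exact slope with floored sigma", {
  x <- 1:10
  y <- 0.3 * x - 2
  fit <- censored_linregress(y, x)
  expect_equal(fit$slope, 0.3, tolerance = 1e-12)
  expect_equal(fit$intercept, -2, tolerance = 1e-12)
  expect_lte(fit$sigma, 1e-8)
  expect_lt(fit$p_value, 1e-10)
})

test_that("MLE matches a dense grid search of the same likelihood (30% censoring)", {
  set.seed(42)
  n <- 30
  x <- runif(n, 1, 4)
  y_true <- 0.6 * x + 0.5 + rnorm(n, 0, 0.7)
  lim <- quantile(y_true, 0.3, names = FALSE)
  cens <- y_true < lim
  y <- ifelse(cens, lim, y_true)

  fit <- censored_linregress(y, x, cens)
  oracle <- oracle_grid_fit(y, x, cens)
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-3)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-3)
  # returned optimum beats every grid point
  expect_gte(fit$log_likelihood, oracle$loglik - 1e-6)
})

test_that("MLE agrees with survreg's left-censored Gaussian fit", {
  skip_if_not_installed("survival")
  set.seed(43)
  n <- 60
  x <- runif(n, 1, 4)
  y_true <- -0.4 * x + 2 + rnorm(n, 0, 0.6)
  lim <- quantile(y_true, 0.25, names = FALSE)
  cens <- y_true < lim
  y <- ifelse(cens, lim, y_true)
  fit <- censored_linregress(y, x, cens)
  sr <- survival::survreg(survival::Surv(y, !cens, type = "left") ~ x,
                          dist = "gaussian")
  expect_equal(fit$slope, unname(coef(sr)[2]), tolerance = 1e-5)
  expect_equal(fit$intercept, unname(coef(sr)[1]), tolerance = 1e-5)
  expect_equal(fit$sigma, sr$scale, tolerance = 1e-4)
  expect_equal(fit$slope_se, sqrt(diag(sr$var))[2], tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("shift and scale equivariance; mild robustness to deep censoring", {
  set.seed(44)
  n <- 40
  x <- runif(n, 1, 4)
  y_true <- 0.5 * x + rnorm(n, 0, 0.5)
  lim <- quantile(y_true, 0.25, names = FALSE)
  cens <- y_true < lim
  y <- ifelse(cens, lim, y_true)
  f1 <- censored_linregress(y, x, cens)
  # adding a constant to y (and the limits inside y) shifts only the intercept
  f2 <- censored_linregress(y + 5, x, cens)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-8)
  expect_equal(f2$intercept, f1$intercept + 5, tolerance = 1e-8)
  # multiplying x by c divides the slope by c
  f3 <- censored_linregress(y, 2 * x, cens)
  expect_equal(f3$slope, f1$slope / 2, tolerance = 1e-8)

  # censoring a point already far below its fitted mean barely moves the slope
  idx <- which(!cens)[which.min(y[!cens] - (f1$intercept + f1$slope * x[!cens]))]
  y2 <- y; cens2 <- cens
  cens2[idx] <- TRUE  # value becomes its own limit: "< y" is nearly certain
  f4 <- censored_linregress(y2, x, cens2)
  expect_lt(abs(f4$slope - f1$slope), f1$sigma)

  expect_error(censored_linregress(c(1, 2, 3), c(2, 2, 2)), "constant")
  expect_error(censored_linregress(c(1, 2, 3, 4), 1:4,
                                   c(TRUE, TRUE, FALSE, FALSE)),
               "3 uncensored")
})

test_that("likelihood-ratio p-value is available and sane", {
  set.seed(45)
  x <- runif(50, 1, 4)
  y <- 0.8 * x + rnorm(50, 0, 0.5)
  lim <- quantile(y, 0.2, names = FALSE)
  cens <- y < lim
  yy <- ifelse(cens, lim, y)
  fw <- censored_linregress(yy, x, cens, test = "wald")
  fl <- censored_linregress(yy, x, cens, test = "lrt")
  expect_equal(fw$slope, fl$slope, tolerance = 1e-10)
  expect_lt(fl$p_value, 0.001)
  expect_lt(fw$p_value, 0.001)
})
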