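# Statistics for left-censored (nondetect) data: regression-on-order-
# statistics summary means and maximum-likelihood censored linear
# regression, the engine behind every TMF.

#' Summary means of left-censored data by regression on order statistics
#'
#' Helsel-style ROS for multiply-censored environmental data, assuming a
#' lognormal distribution. Plotting positions come from the
#' Hirsch-Stedinger survival recursion over the distinct censoring limits
#' (processed in descending-limit order); the natural logs of the
#' uncensored observations are regressed on the corresponding normal
#' quantiles, censored observations are imputed from the fitted line, and
#' the geometric and arithmetic means are taken over observed plus imputed
#' values. With no censoring the procedure reduces exactly to the sample
#' statistics (no imputation occurs).
#'
#' @param value Positive measurement values; for censored entries the value
#'   is the quantification limit.
#' @param censored Logical vector: `TRUE` where the observation is a
#'   nondetect ("< limit").
#' @return List with `geometric_mean`, `arithmetic_mean`, `n`, `n_censored`,
#'   and `imputed` (imputed values for the censored observations, in input
#'   order).
#' @examples
#' ros_summary(c(1, 2, 4, 0.5, 0.5), censored = c(FALSE, FALSE, FALSE, TRUE, TRUE))
#' @export
ros_summary <- function(value, censored) {
  censored <- as.logical(censored)
  stopifnot(length(value) == length(censored))
  if (length(value) < 3L)
    stop("ros_summary needs at least 3 observations", call. = FALSE)
  if (any(!is.finite(value)) || any(value <= 0))
    stop("values must be positive and finite", call. = FALSE)
  if (!any(!censored))
    stop("all observations censored: report '< limit' instead", call. = FALSE)
  cen_frac <- mean(censored)
  if (cen_frac >= 0.8)
    stop(sprintf(
      "censoring fraction %.0f%% >= 80%%: ROS unreliable, report '< limit' instead",
      100 * cen_frac), call. = FALSE)

  n <- length(value)
  if (!any(censored)) {
    return(list(geometric_mean = exp(mean(log(value))),
                arithmetic_mean = mean(value),
                n = n, n_censored = 0L, imputed = numeric()))
  }

  pp <- ros_plotting_positions(value, censored)
  lnv <- log(value)
  xq <- stats::qnorm(pp)
  xu <- xq[!censored]; yu <- lnv[!censored]
  # OLS of ln(value) on normal quantiles over the uncensored observations
  xbar <- mean(xu); ybar <- mean(yu)
  ssx <- sum((xu - xbar)^2)
  if (ssx <= 0)
    stop("degenerate plotting positions: cannot fit ROS line", call. = FALSE)
  slope <- sum((xu - xbar) * (yu - ybar)) / ssx
  intercept <- ybar - slope * xbar
  imputed <- exp(intercept + slope * xq[censored])
  all_vals <- c(value[!censored], imputed)
  list(geometric_mean = exp(mean(log(all_vals))),
       arithmetic_mean = mean(all_vals),
       n = n, n_censored = sum(censored), imputed = imputed)
}

# Hirsch-Stedinger plotting positions for multiply left-censored data.
# Returns cumulative probabilities in input order.
ros_plotting_positions <- function(value, censored) {
  n <- length(value)
  limits <- sort(unique(value[censored]))         # distinct censoring limits
  lims <- c(0, limits)                            # pseudo-limit 0 at bottom
  m <- length(lims)
  upper <- c(lims[-1], Inf)
  # A_j: uncensored obs in [L_j, L_{j+1}); B_j: all obs below L_j;
  # C_j: censored obs at L_j. Survival recursion runs from the top limit down.
  A <- B <- C <- numeric(m)
  for (j in seq_len(m)) {
    A[j] <- sum(!censored & value >= lims[j] & value < upper[j])
    B[j] <- sum((!censored & value < lims[j]) | (censored & value <= lims[j] &
                                                   value > 0 & lims[j] > 0))
    C[j] <- sum(censored & value == lims[j])
  }
  # B for the pseudo-limit is 0 by construction (lims[1] == 0)
  pe <- numeric(m + 1L)                           # pe[j] = P(X >= L_j), pe[m+1] = 0
  for (j in m:1) {
    denom <- A[j] + B[j]
    pe[j] <- if (denom > 0) pe[j + 1L] + A[j] / denom * (1 - pe[j + 1L])
             else pe[j + 1L]
  }
  pp <- numeric(n)
  for (j in seq_len(m)) {
    idx_u <- which(!censored & value >= lims[j] & value < upper[j])
    if (length(idx_u)) {
      ord <- order(value[idx_u])
      ranks <- seq_along(idx_u)
      pp[idx_u[ord]] <- (1 - pe[j]) +
        (pe[j] - pe[j + 1L]) * ranks / (length(idx_u) + 1L)
    }
    idx_c <- which(censored & value == lims[j])
    if (length(idx_c))
      pp[idx_c] <- (1 - pe[j]) * seq_along(idx_c) / (length(idx_c) + 1L)
  }
  pp
}

#' Maximum-likelihood linear regression with left-censored response
#'
#' Fits \eqn{y_i = b_0 + b_1 x_i + \epsilon_i}, \eqn{\epsilon_i \sim
#' N(0, \sigma^2)}, where censored responses are known only to lie below
#' their reported value (the log quantification limit). The log-likelihood
#' combines Gaussian density terms for uncensored points with lower-tail
#' probabilities \eqn{\Phi((y_i - \mu_i)/\sigma)} for censored points, and
#' is maximized over \eqn{(b_0, b_1, \log\sigma)} by quasi-Newton descent
#' started from OLS with censored values substituted at their limits. The
#' slope standard error comes from the observed information matrix; the
#' default p-value is a two-sided Wald test of slope = 0, with a
#' likelihood-ratio alternative.
#'
#' With no censored observations the maximum-likelihood fit coincides with
#' ordinary least squares.
#'
#' @param y Response values on the natural-log scale; for censored entries
#'   the log of the quantification limit.
#' @param x Covariate (trophic position); must not be constant.
#' @param censored Logical nondetect flags (default none).
#' @param test `"wald"` (default) or `"lrt"` for the slope p-value.
#' @param sigma_floor Lower bound on the residual standard deviation,
#'   guarding exact-fit degeneracies. Default 1e-8.
#' @return Object of class `censored_fit`: `slope`, `intercept`, `slope_se`,
#'   `sigma`, `n_total`, `n_censored`, `log_likelihood`, `p_value`,
#'   `test`, `convergence`.
#' @export
censored_linregress <- function(y, x, censored = rep(FALSE, length(y)),
                                test = c("wald", "lrt"),
                                sigma_floor = 1e-8) {
  test <- match.arg(test)
  censored <- as.logical(censored)
  stopifnot(length(y) == length(x), length(censored) == length(y))
  ok <- is.finite(y) & is.finite(x)
  if (!all(ok)) stop("y and x must be finite", call. = FALSE)
  n <- length(y)
  if (sum(!censored) < 3L)
    stop("need at least 3 uncensored observations", call. = FALSE)
  if (stats::var(x) <= 0)
    stop("design degeneracy: x is constant", call. = FALSE)

  ols <- ols_line(y, x)

  nll <- function(par) {
    mu <- par[1] + par[2] * x
    s <- max(exp(par[3]), sigma_floor)
    ll <- sum(stats::dnorm(y[!censored], mu[!censored], s, log = TRUE))
    if (any(censored))
      ll <- ll + sum(stats::pnorm(y[censored], mu[censored], s,
                                  log.p = TRUE))
    if (!is.finite(ll)) return(1e300)
    -ll
  }

  if (!any(censored) && ols$sigma < 1e-10) {
    # exact linear data: likelihood is unbounded as sigma -> 0; report the
    # OLS line with sigma at the floor
    return(structure(
      list(slope = ols$slope, intercept = ols$intercept,
           slope_se = 0, sigma = sigma_floor, n_total = n, n_censored = 0L,
           log_likelihood = -nll(c(ols$intercept, ols$slope,
                                   log(sigma_floor))),
           p_value = if (ols$slope == 0) 1 else 0,
           test = test, convergence = 0L),
      class = "censored_fit"))
  }

  # analytic gradient of the negative log-likelihood in (b0, b1, log sigma)
  nll_grad <- function(par) {
    mu <- par[1] + par[2] * x
    s <- max(exp(par[3]), sigma_floor)
    g <- c(0, 0, 0)
    if (any(!censored)) {
      r <- (y[!censored] - mu[!censored]) / s
      g[1] <- g[1] - sum(r) / s
      g[2] <- g[2] - sum(r * x[!censored]) / s
      g[3] <- g[3] - sum(r^2 - 1)
    }
    if (any(censored)) {
      z <- (y[censored] - mu[censored]) / s
      # d log Phi(z) / dz, computed stably in logs
      w <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
      g[1] <- g[1] + sum(w) / s
      g[2] <- g[2] + sum(w * x[censored]) / s
      g[3] <- g[3] + sum(w * z)
    }
    g
  }

  start <- c(ols$intercept, ols$slope, log(max(ols$sigma, 1e-3)))
  opt <- stats::optim(start, nll, gr = nll_grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  if (opt$convergence != 0) {
    opt2 <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                         control = list(maxit = 5000, reltol = 1e-14))
    if (opt2$value <= opt$value) opt <- opt2
    if (opt$convergence != 0)
      stop(sprintf(
        "censored regression did not converge (code %d, nll %.6g)",
        opt$convergence, opt$value), call. = FALSE)
  }
  # Newton polish: drive the gradient to ~0 so estimates do not carry
  # optimizer noise (scheme-equivalence identities hold to ~1e-12)
  for (it in 1:25) {
    g <- nll_grad(opt$par)
    if (max(abs(g)) < 1e-11) break
    h <- stats::optimHess(opt$par, nll, gr = nll_grad)
    step <- tryCatch(solve(h, g), error = function(e) NULL)
    if (is.null(step)) break
    cand <- opt$par - step
    vc <- nll(cand)
    if (!is.finite(vc) || vc > opt$value + 1e-8) break
    opt$par <- cand; opt$value <- vc
  }
  hess <- stats::optimHess(opt$par, nll, gr = nll_grad)
  vcov <- tryCatch(solve(hess), error = function(e) NULL)
  slope_se <- if (!is.null(vcov) && vcov[2, 2] > 0) sqrt(vcov[2, 2]) else NA_real_
  slope <- opt$par[2]; intercept <- opt$par[1]
  sigma <- max(exp(opt$par[3]), sigma_floor)
  ll <- -opt$value

  p_value <- if (test == "wald") {
    if (is.na(slope_se) || slope_se == 0) {
      if (is.na(slope_se)) NA_real_ else if (slope == 0) 1 else 0
    } else 2 * stats::pnorm(-abs(slope / slope_se))
  } else {
    nll0 <- function(par) nll(c(par[1], 0, par[2]))
    opt0 <- stats::optim(c(mean(y), log(max(stats::sd(y), 1e-3))), nll0,
                         method = "BFGS",
                         control = list(maxit = 1000, reltol = 1e-14))
    stats::pchisq(2 * (ll - (-opt0$value)), df = 1, lower.tail = FALSE)
  }

  structure(
    list(slope = slope, intercept = intercept, slope_se = slope_se,
         sigma = sigma, n_total = n, n_censored = sum(censored),
         log_likelihood = ll, p_value = p_value, test = test,
         convergence = opt$convergence),
    class = "censored_fit")
}

#' @export
print.censored_fit <- function(x, ...) {
  cat(sprintf(
    "<censored_fit> slope = %.4g (se %.3g), intercept = %.4g, sigma = %.3g\n",
    x$slope, x$slope_se, x$intercept, x$sigma))
  cat(sprintf("  n = %d (%d censored), logLik = %.4g, p(%s) = %.3g\n",
              x$n_total, x$n_censored, x$log_likelihood, x$test, x$p_value))
  invisible(x)
}

# closed-form OLS, censored values taken at their limits
ols_line <- function(y, x) {
  xbar <- mean(x); ybar <- mean(y)
  ssx <- sum((x - xbar)^2)
  slope <- sum((x - xbar) * (y - ybar)) / ssx
  intercept <- ybar - slope * xbar
  resid <- y - intercept - slope * x
  list(slope = slope, intercept = intercept,
       sigma = sqrt(sum(resid^2) / length(y)))
}
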