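# Independent oracles and shared fixtures. Everything here is computed
# without touching the code paths it checks.

# closed-form OLS slope/intercept
oracle_ols <- function(y, x) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# independent left-censored Gaussian log-likelihood (y on ln scale;
# censored entries carry the ln limit as their value)
oracle_cens_loglik <- function(b0, b1, sigma, y, x, cens) {
  mu <- b0 + b1 * x
  sum(dnorm(y[!cens], mu[!cens], sigma, log = TRUE)) +
    sum(pnorm(y[cens], mu[cens], sigma, log.p = TRUE))
}

# dense grid-search maximization of the censored likelihood: iteratively
# refined slope x intercept grid with sigma profiled by 1-D optimization
oracle_grid_fit <- function(y, x, cens, iters = 4, steps = 31) {
  start <- oracle_ols(y, x)
  ctr <- c(start["slope"], start["intercept"])
  width <- c(1, 2)
  sd0 <- sd(y)
  best <- NULL
  for (it in seq_len(iters)) {
    slopes <- seq(ctr[1] - width[1], ctr[1] + width[1], length.out = steps)
    ints <- seq(ctr[2] - width[2], ctr[2] + width[2], length.out = steps)
    vals <- matrix(NA_real_, steps, steps)
    for (i in seq_len(steps)) for (j in seq_len(steps)) {
      o <- optimize(function(s)
        oracle_cens_loglik(ints[j], slopes[i], s, y, x, cens),
        interval = c(1e-4, 5 * sd0), maximum = TRUE, tol = 1e-10)
      vals[i, j] <- o$objective
    }
    k <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    ctr <- c(slopes[k[1]], ints[k[2]])
    best <- list(slope = slopes[k[1]], intercept = ints[k[2]],
                 loglik = max(vals))
    width <- width * 2.5 / (steps - 1)  # shrink around the best cell
  }
  best
}

# small chemical table built in code: one fully-measured chemical per class
toy_chem <- function(name = "TOY", class = "PFSA",
                     logd = c(NLW = 0, PLW = 3.5, ALBW = 4.5, SPW = 2.5),
                     melting_point = 400, molar_mass = 500,
                     water_solubility = 0.5, molar_volume = 270) {
  chemical_record(name, class, 8, molar_mass, molar_volume, melting_point,
                  water_solubility, logd = logd)
}

# composition fixtures
comp_water <- tissue_composition(phi_W = 1)
comp_avian <- tissue_composition(phi_NL = 0.04, phi_PL = 0.010,
                                 phi_ALB = 0.039, phi_SP = 0.021,
                                 phi_W = 0.75)

# constant-composition synthetic config (identical composition and body
# temperature for every sample), used for the scheme-equivalence identity
constant_comp_config <- function(seed, ...) {
  synthetic_config(
    seed = seed,
    composition = list(
      intercepts = c(NL = 0.02, PL = 0.01, ALB = 0.03, SP = 0.02, W = 0.75),
      slopes = c(NL = 0, PL = 0, ALB = 0, SP = 0, W = 0)),
    tp_cutoff = 0,  # all samples share the warm body temperature
    ...)
}

# samples/measurements data-frame pair built directly (no generator):
# constant composition, wet-weight values exactly exp(b0 + m * tp)
handmade_dataset <- function(tp, m, b0 = 0, comp = comp_avian,
                             analyte = "TOY") {
  n <- length(tp)
  samples <- data.frame(
    sample_id = sprintf("H%02d", seq_len(n)), species = "x", group = "g",
    delta15N = NA_real_, trophic_position = tp, body_temperature_K = 313,
    phi_NL = comp[["NL"]], phi_PL = comp[["PL"]], phi_ALB = comp[["ALB"]],
    phi_SP = comp[["SP"]], phi_W = comp[["W"]])
  conc <- exp(b0 + m * tp)
  measurements <- data.frame(
    sample_id = samples$sample_id, analyte = analyte,
    conc_ng_g_ww = conc, censored = 0L,
    mloq_ng_g_ww = min(conc) / 10)
  list(samples = samples, measurements = measurements)
}
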