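# Synthetic food-web generator: datasets with the statistical structure the
# TMF analysis assumes (composition trending with trophic position,
# log-normal activity noise around a true TMF, left-censoring at a
# quantification limit), plus parameter-recovery experiments.

#' Configuration for the synthetic food-web generator
#'
#' The generator states a food web of `n_samples` organisms spanning the
#' trophic-position range `tp_range` (evenly spaced with Gaussian jitter,
#' floored at 1). Tissue fractions follow per-phase linear models in TP
#' whose default slopes mirror observed terrestrial food-web trends:
#' albumin +0.96 and neutral lipid +0.93 percentage points per trophic
#' level, polar lipid +0.41, structural protein +0.14 (total protein ~1.1
#' minus albumin), water flat at 70%. Each analyte's true state is an
#' activity-scale TMF, a baseline activity at TP = 0, and a log-scale
#' residual sd; wet-weight concentrations are obtained by inverting the
#' apparent-activity equation per sample, and left-censoring is applied at
#' a per-analyte MLOQ (given explicitly or derived as the
#' `censoring_target` quantile of the drawn concentrations).
#'
#' @param n_samples Number of biota samples (default 74).
#' @param tp_range Trophic-position range, default `c(1, 4)`.
#' @param tp_jitter_sd Gaussian jitter sd on TP (default 0.15).
#' @param composition List with numeric vectors `intercepts` and `slopes`,
#'   each named `NL`, `PL`, `ALB`, `SP`, `W`, on the fraction (0-1) scale.
#' @param analytes data.frame with columns `name`, `true_tmf`,
#'   `baseline_activity`, `sigma`, and optionally `mloq` (NA = derive from
#'   `censoring_target`). Default: four bundled analytes with true TMFs
#'   0.5, 1, 2 and 5.
#' @param censoring_target Target left-censoring fraction in \[0, 0.8)
#'   (default 0.30) used when an analyte has no explicit MLOQ.
#' @param chemicals A `chem_table`; default the bundled synthetic property
#'   table ([synthetic_chem_table()]).
#' @param body_temperature_cold,body_temperature_warm,tp_cutoff Body
#'   temperatures (K) assigned below/above the TP cutoff: 291 K
#'   (poikilothermic invertebrates) and 313 K (birds), cutoff 2.5.
#' @param density Tissue density, g/cm^3.
#' @param entropy_ratio Entropy-of-fusion ratio for the fugacity ratio.
#' @param seed Integer seed recorded in the output; `NULL` leaves the RNG
#'   state untouched.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 74, tp_range = c(1, 4),
                             tp_jitter_sd = 0.15,
                             composition = list(
                               intercepts = c(NL = 0.002, PL = 0.0005,
                                              ALB = 0.005, SP = 0.012,
                                              W = 0.70),
                               slopes = c(NL = 0.0093, PL = 0.0041,
                                          ALB = 0.0096, SP = 0.0014,
                                          W = 0)),
                             analytes = NULL, censoring_target = 0.30,
                             chemicals = NULL,
                             body_temperature_cold = 291,
                             body_temperature_warm = 313, tp_cutoff = 2.5,
                             density = 1, entropy_ratio = 6.79,
                             seed = NULL) {
  if (is.null(chemicals)) chemicals <- synthetic_chem_table()
  if (is.null(analytes))
    analytes <- data.frame(name = c("PFBS", "PFOA", "PFNA", "PFOS"),
                           true_tmf = c(0.5, 1, 2, 5),
                           baseline_activity = 1e-8, sigma = 0.6,
                           mloq = NA_real_)
  if (!"mloq" %in% names(analytes)) analytes$mloq <- NA_real_
  stopifnot(n_samples >= 3, length(tp_range) == 2, tp_range[1] >= 1,
            tp_range[2] > tp_range[1], tp_jitter_sd >= 0,
            all(analytes$sigma >= 0), all(analytes$true_tmf > 0),
            all(analytes$baseline_activity > 0),
            censoring_target >= 0, censoring_target < 0.8)
  phases <- c("NL", "PL", "ALB", "SP", "W")
  stopifnot(all(phases %in% names(composition$intercepts)),
            all(phases %in% names(composition$slopes)))
  # the composition model must admit valid samples over the TP range
  for (tp in tp_range) {
    phi <- pmin(pmax(composition$intercepts[phases] +
                       composition$slopes[phases] * tp, 0), 1)
    if (sum(phi) > 1 + 1e-9)
      stop(sprintf(
        "composition model invalid: fractions sum to %.3f > 1 at TP = %g",
        sum(phi), tp), call. = FALSE)
  }
  for (nm in analytes$name) chem_get(chemicals, nm)  # must all resolve
  structure(
    list(n_samples = as.integer(n_samples), tp_range = tp_range,
         tp_jitter_sd = tp_jitter_sd, composition = composition,
         analytes = analytes, censoring_target = censoring_target,
         chemicals = chemicals,
         body_temperature_cold = body_temperature_cold,
         body_temperature_warm = body_temperature_warm,
         tp_cutoff = tp_cutoff, density = density,
         entropy_ratio = entropy_ratio, seed = seed),
    class = "synthetic_config")
}

#' Bundled synthetic chemical property table
#'
#' Reads the synthetic PFAS property table shipped with the package
#' (`extdata/chemicals_synthetic.csv`): twelve perfluoroalkyl acids with
#' field-realistic molar volumes, melting points, water solubilities, and
#' phase-water log distribution coefficients. "Measured" coefficients are
#' present for the shorter homologues (PFCA C8-C11, PFSA C4-C8); longer
#' chains carry empty cells and are filled by QSPR prediction. The values
#' are synthetic stand-ins with realistic magnitudes and trends, not
#' literature data.
#'
#' @return A `chem_table`.
#' @export
synthetic_chem_table <- function() {
  read_chemicals(system.file("extdata", "chemicals_synthetic.csv",
                             package = "pfastmf", mustWork = TRUE))
}

#' Generate a synthetic food-web dataset
#'
#' Draws trophic positions, builds tissue compositions from the linear
#' composition model (clipped to \[0, 1\], clipping counted), draws
#' log-normal apparent activities around each analyte's true TMF line,
#' inverts the activity equation to wet-weight concentrations, and applies
#' left-censoring at the MLOQ. The same config and seed reproduce the
#' dataset exactly.
#'
#' @param config A [synthetic_config()].
#' @return Object of class `synthetic_foodweb`: list with `samples`,
#'   `measurements`, `chemicals`, `truth` (per-analyte true TMF, baseline,
#'   sigma, MLOQ, realized censoring), `activities` (uncensored true
#'   activities and concentrations, for round-trip checks), `n_clipped`,
#'   and the `config`.
#' @export
generate_foodweb <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_samples
  tp <- seq(config$tp_range[1], config$tp_range[2], length.out = n) +
    stats::rnorm(n, 0, config$tp_jitter_sd)
  tp <- pmax(tp, 1)

  phases <- c("NL", "PL", "ALB", "SP", "W")
  phi_raw <- sapply(phases, function(p)
    config$composition$intercepts[[p]] + config$composition$slopes[[p]] * tp)
  phi <- pmin(pmax(phi_raw, 0), 1)
  n_clipped <- sum(phi != phi_raw)
  if (n_clipped > 0)
    message(n_clipped, " composition value(s) clipped to [0, 1]")
  bad <- rowSums(phi) > 1 + 1e-9
  if (any(bad))
    stop(sum(bad), " generated sample(s) have fractions summing above 1",
         call. = FALSE)

  body_temp <- ifelse(tp < config$tp_cutoff, config$body_temperature_cold,
                      config$body_temperature_warm)
  samples <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    species = ifelse(tp < config$tp_cutoff, "invertebrate", "bird"),
    group = "sim", delta15N = NA_real_, trophic_position = tp,
    body_temperature_K = body_temp,
    phi_NL = phi[, "NL"], phi_PL = phi[, "PL"], phi_ALB = phi[, "ALB"],
    phi_SP = phi[, "SP"], phi_W = phi[, "W"], row.names = NULL)

  fits <- fit_qspr_table(config$chemicals)
  meas <- list(); truth <- list(); acts <- list()
  for (a in seq_len(nrow(config$analytes))) {
    an <- config$analytes$name[a]
    chem <- chem_get(config$chemicals, an)
    # per-sample activity per unit wet-weight concentration
    k <- numeric(n)
    for (i in seq_len(n)) {
      comp <- tissue_composition(phi[i, "NL"], phi[i, "PL"], phi[i, "ALB"],
                                 phi[i, "SP"], phi[i, "W"])
      k[i] <- apparent_activity(1, comp, chem, body_temp[i], fits = fits,
                                density = config$density,
                                entropy_ratio = config$entropy_ratio)$activity
    }
    ln_a <- log(config$analytes$baseline_activity[a]) +
      log(config$analytes$true_tmf[a]) * tp +
      stats::rnorm(n, 0, config$analytes$sigma[a])
    activity <- exp(ln_a)
    c_ww <- activity / k
    mloq <- config$analytes$mloq[a]
    if (is.na(mloq)) {
      mloq <- if (config$censoring_target > 0)
        stats::quantile(c_ww, config$censoring_target, names = FALSE)
      else min(c_ww) * 1e-3
    }
    cens <- c_ww < mloq
    meas[[a]] <- data.frame(
      sample_id = samples$sample_id, analyte = an,
      conc_ng_g_ww = ifelse(cens, mloq, c_ww),
      censored = as.integer(cens), mloq_ng_g_ww = mloq, row.names = NULL)
    truth[[a]] <- data.frame(
      analyte = an, true_tmf = config$analytes$true_tmf[a],
      baseline_activity = config$analytes$baseline_activity[a],
      sigma = config$analytes$sigma[a], mloq = mloq,
      realized_censoring = mean(cens), row.names = NULL)
    acts[[a]] <- data.frame(sample_id = samples$sample_id, analyte = an,
                            activity = activity, c_ww_true = c_ww,
                            row.names = NULL)
  }
  structure(
    list(samples = samples, measurements = do.call(rbind, meas),
         chemicals = config$chemicals, truth = do.call(rbind, truth),
         activities = do.call(rbind, acts), n_clipped = n_clipped,
         config = config),
    class = "synthetic_foodweb")
}

#' Parameter-recovery experiment
#'
#' Repeats generate-then-estimate `n_reps` times (seeds `seed + 1 ...
#' seed + n_reps`) and aggregates, per analyte and scheme, the mean TMF
#' estimate, the bias of the log TMF, its relative bias (NA when the true
#' log TMF is 0), and the 95% CI coverage of the true value.
#'
#' @param config A [synthetic_config()]; its `seed` (default 0 when `NULL`)
#'   anchors the replicate seeds.
#' @param n_reps Number of replicates (>= 2).
#' @param schemes Schemes to estimate under (default `"activity"`, the
#'   scale on which the generator's truth lives).
#' @param ... Passed to [compute_tmf()].
#' @return data.frame with columns `analyte`, `scheme`, `true_tmf`,
#'   `mean_tmf`, `mean_ln_tmf`, `bias_ln`, `rel_bias_ln`, `coverage`,
#'   `n_reps`.
#' @export
recovery_experiment <- function(config, n_reps, schemes = "activity", ...) {
  stopifnot(inherits(config, "synthetic_config"), n_reps >= 2)
  base_seed <- if (is.null(config$seed)) 0L else config$seed
  keys <- expand.grid(analyte = config$analytes$name, scheme = schemes,
                      stringsAsFactors = FALSE)
  est <- array(NA_real_, dim = c(n_reps, nrow(keys), 2),
               dimnames = list(NULL, NULL, c("slope", "se")))
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- base_seed + r
    fw <- generate_foodweb(cfg)
    for (j in seq_len(nrow(keys))) {
      fit <- compute_tmf(fw$samples, fw$measurements, fw$chemicals,
                         keys$analyte[j], keys$scheme[j], ...)
      est[r, j, "slope"] <- fit$slope
      est[r, j, "se"] <- fit$slope_se
    }
  }
  out <- keys
  out$true_tmf <- config$analytes$true_tmf[
    match(keys$analyte, config$analytes$name)]
  ln_true <- log(out$true_tmf)
  out$mean_tmf <- colMeans(exp(est[, , "slope", drop = FALSE]))[seq_len(nrow(keys))]
  out$mean_ln_tmf <- colMeans(est[, , "slope", drop = FALSE])[seq_len(nrow(keys))]
  out$bias_ln <- out$mean_ln_tmf - ln_true
  out$rel_bias_ln <- ifelse(ln_true != 0, out$bias_ln / ln_true, NA_real_)
  # tiny tolerance so the degenerate zero-noise CI (width 0 at the exact
  # slope) counts as covering its own truth despite rounding
  tol <- 1e-9 * pmax(1, abs(ln_true))
  cover <- vapply(seq_len(nrow(keys)), function(j)
    mean(est[, j, "slope"] - 1.96 * est[, j, "se"] - tol[j] <= ln_true[j] &
           ln_true[j] <= est[, j, "slope"] + 1.96 * est[, j, "se"] + tol[j]),
    numeric(1))
  out$coverage <- cover
  out$n_reps <- n_reps
  out
}
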