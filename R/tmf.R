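# Trophic magnification pipeline: trophic positions, the detection-
# frequency gate, per-analyte TMFs under each normalization scheme, and
# cross-scheme comparison.

#' Trophic position from nitrogen stable-isotope ratio
#'
#' \deqn{TP = TP_{base} + (\delta^{15}N - \delta^{15}N_{base}) / \Delta}
#' where \eqn{\Delta} is the per-trophic-level isotopic enrichment
#' (default 2.88 per mille, a food-web-specific value estimated elsewhere
#' and treated here as a configurable input).
#'
#' @param delta15N Measured delta-15-N, per mille. Vectorized.
#' @param baseline_delta15N Baseline delta-15-N, per mille.
#' @param baseline_tp Trophic position of the baseline organism (default 1).
#' @param enrichment Enrichment per trophic level, per mille (default 2.88).
#' @return Trophic position(s).
#' @export
trophic_position <- function(delta15N, baseline_delta15N, baseline_tp = 1,
                             enrichment = 2.88) {
  if (!is.numeric(enrichment) || enrichment <= 0)
    stop("enrichment must be positive", call. = FALSE)
  baseline_tp + (delta15N - baseline_delta15N) / enrichment
}

#' Detection-frequency gate for a TMF analysis
#'
#' A TMF is only computed for analytes detected (uncensored) in more than
#' `threshold` of all biota samples; the inequality is strict, so exactly
#' 60% detection with the default threshold excludes the analyte.
#'
#' @param measurements Measurements data frame (columns `analyte`,
#'   `censored`; see [read_dataset()]).
#' @param analyte Analyte name.
#' @param threshold Detection-frequency threshold in (0, 1); default 0.60.
#' @return List with `include` (logical), `frequency`, `n_total`,
#'   `n_detected`.
#' @export
detection_filter <- function(measurements, analyte, threshold = 0.60) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  rows <- measurements[measurements$analyte == analyte, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("unknown analyte: no measurements for ", analyte, call. = FALSE)
  n_total <- nrow(rows)
  n_detected <- sum(!as.logical(rows$censored))
  freq <- n_detected / n_total
  list(include = freq > threshold, frequency = freq,
       n_total = n_total, n_detected = n_detected)
}

# Trophic positions for a samples table. Explicit trophic_position column
# takes precedence over delta15N-derived values; mixing is allowed but
# reported via the "mixed_tp_source" attribute.
sample_tp <- function(samples, baseline_delta15N = 0, baseline_tp = 1,
                      enrichment = 2.88) {
  tp <- rep(NA_real_, nrow(samples))
  has_tp <- "trophic_position" %in% names(samples) &
    !is.na(samples$trophic_position)
  if (any(has_tp)) tp[has_tp] <- samples$trophic_position[has_tp]
  need <- is.na(tp)
  if (any(need)) {
    if (!"delta15N" %in% names(samples) || anyNA(samples$delta15N[need]))
      stop("samples lack both trophic_position and delta15N", call. = FALSE)
    tp[need] <- trophic_position(samples$delta15N[need], baseline_delta15N,
                                 baseline_tp, enrichment)
  }
  attr(tp, "mixed_tp_source") <- any(has_tp) && any(need)
  tp
}

#' Transform measurements of one analyte onto a scheme's scale
#'
#' Applies the per-sample transformation of the chosen scheme to each
#' measured value *and its quantification limit* (the same positive
#' per-sample constant multiplies both, so censoring thresholds stay
#' consistent across samples). Samples whose composition makes the scheme's
#' fraction zero are dropped with a warning and counted.
#'
#' @param samples,measurements Data frames in the package schemas.
#' @param chems A `chem_table` or list of `chem_record` objects.
#' @param analyte Analyte name.
#' @param scheme One of [tmf_schemes].
#' @param fits Optional QSPR fits; computed from `chems` when `NULL`.
#' @param density Tissue density, g/cm^3 (activity scheme only).
#' @param entropy_ratio Entropy-of-fusion ratio for [fugacity_ratio()].
#' @param baseline_delta15N,baseline_tp,enrichment Trophic-position
#'   parameters for samples carrying only delta15N.
#' @return data.frame with columns `sample_id`, `tp`, `value`, `limit`,
#'   `censored`; attribute `n_excluded` counts dropped samples.
#' @export
transform_measurements <- function(samples, measurements, chems, analyte,
                                   scheme, fits = NULL, density = 1,
                                   entropy_ratio = 6.79,
                                   baseline_delta15N = 0, baseline_tp = 1,
                                   enrichment = 2.88) {
  scheme <- match.arg(scheme, tmf_schemes)
  records <- as_chem_list(chems)
  if (scheme == "activity" && is.null(fits)) fits <- fit_qspr_table(records)
  chem <- if (scheme == "activity") chem_get(records, analyte) else NULL
  tp <- sample_tp(samples, baseline_delta15N, baseline_tp, enrichment)
  rows <- measurements[measurements$analyte == analyte, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("unknown analyte: no measurements for ", analyte, call. = FALSE)
  idx <- match(rows$sample_id, samples$sample_id)
  if (anyNA(idx))
    stop("measurements reference unknown sample_id: ",
         paste(unique(rows$sample_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  n_excluded <- 0L
  out <- vector("list", nrow(rows))
  for (k in seq_len(nrow(rows))) {
    srow <- samples[idx[k], ]
    comp <- sample_composition(srow)
    cens <- as.logical(rows$censored[k])
    vals <- c(rows$conc_ng_g_ww[k], rows$mloq_ng_g_ww[k])
    tv <- if (scheme == "activity") {
      apparent_activity(vals, comp, chem, srow$body_temperature_K,
                        fits = fits, density = density,
                        entropy_ratio = entropy_ratio)$activity
    } else {
      suppressWarnings(normalize_concentration(vals, comp, scheme))
    }
    if (anyNA(tv)) {
      n_excluded <- n_excluded + 1L
      warning(sprintf(
        "sample %s excluded under scheme '%s' (zero tissue fraction)",
        rows$sample_id[k], scheme), call. = FALSE)
      next
    }
    out[[k]] <- data.frame(sample_id = rows$sample_id[k], tp = tp[idx[k]],
                           value = tv[1], limit = tv[2], censored = cens,
                           row.names = NULL)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(sample_id = character(), tp = numeric(),
                      value = numeric(), limit = numeric(),
                      censored = logical())
  attr(res, "n_excluded") <- n_excluded
  res
}

#' Trophic magnification factor of one analyte under one scheme
#'
#' Transforms the analyte's measurements (and quantification limits) onto
#' the scheme's scale, takes natural logs, and fits a left-censored Gaussian
#' regression of log value on trophic position ([censored_linregress()]).
#' The TMF is \eqn{e^m} for slope \eqn{m}, with a Wald 95% CI
#' \eqn{(e^{m - 1.96\,se}, e^{m + 1.96\,se})}.
#'
#' @inheritParams transform_measurements
#' @param threshold Detection-frequency gate (strict `>`); default 0.60.
#' @param enforce_detection If `TRUE` (default) an analyte failing the gate
#'   raises an error; set `FALSE` for diagnostics such as sensitivity sweeps
#'   on already-gated analytes.
#' @param test `"wald"` or `"lrt"` slope test.
#' @return Object of class `tmf_result`: `analyte`, `scheme`, `slope`,
#'   `slope_se`, `tmf`, `ci95`, `p_value`, `n_total`, `n_censored`,
#'   `n_excluded`, `detection_frequency`.
#' @export
compute_tmf <- function(samples, measurements, chems, analyte,
                        scheme = "activity", threshold = 0.60,
                        fits = NULL, density = 1, entropy_ratio = 6.79,
                        baseline_delta15N = 0, baseline_tp = 1,
                        enrichment = 2.88, enforce_detection = TRUE,
                        test = "wald") {
  scheme <- match.arg(scheme, tmf_schemes)
  gate <- detection_filter(measurements, analyte, threshold)
  if (enforce_detection && !gate$include)
    stop(sprintf(
      "analyte %s fails the detection-frequency gate: %.1f%% <= %.0f%%",
      analyte, 100 * gate$frequency, 100 * threshold), call. = FALSE)
  tr <- transform_measurements(samples, measurements, chems, analyte, scheme,
                               fits = fits, density = density,
                               entropy_ratio = entropy_ratio,
                               baseline_delta15N = baseline_delta15N,
                               baseline_tp = baseline_tp,
                               enrichment = enrichment)
  if (nrow(tr) < 3L)
    stop(sprintf(
      "insufficient data for %s under scheme '%s': %d usable samples",
      analyte, scheme, nrow(tr)), call. = FALSE)
  fit <- censored_linregress(log(tr$value), tr$tp, tr$censored, test = test)
  m <- fit$slope; se <- fit$slope_se
  structure(
    list(analyte = analyte, scheme = scheme, slope = m, slope_se = se,
         tmf = exp(m),
         ci95 = c(exp(m - 1.96 * se), exp(m + 1.96 * se)),
         p_value = fit$p_value, sigma = fit$sigma,
         n_total = fit$n_total, n_censored = fit$n_censored,
         n_excluded = attr(tr, "n_excluded"),
         detection_frequency = gate$frequency),
    class = "tmf_result")
}

#' @export
print.tmf_result <- function(x, ...) {
  cat(sprintf(
    "<tmf_result> %s [%s]: TMF = %.3g (95%% CI %.3g-%.3g), p = %.3g\n",
    x$analyte, x$scheme, x$tmf, x$ci95[1], x$ci95[2], x$p_value))
  cat(sprintf("  slope = %.4g (se %.3g), n = %d (%d censored, %d excluded), detection %.0f%%\n",
              x$slope, x$slope_se, x$n_total, x$n_censored, x$n_excluded,
              100 * x$detection_frequency))
  invisible(x)
}

#' TMFs for many analytes and schemes
#'
#' Runs [compute_tmf()] for each analyte passing the detection gate under
#' each requested scheme and binds the results into one table. Gated-out
#' analytes are recorded in the `excluded_analytes` attribute.
#'
#' @inheritParams compute_tmf
#' @param analytes Analyte names; default every analyte present in
#'   `measurements`.
#' @param schemes Subset of [tmf_schemes]; default all six.
#' @return data.frame, one row per analyte x scheme, with the `tmf_result`
#'   fields flattened (`ci_lo`, `ci_hi`).
#' @export
compute_tmf_all <- function(samples, measurements, chems, analytes = NULL,
                            schemes = tmf_schemes, threshold = 0.60, ...) {
  if (is.null(analytes)) analytes <- unique(measurements$analyte)
  schemes <- match.arg(schemes, tmf_schemes, several.ok = TRUE)
  rows <- list(); excluded <- character()
  for (an in analytes) {
    gate <- detection_filter(measurements, an, threshold)
    if (!gate$include) { excluded <- c(excluded, an); next }
    for (sc in schemes) {
      r <- compute_tmf(samples, measurements, chems, an, sc,
                       threshold = threshold, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = r$analyte, scheme = r$scheme, slope = r$slope,
        slope_se = r$slope_se, tmf = r$tmf, ci_lo = r$ci95[1],
        ci_hi = r$ci95[2], p_value = r$p_value, n_total = r$n_total,
        n_censored = r$n_censored, n_excluded = r$n_excluded,
        detection_frequency = r$detection_frequency, row.names = NULL)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(analyte = character(), scheme = character())
  attr(res, "excluded_analytes") <- excluded
  res
}

#' Pairwise 95% CI overlap between TMF estimates
#'
#' Two TMFs are flagged as not statistically distinguishable when their 95%
#' confidence intervals overlap; the ratio matrix gives the multiplicative
#' difference between point estimates.
#'
#' @param results List of `tmf_result` objects, or a data.frame from
#'   [compute_tmf_all()] (needs columns `tmf`, `ci_lo`, `ci_hi`).
#' @return List with `overlap` (logical matrix) and `ratio` (numeric matrix
#'   of `tmf_i / tmf_j`), dimnames `analyte.scheme` labels when available.
#' @export
compare_tmfs <- function(results) {
  if (is.data.frame(results)) {
    tmf <- results$tmf; lo <- results$ci_lo; hi <- results$ci_hi
    labels <- paste(results$analyte, results$scheme, sep = ".")
  } else {
    tmf <- vapply(results, `[[`, numeric(1), "tmf")
    lo <- vapply(results, function(r) r$ci95[1], numeric(1))
    hi <- vapply(results, function(r) r$ci95[2], numeric(1))
    labels <- vapply(results, function(r)
      paste(r$analyte, r$scheme, sep = "."), character(1))
  }
  k <- length(tmf)
  if (k < 2L) stop("compare_tmfs needs at least 2 results", call. = FALSE)
  overlap <- outer(seq_len(k), seq_len(k),
                   Vectorize(function(i, j) lo[i] <= hi[j] && lo[j] <= hi[i]))
  ratio <- outer(tmf, tmf, `/`)
  dimnames(overlap) <- dimnames(ratio) <- list(labels, labels)
  list(overlap = overlap, ratio = ratio)
}
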