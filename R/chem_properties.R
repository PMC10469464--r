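# Chemical property registry and QSPR prediction of phase-water
# distribution coefficients from molar volume.

#' Tissue phases with phase-water distribution coefficients
#'
#' The four sorbing tissue phases whose affinity for a chemical is expressed
#' as a log10 distribution coefficient relative to water: neutral (storage)
#' lipid, polar (membrane) lipid, albumin, and structural protein. Water
#' itself has unit relative capacity and carries no coefficient.
#'
#' @format Character vector of phase codes: `"NLW"`, `"PLW"`, `"ALBW"`, `"SPW"`.
#' @export
logd_phases <- c("NLW", "PLW", "ALBW", "SPW")

#' Create a chemical record
#'
#' A chemical record holds the identity and physicochemical properties of one
#' perfluoroalkyl acid: homologue class (carboxylic `PFCA` or sulfonic
#' `PFSA`), chain length, molar mass, molar volume, melting point, water
#' solubility, and log10 phase-water distribution coefficients (`logD`) for
#' the phases in [logd_phases]. Each `logD` value is tagged with its
#' provenance (`"measured"` or `"predicted"`); missing coefficients can be
#' filled by [predict_logd()] from a QSPR fit.
#'
#' @param name Analyte name (e.g. `"PFOS"`).
#' @param analyte_class `"PFCA"` or `"PFSA"`; selects which QSPR fit applies.
#' @param chain_length Integer number of carbons.
#' @param molar_mass Molar mass, g/mol.
#' @param molar_volume Molar volume, cm^3/mol. Must be positive.
#' @param melting_point Melting point, K. Must be positive.
#' @param water_solubility Water solubility S_W, mol/m^3, at the reference
#'   temperature `sw_temperature`. Must be positive.
#' @param logd Named numeric vector of log10 distribution coefficients;
#'   names must be a subset of [logd_phases]. May be empty.
#' @param logd_source Named character vector of provenance tags parallel to
#'   `logd`; defaults to `"measured"` for every supplied value.
#' @param sw_temperature Temperature (K) at which `water_solubility` was
#'   determined; metadata only, no correction is applied.
#' @return An object of class `chem_record`.
#' @examples
#' chemical_record("PFOS", "PFSA", 8, 500.13, 331, 440, 1.2,
#'                 logd = c(ALBW = 4.5, PLW = 3.9, SPW = 2.4, NLW = 0.1))
#' @export
chemical_record <- function(name, analyte_class, chain_length, molar_mass,
                            molar_volume, melting_point, water_solubility,
                            logd = numeric(), logd_source = NULL,
                            sw_temperature = 298.15) {
  analyte_class <- match.arg(analyte_class, c("PFCA", "PFSA"))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(molar_volume) || molar_volume <= 0)
    stop("molar_volume must be positive for ", name, call. = FALSE)
  if (!is.numeric(melting_point) || melting_point <= 0)
    stop("melting_point must be positive for ", name, call. = FALSE)
  if (!is.numeric(water_solubility) || water_solubility <= 0)
    stop("water_solubility must be positive for ", name, call. = FALSE)
  logd <- logd[!is.na(logd)]
  if (length(logd)) {
    if (is.null(names(logd)) || !all(names(logd) %in% logd_phases))
      stop("logd must be named with phases among: ",
           paste(logd_phases, collapse = ", "), call. = FALSE)
  }
  if (is.null(logd_source)) {
    logd_source <- rep("measured", length(logd))
    names(logd_source) <- names(logd)
  } else {
    logd_source <- logd_source[names(logd)]
    logd_source[is.na(logd_source) | !nzchar(logd_source)] <- "measured"
    names(logd_source) <- names(logd)
  }
  structure(
    list(name = name, analyte_class = analyte_class,
         chain_length = as.integer(chain_length),
         molar_mass = as.numeric(molar_mass),
         molar_volume = as.numeric(molar_volume),
         melting_point = as.numeric(melting_point),
         water_solubility = as.numeric(water_solubility),
         logd = logd, logd_source = logd_source,
         sw_temperature = sw_temperature),
    class = "chem_record")
}

#' @export
print.chem_record <- function(x, ...) {
  cat(sprintf("<chem_record> %s (%s, C%d)\n", x$name, x$analyte_class,
              x$chain_length))
  cat(sprintf("  M = %.2f g/mol, Vm = %.1f cm^3/mol, Tm = %.1f K, S_W = %.3g mol/m^3\n",
              x$molar_mass, x$molar_volume, x$melting_point,
              x$water_solubility))
  for (p in names(x$logd))
    cat(sprintf("  logD_%s = %.3f (%s)\n", p, x$logd[[p]], x$logd_source[[p]]))
  invisible(x)
}

#' Fit a QSPR line of logD on molar volume
#'
#' Ordinary least-squares regression of log10 phase-water distribution
#' coefficients on molar volume, fit separately per analyte class
#' (carboxylic vs sulfonic homologues partition differently) and per tissue
#' phase. The fitted line fills in coefficients for homologues lacking
#' measurements; see [predict_logd()].
#'
#' @param molar_volume Numeric vector of molar volumes (cm^3/mol) of the
#'   measured chemicals. At least two distinct values.
#' @param logd Numeric vector of measured log10 distribution coefficients,
#'   same length.
#' @param analyte_class `"PFCA"` or `"PFSA"`.
#' @param phase One of [logd_phases].
#' @return An object of class `qspr_fit` with components `slope` (per
#'   cm^3/mol), `intercept` (log10 units), `n_points`, `residual_sd`
#'   (log10 units, n-2 degrees of freedom; 0 when n = 2), and `mv_range`.
#' @export
fit_logd_qspr <- function(molar_volume, logd, analyte_class, phase) {
  analyte_class <- match.arg(analyte_class, c("PFCA", "PFSA"))
  phase <- match.arg(phase, logd_phases)
  ok <- is.finite(molar_volume) & is.finite(logd)
  x <- molar_volume[ok]; y <- logd[ok]
  n <- length(x)
  if (n < 2L || length(unique(x)) < 2L)
    stop(sprintf(
      "cannot fit QSPR for %s/%s: need >= 2 points with distinct molar volumes (got %d)",
      analyte_class, phase, n), call. = FALSE)
  xbar <- mean(x); ybar <- mean(y)
  ssx <- sum((x - xbar)^2)
  slope <- sum((x - xbar) * (y - ybar)) / ssx
  intercept <- ybar - slope * xbar
  resid <- y - (intercept + slope * x)
  residual_sd <- if (n > 2L) sqrt(sum(resid^2) / (n - 2L)) else 0
  structure(
    list(analyte_class = analyte_class, phase = phase,
         slope = slope, intercept = intercept, n_points = n,
         residual_sd = residual_sd, mv_range = range(x)),
    class = "qspr_fit")
}

#' @export
print.qspr_fit <- function(x, ...) {
  cat(sprintf(
    "<qspr_fit> %s/%s: logD = %.4g + %.4g * Vm  (n = %d, resid sd = %.3g, Vm %g-%g)\n",
    x$analyte_class, x$phase, x$intercept, x$slope, x$n_points,
    x$residual_sd, x$mv_range[1], x$mv_range[2]))
  invisible(x)
}

#' Fit QSPR lines for every class/phase with measured coefficients
#'
#' Collects the measured `logD` entries of a chemical table and fits one
#' [fit_logd_qspr()] line per (analyte class, phase) combination that has at
#' least two measured points with distinct molar volumes. Combinations
#' without enough data are silently absent from the result;
#' [predict_logd()] raises a missing-property error if asked for them.
#'
#' @param chems A `chem_table` (see [read_chemicals()]) or list of
#'   `chem_record` objects.
#' @return Named list of `qspr_fit` objects keyed `"<class>.<phase>"`.
#' @export
fit_qspr_table <- function(chems) {
  records <- as_chem_list(chems)
  fits <- list()
  for (cls in c("PFCA", "PFSA")) {
    for (ph in logd_phases) {
      mv <- numeric(); ld <- numeric()
      for (r in records) {
        if (r$analyte_class != cls) next
        if (!ph %in% names(r$logd)) next
        # experimental values carry free-form provenance labels; only
        # model-derived tags are excluded from the fit
        if (unname(r$logd_source[[ph]]) %in% c("predicted", "sensitivity")) next
        mv <- c(mv, r$molar_volume); ld <- c(ld, r$logd[[ph]])
      }
      if (length(mv) >= 2L && length(unique(mv)) >= 2L)
        fits[[paste(cls, ph, sep = ".")]] <-
          fit_logd_qspr(mv, ld, cls, ph)
    }
  }
  fits
}

#' Resolve a chemical's logD for one phase, predicting if needed
#'
#' Measured values always take precedence and are returned untouched.
#' Otherwise the QSPR line for the chemical's class and the requested phase
#' is evaluated at the chemical's molar volume and the value is tagged
#' `"predicted"`. A warning is raised when the molar volume lies outside the
#' range the line was fitted on (extrapolation is allowed, as long-chain
#' homologues typically lack measurements, but flagged).
#'
#' @param chem A `chem_record`.
#' @param fits Named list of `qspr_fit` objects from [fit_qspr_table()].
#' @param phase One of [logd_phases].
#' @return Numeric logD value with attribute `source` (`"measured"` or
#'   `"predicted"`).
#' @export
predict_logd <- function(chem, fits, phase) {
  phase <- match.arg(phase, logd_phases)
  if (phase %in% names(chem$logd)) {
    v <- unname(chem$logd[[phase]])
    attr(v, "source") <- unname(chem$logd_source[[phase]])
    return(v)
  }
  key <- paste(chem$analyte_class, phase, sep = ".")
  fit <- fits[[key]]
  if (is.null(fit))
    stop(sprintf(
      "missing property: no measured logD_%s for %s and no QSPR fit for %s/%s",
      phase, chem$name, chem$analyte_class, phase), call. = FALSE)
  if (chem$molar_volume < fit$mv_range[1] || chem$molar_volume > fit$mv_range[2])
    warning(sprintf(
      "logD_%s for %s predicted by extrapolation: Vm = %g outside fitted range [%g, %g]",
      phase, chem$name, chem$molar_volume, fit$mv_range[1], fit$mv_range[2]),
      call. = FALSE)
  v <- fit$intercept + fit$slope * chem$molar_volume
  attr(v, "source") <- "predicted"
  v
}

#' Resolve all four phase-water logD values of a chemical
#'
#' @param chem A `chem_record`.
#' @param fits Named list of `qspr_fit` objects; may be `NULL` if all four
#'   values are measured.
#' @return Named numeric vector over [logd_phases] with attribute `source`,
#'   a parallel character vector of provenance tags.
#' @export
resolve_logd <- function(chem, fits = NULL) {
  vals <- numeric(length(logd_phases))
  src <- character(length(logd_phases))
  names(vals) <- names(src) <- logd_phases
  for (ph in logd_phases) {
    v <- predict_logd(chem, fits, ph)
    vals[[ph]] <- as.numeric(v)
    src[[ph]] <- attr(v, "source")
  }
  attr(vals, "source") <- src
  vals
}

as_chem_list <- function(chems) {
  if (inherits(chems, "chem_table")) return(chems$records)
  if (inherits(chems, "chem_record")) return(stats::setNames(list(chems), chems$name))
  if (is.list(chems)) {
    stopifnot(all(vapply(chems, inherits, logical(1), "chem_record")))
    nm <- vapply(chems, `[[`, character(1), "name")
    return(stats::setNames(chems, nm))
  }
  stop("expected a chem_table, chem_record, or list of chem_record objects",
       call. = FALSE)
}

#' Look up one chemical in a chemical table
#'
#' @param chems A `chem_table` or list of `chem_record` objects.
#' @param name Analyte name.
#' @return The matching `chem_record`.
#' @export
chem_get <- function(chems, name) {
  records <- as_chem_list(chems)
  if (!name %in% names(records))
    stop("unknown analyte: ", name, call. = FALSE)
  records[[name]]
}
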