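# Sorptive capacity of a tissue mixture and the distribution of chemical
# mass among the five tissue phases.

#' Create a tissue composition
#'
#' Mass fractions (g/g wet sample) of the five tissue phases the
#' partitioning model resolves: neutral (storage) lipid, polar (membrane)
#' lipid, albumin, structural protein, and water. The fractions may sum to
#' less than 1; residual mass (carbohydrate, ash) is ignored by the model,
#' never lumped into water.
#'
#' @param phi_NL,phi_PL,phi_ALB,phi_SP,phi_W Mass fractions in \[0, 1\].
#' @return Object of class `tissue_composition`: a named numeric vector with
#'   components `NL`, `PL`, `ALB`, `SP`, `W`.
#' @examples
#' avian <- tissue_composition(phi_NL = 0.04, phi_PL = 0.01,
#'                             phi_ALB = 0.039, phi_SP = 0.021, phi_W = 0.75)
#' phi_total_protein(avian)  # 0.06
#' @export
tissue_composition <- function(phi_NL = 0, phi_PL = 0, phi_ALB = 0,
                               phi_SP = 0, phi_W = 0) {
  phi <- c(NL = as.numeric(phi_NL), PL = as.numeric(phi_PL),
           ALB = as.numeric(phi_ALB), SP = as.numeric(phi_SP),
           W = as.numeric(phi_W))
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > 1))
    stop("tissue fractions must lie in [0, 1]", call. = FALSE)
  if (sum(phi) > 1 + 1e-9)
    stop(sprintf("tissue fractions sum to %.4f > 1", sum(phi)), call. = FALSE)
  structure(phi, class = "tissue_composition")
}

#' @rdname tissue_composition
#' @param comp A `tissue_composition`.
#' @export
phi_total_protein <- function(comp) unname(comp[["ALB"]] + comp[["SP"]])

#' @rdname tissue_composition
#' @export
phi_total_lipid <- function(comp) unname(comp[["NL"]] + comp[["PL"]])

#' Sorptive capacity of a tissue mixture for a chemical
#'
#' The capacity of a composite tissue for a chemical, relative to the
#' chemical's water solubility:
#' \deqn{\phi_{NL} D_{NLW} + \phi_{PL} D_{PLW} + \phi_{ALB} D_{ALBW} +
#'       \phi_{SP} D_{SPW} + \phi_W}
#' where each \eqn{D = 10^{\log D}} is the phase-water distribution
#' coefficient. Pure water has unit capacity. The capacity converts a bulk
#' concentration to an effective dissolved-phase saturation level and is the
#' denominator of the apparent chemical activity.
#'
#' @param comp A [tissue_composition()].
#' @param chem A [chemical_record()].
#' @param fits Optional QSPR fits from [fit_qspr_table()] to resolve missing
#'   logD values.
#' @return Positive dimensionless capacity.
#' @export
sorptive_capacity <- function(comp, chem, fits = NULL) {
  ld <- resolve_logd(chem, fits)
  unname(comp[["NL"]] * 10^ld[["NLW"]] + comp[["PL"]] * 10^ld[["PLW"]] +
         comp[["ALB"]] * 10^ld[["ALBW"]] + comp[["SP"]] * 10^ld[["SPW"]] +
         comp[["W"]])
}

#' Distribution of chemical mass among tissue phases
#'
#' The fraction of the total chemical mass in a sample residing in each
#' phase at equilibrium: \eqn{\phi_i D_i / \sum_j \phi_j D_j} with
#' \eqn{D_W \equiv 1}. Fractions sum to 1 exactly.
#'
#' @inheritParams sorptive_capacity
#' @return Object of class `mass_distribution`: named numeric vector over
#'   phases `NL`, `PL`, `ALB`, `SP`, `W`, summing to 1.
#' @export
mass_distribution <- function(comp, chem, fits = NULL) {
  ld <- resolve_logd(chem, fits)
  v <- c(NL = comp[["NL"]] * 10^ld[["NLW"]],
         PL = comp[["PL"]] * 10^ld[["PLW"]],
         ALB = comp[["ALB"]] * 10^ld[["ALBW"]],
         SP = comp[["SP"]] * 10^ld[["SPW"]],
         W = comp[["W"]])
  cap <- sum(v)
  if (cap <= 0)
    stop("degenerate composition: all phase fractions zero, capacity is 0",
         call. = FALSE)
  structure(v / cap, class = "mass_distribution")
}

#' Mass distribution of several analytes across samples, long format
#'
#' Convenience wrapper producing the long table (sample_id, analyte, phase,
#' fraction) used for stacked-area composition plots.
#'
#' @param samples Samples data frame (see [read_dataset()] schema).
#' @param chems A `chem_table` or list of `chem_record` objects.
#' @param analytes Analyte names; default all in `chems`.
#' @param fits Optional QSPR fits; computed from `chems` when `NULL`.
#' @return data.frame with columns `sample_id`, `analyte`, `phase`,
#'   `fraction`.
#' @export
mass_distribution_table <- function(samples, chems, analytes = NULL,
                                    fits = NULL) {
  records <- as_chem_list(chems)
  if (is.null(analytes)) analytes <- names(records)
  if (is.null(fits)) fits <- fit_qspr_table(chems)
  out <- vector("list", nrow(samples) * length(analytes))
  k <- 0L
  for (i in seq_len(nrow(samples))) {
    comp <- sample_composition(samples[i, ])
    for (an in analytes) {
      md <- mass_distribution(comp, chem_get(records, an), fits)
      k <- k + 1L
      out[[k]] <- data.frame(sample_id = samples$sample_id[i], analyte = an,
                             phase = names(md), fraction = as.numeric(md),
                             row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Sensitivity of a TMF to one phase-water distribution coefficient
#'
#' Substitutes each candidate logD value for the named analyte and phase
#' into the chemical table (globally, for all samples), recomputes the
#' activity-based TMF, and reports the percent change against the reference
#' value together with 95% CI overlap. Literature sources can disagree by
#' nearly an order of magnitude on the albumin-water coefficient of some
#' homologues; this quantifies how much that uncertainty propagates into the
#' biomagnification conclusion.
#'
#' @param samples,measurements Data frames in the package schemas.
#' @param chems A `chem_table` or list of `chem_record` objects.
#' @param analyte Analyte name; must pass the detection-frequency gate.
#' @param phase One of [logd_phases].
#' @param logd_values Numeric vector of substituted logD values.
#' @param reference_logd Reference logD; default the value currently
#'   resolved from the table (measured or predicted).
#' @param ... Passed to [compute_tmf()] (e.g. `threshold`, `density`).
#' @return data.frame with one row per logD value (reference first):
#'   `logd`, `tmf`, `ci_lo`, `ci_hi`, `pct_change`, `overlaps_reference`.
#' @export
logd_sensitivity <- function(samples, measurements, chems, analyte, phase,
                             logd_values, reference_logd = NULL, ...) {
  phase <- match.arg(phase, logd_phases)
  records <- as_chem_list(chems)
  chem <- chem_get(records, analyte)
  if (is.null(reference_logd)) {
    fits <- fit_qspr_table(records)
    reference_logd <- as.numeric(predict_logd(chem, fits, phase))
  }
  run_one <- function(ld) {
    mod <- records
    r <- mod[[analyte]]
    r$logd[[phase]] <- ld
    r$logd_source[[phase]] <- "sensitivity"
    mod[[analyte]] <- r
    compute_tmf(samples, measurements, mod, analyte, scheme = "activity", ...)
  }
  all_ld <- c(reference_logd, setdiff(logd_values, reference_logd))
  res <- lapply(all_ld, run_one)
  ref <- res[[1L]]
  data.frame(
    logd = all_ld,
    tmf = vapply(res, `[[`, numeric(1), "tmf"),
    ci_lo = vapply(res, function(r) r$ci95[1], numeric(1)),
    ci_hi = vapply(res, function(r) r$ci95[2], numeric(1)),
    pct_change = vapply(res, function(r) 100 * (r$tmf - ref$tmf) / ref$tmf,
                        numeric(1)),
    overlaps_reference = vapply(res, function(r)
      r$ci95[1] <= ref$ci95[2] && ref$ci95[1] <= r$ci95[2], logical(1)),
    row.names = NULL)
}

# Build a tissue_composition from one row of a samples data frame.
sample_composition <- function(row) {
  tissue_composition(phi_NL = row$phi_NL, phi_PL = row$phi_PL,
                     phi_ALB = row$phi_ALB, phi_SP = row$phi_SP,
                     phi_W = row$phi_W)
}
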