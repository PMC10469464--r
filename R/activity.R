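# Fugacity-ratio correction, apparent chemical activity, the concentration
# normalization schemes, and the pairwise biomagnification factor.

#' Concentration normalization schemes
#'
#' The six axes on which concentrations can be placed before regression
#' against trophic position: apparent chemical activity plus five
#' concentration normalizations (wet weight, total protein equivalent,
#' albumin equivalent, polar lipid equivalent, total lipid equivalent).
#'
#' @format Character vector of scheme codes.
#' @export
tmf_schemes <- c("activity", "total_protein", "albumin", "total_lipid",
                 "polar_lipid", "wet")

#' Fugacity ratio of a solid chemical at body temperature
#'
#' Correction factor treating a chemical that is solid at body temperature
#' as a sub-cooled liquid: \eqn{F = \exp(-\Delta S_{fus}/R \cdot (T_m/T - 1))}
#' for \eqn{T_m > T}, and \eqn{F = 1} otherwise. The entropy-of-fusion term
#' defaults to Walden's rule, \eqn{\Delta S_{fus}/R = 6.79}.
#'
#' @param melting_point Melting point(s) \eqn{T_m}, K.
#' @param body_temperature Body temperature(s) \eqn{T}, K.
#' @param entropy_ratio \eqn{\Delta S_{fus}/R}, dimensionless; default 6.79.
#' @return Fugacity ratio(s) in (0, 1]. Vectorized with recycling.
#' @examples
#' fugacity_ratio(373, 298)           # solid at 25 C
#' fugacity_ratio(290, 313)           # liquid at avian body temperature -> 1
#' @export
fugacity_ratio <- function(melting_point, body_temperature,
                           entropy_ratio = 6.79) {
  if (any(!is.finite(melting_point)) || any(melting_point <= 0))
    stop("melting_point must be positive", call. = FALSE)
  if (any(!is.finite(body_temperature)) || any(body_temperature <= 0))
    stop("body_temperature must be positive", call. = FALSE)
  ifelse(melting_point <= body_temperature, 1,
         exp(-entropy_ratio * (melting_point / body_temperature - 1)))
}

#' Convert a wet-weight concentration to a molar volumetric concentration
#'
#' ng/g wet weight to mol/m^3 assuming a tissue density (default 1 g/cm^3).
#'
#' @param c_ww Concentration, ng/g wet weight.
#' @param molar_mass Molar mass, g/mol.
#' @param density Tissue density, g/cm^3.
#' @return Concentration, mol/m^3.
#' @export
molar_concentration <- function(c_ww, molar_mass, density = 1) {
  c_ww * 1e-3 * density / molar_mass
}

#' Apparent chemical activity of a chemical in a biota sample
#'
#' Converts a wet-weight concentration to an apparent chemical activity
#' \deqn{a = F \cdot C / (S_W \cdot \mathrm{capacity})}
#' where \eqn{C} is the molar volumetric concentration
#' ([molar_concentration()]), \eqn{S_W} the water solubility, the capacity
#' is [sorptive_capacity()], and \eqn{F} the [fugacity_ratio()] at the
#' organism's body temperature. "Apparent" because \eqn{S_W} is used at its
#' measurement temperature and the distribution coefficients at theirs; no
#' temperature correction of either is attempted.
#'
#' Activity is linear in `c_ww`, so a quantification limit transformed by
#' the same call remains a consistent censoring threshold.
#'
#' @param c_ww Concentration(s), ng/g wet weight; may be a vector (e.g.
#'   value and quantification limit).
#' @param comp A [tissue_composition()].
#' @param chem A [chemical_record()].
#' @param body_temperature Body temperature, K.
#' @param fits Optional QSPR fits for missing logD values.
#' @param density Tissue density, g/cm^3 (default 1).
#' @param entropy_ratio Passed to [fugacity_ratio()].
#' @return Object of class `activity_result`: list with `activity` (same
#'   length as `c_ww`), `fugacity_ratio`, `capacity`, `body_temperature`.
#' @export
apparent_activity <- function(c_ww, comp, chem, body_temperature,
                              fits = NULL, density = 1,
                              entropy_ratio = 6.79) {
  if (any(c_ww < 0)) stop("c_ww must be non-negative", call. = FALSE)
  cap <- sorptive_capacity(comp, chem, fits)
  if (cap <= 0) stop("sorptive capacity must be positive", call. = FALSE)
  if (chem$water_solubility <= 0)
    stop("water_solubility must be positive", call. = FALSE)
  f <- fugacity_ratio(chem$melting_point, body_temperature, entropy_ratio)
  cm <- molar_concentration(c_ww, chem$molar_mass, density)
  structure(
    list(activity = f * cm / (chem$water_solubility * cap),
         fugacity_ratio = f, capacity = cap,
         body_temperature = body_temperature),
    class = "activity_result")
}

#' Normalize a wet-weight concentration to a tissue fraction
#'
#' `wet` returns the concentration unchanged; every other scheme divides by
#' the corresponding mass fraction (total protein = albumin + structural
#' protein; total lipid = neutral + polar lipid). A zero fraction makes the
#' sample non-normalizable under that scheme: the function warns and returns
#' `NA`, and pipeline callers drop the sample.
#'
#' @param c_ww Concentration(s), ng/g wet weight.
#' @param comp A [tissue_composition()].
#' @param scheme One of `"wet"`, `"total_protein"`, `"albumin"`,
#'   `"polar_lipid"`, `"total_lipid"`.
#' @return Normalized concentration(s), or `NA` with a warning when the
#'   scheme's fraction is zero.
#' @export
normalize_concentration <- function(c_ww, comp, scheme) {
  scheme <- match.arg(scheme, c("wet", "total_protein", "albumin",
                                "polar_lipid", "total_lipid"))
  if (any(c_ww < 0)) stop("c_ww must be non-negative", call. = FALSE)
  phi <- switch(scheme,
                wet = 1,
                total_protein = phi_total_protein(comp),
                albumin = unname(comp[["ALB"]]),
                polar_lipid = unname(comp[["PL"]]),
                total_lipid = phi_total_lipid(comp))
  if (scheme != "wet" && phi <= 0) {
    warning(sprintf("sample non-normalizable under scheme '%s': fraction is 0",
                    scheme), call. = FALSE)
    return(rep(NA_real_, length(c_ww)))
  }
  c_ww / phi
}

#' Pairwise biomagnification factor
#'
#' Unitless predator/prey ratio of activities or same-scheme normalized
#' concentrations. BMF > 1 indicates biomagnification, < 1 biodilution.
#'
#' @param value_predator,value_prey Positive values on the same scheme.
#' @param scheme Scheme label recorded in the result.
#' @return Object of class `bmf_result` with `bmf` and `scheme`.
#' @export
compute_bmf <- function(value_predator, value_prey, scheme = "activity") {
  if (!is.finite(value_prey) || value_prey <= 0)
    stop("undefined biomagnification ratio: prey value must be positive",
         call. = FALSE)
  if (!is.finite(value_predator) || value_predator < 0)
    stop("predator value must be non-negative and finite", call. = FALSE)
  structure(list(bmf = value_predator / value_prey, scheme = scheme),
            class = "bmf_result")
}
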