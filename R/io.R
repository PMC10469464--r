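# Readers/writers for the three input tables, validation, and run
# summaries. Delimited text (comma, UTF-8, header row) is the canonical
# interchange; units are fixed by the schemas.

#' Read a chemical property table
#'
#' Schema (CSV, header row): `name`, `class` (PFCA/PFSA), `chain_length`,
#' `molar_mass` (g/mol), `molar_volume_cm3_mol`, `melting_point_K`,
#' `water_solubility_mol_m3`, and optionally `logD_NLW`, `logD_PLW`,
#' `logD_ALBW`, `logD_SPW` plus parallel `*_source` columns. Empty logD
#' cells mean "predict me" via [fit_qspr_table()] / [predict_logd()].
#'
#' @param path Path to the CSV file.
#' @return Object of class `chem_table` (list of `chem_record` keyed by
#'   name, plus the raw table).
#' @export
read_chemicals <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("name", "class", "chain_length", "molar_mass",
                "molar_volume_cm3_mol", "melting_point_K",
                "water_solubility_mol_m3")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("chemical table ", path, " missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  records <- list()
  for (i in seq_len(nrow(df))) {
    logd <- numeric(); src <- character()
    for (ph in logd_phases) {
      col <- paste0("logD_", ph)
      if (col %in% names(df) && !is.na(df[[col]][i])) {
        logd[ph] <- df[[col]][i]
        scol <- paste0(col, "_source")
        src[ph] <- if (scol %in% names(df) && !is.na(df[[scol]][i]) &&
                       nzchar(df[[scol]][i])) df[[scol]][i] else "measured"
      }
    }
    records[[df$name[i]]] <- chemical_record(
      name = df$name[i], analyte_class = df$class[i],
      chain_length = df$chain_length[i], molar_mass = df$molar_mass[i],
      molar_volume = df$molar_volume_cm3_mol[i],
      melting_point = df$melting_point_K[i],
      water_solubility = df$water_solubility_mol_m3[i],
      logd = logd, logd_source = src)
  }
  structure(list(records = records, table = df), class = "chem_table")
}

#' @export
print.chem_table <- function(x, ...) {
  cat(sprintf("<chem_table> %d chemicals: %s\n", length(x$records),
              paste(names(x$records), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.chem_table <- function(x, ...) x$table

#' Write a chemical table to CSV
#'
#' @param chems A `chem_table`.
#' @param path Output path.
#' @export
write_chemicals <- function(chems, path) {
  utils::write.csv(as.data.frame(chems), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a food-web dataset
#'
#' Reads the samples, measurements, and chemicals tables, enforces all
#' record-level invariants, and reports every violation with its table and
#' row number in a single error.
#'
#' Samples schema: `sample_id`, `species`, `group`, `delta15N`,
#' `trophic_position` (one of the last two required per row),
#' `body_temperature_K` (270-320), `phi_NL`, `phi_PL`, `phi_ALB`,
#' `phi_SP`, `phi_W` (each in \[0,1\], summing to <= 1).
#' Measurements schema: `sample_id`, `analyte`, `conc_ng_g_ww` (> 0),
#' `censored` (0/1), `mloq_ng_g_ww` (> 0 where censored; a censored row's
#' concentration is its limit).
#'
#' @param samples_path,measurements_path,chemicals_path CSV paths.
#' @return List with validated `samples`, `measurements` data frames and
#'   the `chemicals` `chem_table`.
#' @export
read_dataset <- function(samples_path, measurements_path, chemicals_path) {
  samples <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  measurements <- utils::read.csv(measurements_path, stringsAsFactors = FALSE)
  chemicals <- read_chemicals(chemicals_path)
  errs <- character()
  add <- function(tbl, row, msg)
    errs[[length(errs) + 1L]] <<- sprintf("%s row %d: %s", tbl, row, msg)

  req_s <- c("sample_id", "body_temperature_K", "phi_NL", "phi_PL",
             "phi_ALB", "phi_SP", "phi_W")
  miss <- setdiff(req_s, names(samples))
  if (length(miss))
    stop("samples table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!any(c("trophic_position", "delta15N") %in% names(samples)))
    stop("samples table needs a trophic_position or delta15N column",
         call. = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in samples table", call. = FALSE)
  phicols <- c("phi_NL", "phi_PL", "phi_ALB", "phi_SP", "phi_W")
  for (i in seq_len(nrow(samples))) {
    phi <- as.numeric(samples[i, phicols])
    if (any(is.na(phi)) || any(phi < 0) || any(phi > 1))
      add("samples", i, "tissue fraction outside [0, 1]")
    else if (sum(phi) > 1 + 1e-9)
      add("samples", i, sprintf("tissue fractions sum to %.4f > 1", sum(phi)))
    tp <- if ("trophic_position" %in% names(samples))
      samples$trophic_position[i] else NA
    d15 <- if ("delta15N" %in% names(samples)) samples$delta15N[i] else NA
    if (is.na(tp) && is.na(d15))
      add("samples", i, "neither trophic_position nor delta15N present")
    if (!is.na(tp) && tp < 1)
      add("samples", i, sprintf("trophic_position %.3f < 1", tp))
    bt <- samples$body_temperature_K[i]
    if (is.na(bt) || bt < 270 || bt > 320)
      add("samples", i, "body_temperature_K outside [270, 320]")
  }

  req_m <- c("sample_id", "analyte", "conc_ng_g_ww", "censored",
             "mloq_ng_g_ww")
  miss <- setdiff(req_m, names(measurements))
  if (length(miss))
    stop("measurements table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(measurements) == 0L)
    stop("no measurements: the measurements table is empty", call. = FALSE)
  for (i in seq_len(nrow(measurements))) {
    m <- measurements[i, ]
    if (!m$sample_id %in% samples$sample_id)
      add("measurements", i, paste("unknown sample_id", m$sample_id))
    if (is.na(m$conc_ng_g_ww) || m$conc_ng_g_ww <= 0)
      add("measurements", i, "conc_ng_g_ww must be positive")
    if (is.na(m$censored) || !m$censored %in% c(0, 1))
      add("measurements", i, "censored must be 0 or 1")
    else if (m$censored == 1) {
      if (is.na(m$mloq_ng_g_ww) || m$mloq_ng_g_ww <= 0)
        add("measurements", i, "censored row lacking a positive mloq_ng_g_ww")
      else if (!is.na(m$conc_ng_g_ww) &&
               abs(m$conc_ng_g_ww - m$mloq_ng_g_ww) >
                 1e-9 * max(1, m$mloq_ng_g_ww)) {
        warning(sprintf(
          "measurements row %d: censored value set to its limit", i),
          call. = FALSE)
        measurements$conc_ng_g_ww[i] <- m$mloq_ng_g_ww
      }
    }
  }
  if (length(errs))
    stop("dataset validation failed:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  measurements$censored <- as.integer(measurements$censored)
  list(samples = samples, measurements = measurements,
       chemicals = chemicals)
}

#' Write a synthetic food web as the pipeline's input tables
#'
#' Writes `samples.csv`, `measurements.csv`, `chemicals.csv`, and
#' `truth.csv` under `dir`.
#'
#' @param fw A `synthetic_foodweb` from [generate_foodweb()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(fw, dir) {
  stopifnot(inherits(fw, "synthetic_foodweb"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(samples = file.path(dir, "samples.csv"),
             measurements = file.path(dir, "measurements.csv"),
             chemicals = file.path(dir, "chemicals.csv"),
             truth = file.path(dir, "truth.csv"))
  utils::write.csv(fw$samples, paths["samples"], row.names = FALSE, na = "")
  utils::write.csv(fw$measurements, paths["measurements"],
                   row.names = FALSE, na = "")
  write_chemicals(fw$chemicals, paths["chemicals"])
  utils::write.csv(fw$truth, paths["truth"], row.names = FALSE, na = "")
  invisible(paths)
}

# Machine-readable run summary (JSON): version, subcommand, config echo,
# seed, collected warnings.
write_run_summary <- function(path, subcommand, config = list(),
                              seed = NULL, warnings = character()) {
  info <- list(
    package = "pfastmf",
    version = as.character(utils::packageVersion("pfastmf")),
    subcommand = subcommand, config = config, seed = seed,
    warnings = warnings)
  jsonlite::write_json(info, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
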