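#' Delimited-text readers for the cohort tables
#'
#' All inputs are comma- or tab-delimited UTF-8 text with a header
#' (autodetected). Dates are ISO 8601 (`YYYY-MM-DD`), inclusive on both ends.
#'
#' @name cohort-io
NULL

#' @describeIn cohort-io Patient table: `patient_id`, `age` (years), `sex`
#'   (`F`/`M`), `admission_date`, `discharge_date`.
#' @param path Path to a delimited text file.
#' @return A tibble.
#' @export
read_patients <- function(path) {
  df <- read_delim_auto(path)
  require_columns(
    df, c("patient_id", "age", "sex", "admission_date", "discharge_date"),
    "patient table"
  )
  dplyr::mutate(
    tibble::as_tibble(df),
    patient_id = as.character(.data$patient_id),
    age = as.integer(.data$age),
    sex = toupper(substr(as.character(.data$sex), 1, 1)),
    admission_date = as_date_strict(.data$admission_date, "admission_date"),
    discharge_date = as_date_strict(.data$discharge_date, "discharge_date")
  )
}

#' @describeIn cohort-io Diagnosis table: `patient_id`, `icd10`, `rank`
#'   (1 = primary, higher = comorbid).
#' @export
read_diagnoses <- function(path) {
  df <- read_delim_auto(path)
  require_columns(df, c("patient_id", "icd10", "rank"), "diagnosis table")
  dplyr::mutate(
    tibble::as_tibble(df),
    patient_id = as.character(.data$patient_id),
    icd10 = as.character(.data$icd10),
    rank = as.integer(.data$rank)
  )
}

#' @describeIn cohort-io Prescription table: `patient_id`, `drug` (name),
#'   `atc` (optional, may be blank per row), `dose_mg`, `route`, `form`,
#'   `times_per_day`, `interval_days` (exactly one of the two populated per
#'   row; `interval_days` only for `long_acting` forms), `start_date`,
#'   `end_date`.
#' @export
read_prescriptions <- function(path) {
  df <- read_delim_auto(path)
  require_columns(
    df,
    c(
      "patient_id", "drug", "dose_mg", "route", "form",
      "times_per_day", "interval_days", "start_date", "end_date"
    ),
    "prescription table"
  )
  if (!"atc" %in% names(df)) df$atc <- NA_character_
  dplyr::mutate(
    tibble::as_tibble(df),
    patient_id = as.character(.data$patient_id),
    drug = as.character(.data$drug),
    atc = dplyr::if_else(
      is.na(.data$atc) | !nzchar(as.character(.data$atc)),
      NA_character_, toupper(as.character(.data$atc))
    ),
    dose_mg = as.numeric(.data$dose_mg),
    times_per_day = as.numeric(.data$times_per_day),
    interval_days = as.integer(.data$interval_days),
    start_date = as_date_strict(.data$start_date, "start_date"),
    end_date = as_date_strict(.data$end_date, "end_date")
  )
}

#' @describeIn cohort-io Off-label policy table: `atc_prefix`,
#'   `allowed_categories` (semicolon-separated diagnosis categories), `note`.
#' @export
read_label_policy <- function(path) {
  df <- read_delim_auto(path)
  require_columns(df, c("atc_prefix", "allowed_categories"), "label policy table")
  dplyr::mutate(
    tibble::as_tibble(df),
    atc_prefix = parse_atc(.data$atc_prefix),
    allowed_categories = as.character(.data$allowed_categories)
  )
}

#' Resolve prescriptions against a drug registry
#'
#' Attaches the registry entry — canonical name, DDD, antipsychotic flag — to
#' every prescription row. Rows carrying an ATC code are matched on
#' `(atc, route, form)`; rows without one are matched by normalized drug name.
#' Antipsychotic rows that cannot be matched to a registry presentation raise
#' an error naming the offending row (their PDD/DDD summaries would be
#' meaningless); non-antipsychotic rows with a valid ATC pass through with
#' `ddd_mg = NA` so concomitant psychotropics can ride along for regimen and
#' off-label analysis.
#'
#' Validation enforced here: positive dose; exactly one of
#' `times_per_day`/`interval_days` per row; depot (`interval_days`) schedules
#' only on `long_acting` forms; `start_date <= end_date`.
#'
#' @param rx Prescription tibble, see [read_prescriptions()].
#' @param registry A `drug_registry`, e.g. [default_registry()].
#' @return The prescription tibble with `atc`, `drug` canonicalized and
#'   `ddd_mg`, `is_antipsychotic`, `daily_dose_mg` columns added.
#' @export
resolve_prescriptions <- function(rx, registry) {
  rx <- tibble::as_tibble(rx)
  n <- nrow(rx)
  if (n == 0) {
    return(dplyr::mutate(rx,
      ddd_mg = numeric(0), is_antipsychotic = logical(0),
      daily_dose_mg = numeric(0)
    ))
  }

  # name-based resolution where atc is missing
  name_key <- normalize_drug_name(rx$drug)
  idx_by_name <- match(name_key, registry$name_key)
  rx$atc <- ifelse(is.na(rx$atc), registry$atc[idx_by_name], rx$atc)
  unresolved <- is.na(rx$atc)
  if (any(unresolved)) {
    stop(sprintf(
      "prescription row(s) %s: drug '%s' has no ATC code and is not in the registry",
      paste(which(unresolved), collapse = ", "),
      rx$drug[which(unresolved)[1]]
    ), call. = FALSE)
  }
  rx$atc <- parse_atc(rx$atc)

  # registry join on the full presentation key
  key <- paste(rx$atc, rx$route, rx$form)
  reg_key <- paste(registry$atc, registry$route, registry$form)
  idx <- match(key, reg_key)
  matched <- !is.na(idx)
  rx$ddd_mg <- ifelse(matched, registry$ddd_mg[idx], NA_real_)
  rx$drug <- ifelse(matched, registry$name[idx], rx$drug)
  rx$is_antipsychotic <- is_antipsychotic(rx$atc)

  miss_ap <- rx$is_antipsychotic & !matched
  if (any(miss_ap)) {
    i <- which(miss_ap)[1]
    near <- unique(registry$name[startsWith(registry$atc, substr(rx$atc[i], 1, 5))])
    stop(sprintf(
      "prescription row %d: antipsychotic presentation (%s, %s, %s) not in registry; nearest: %s",
      i, rx$atc[i], rx$route[i], rx$form[i],
      if (length(near)) paste(near, collapse = ", ") else "none"
    ), call. = FALSE)
  }

  if (any(rx$start_date > rx$end_date)) {
    stop(sprintf(
      "prescription row(s) %s: start_date after end_date",
      paste(which(rx$start_date > rx$end_date), collapse = ", ")
    ), call. = FALSE)
  }
  depot <- !is.na(rx$interval_days)
  if (any(depot & rx$form != "long_acting")) {
    stop(sprintf(
      "prescription row(s) %s: depot interval schedule on a non-long_acting form",
      paste(which(depot & rx$form != "long_acting"), collapse = ", ")
    ), call. = FALSE)
  }
  rx$daily_dose_mg <- daily_dose(rx$dose_mg, rx$times_per_day, rx$interval_days)
  rx
}
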