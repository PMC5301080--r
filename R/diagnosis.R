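#' ICD-10 diagnosis grouping, age bands and off-label screening
#'
#' Diagnoses are grouped into the decade blocks of the ICD-10 F chapter that
#' drive the cohort tables: organic (F00-F09), substance use (F10-F19),
#' schizophrenia and other psychoses (F20-F29), mood (F30-F39),
#' anxiety-related (F40-F49) and personality (F60-F69) disorders; everything
#' else — other F blocks and non-F chapters — is `other`.
#'
#' @name diagnosis
NULL

diagnosis_categories <- c(
  "organic", "substance_use", "schizophrenia_psychosis",
  "mood", "anxiety_related", "personality", "other"
)

#' Map an ICD-10 code to its diagnosis category
#'
#' @param code Character vector of ICD-10 codes (letter + two digits +
#'   optional subdivision, e.g. `"F20.0"`).
#' @return Factor over the categories `organic`, `substance_use`,
#'   `schizophrenia_psychosis`, `mood`, `anxiety_related`, `personality`,
#'   `other`.
#' @examples
#' categorize_icd10(c("F20.0", "F32", "G30"))
#' @export
categorize_icd10 <- function(code) {
  code <- toupper(trimws(code))
  ok <- grepl("^[A-Z][0-9]{2}(\\.[0-9A-Z]{1,4})?$", code)
  if (any(!ok)) {
    stop(sprintf(
      "malformed ICD-10 code(s): %s",
      paste(unique(code[!ok]), collapse = ", ")
    ), call. = FALSE)
  }
  decade <- substr(code, 2, 2)
  cat <- rep("other", length(code))
  is_f <- startsWith(code, "F")
  cat[is_f & decade == "0"] <- "organic"
  cat[is_f & decade == "1"] <- "substance_use"
  cat[is_f & decade == "2"] <- "schizophrenia_psychosis"
  cat[is_f & decade == "3"] <- "mood"
  cat[is_f & decade == "4"] <- "anxiety_related"
  cat[is_f & decade == "6"] <- "personality"
  factor(cat, levels = diagnosis_categories)
}

age_band_levels <- c("18-34", "35-49", "50-64", ">=65")

#' Assign an age band
#'
#' Half-open bands with the boundary ascending: `[18,35)`, `[35,50)`,
#' `[50,65)`, `[65,Inf)` — a 35-year-old falls in 35-49, a 65-year-old in
#' >=65. The cohort inclusion criterion is adults only, so ages below 18
#' raise an error.
#'
#' @param age Integer ages in years (>= 18).
#' @return Factor over `18-34`, `35-49`, `50-64`, `>=65`.
#' @examples
#' assign_age_band(c(18, 35, 64, 65))
#' @export
assign_age_band <- function(age) {
  if (any(!is.finite(age)) || any(age < 18)) {
    stop("age must be >= 18 (adult inpatient inclusion criterion)", call. = FALSE)
  }
  cut(age,
    breaks = c(18, 35, 50, 65, Inf), right = FALSE,
    labels = age_band_levels
  )
}

#' The default off-label policy table
#'
#' The policy is data, not code: a table of `(atc_prefix,
#' allowed_categories)` rows, editable by the user. The shipped default is a
#' deliberately conservative surrogate — psychotic-spectrum diagnoses
#' (F20-F29) license every antipsychotic, quetiapine is additionally allowed
#' in mood disorders, and any other indication is off-label. It is not a
#' regulatory label database.
#'
#' @return Policy tibble: `atc_prefix`, `allowed_categories`
#'   (semicolon-separated), `note`.
#' @export
default_label_policy <- function() {
  read_label_policy(
    system.file("extdata", "default_policy.csv", package = "rxddd", mustWork = TRUE)
  )
}

#' Flag off-label antipsychotic prescriptions
#'
#' Each (patient, antipsychotic chemical) pair is on-label if any of the
#' patient's diagnosis categories appears in the union of allowed categories
#' of every policy row whose `atc_prefix` prefixes the drug's ATC code.
#' The rationale records why: `psychotic_diagnosis` (licensed via a
#' psychotic-spectrum diagnosis), `approved_nonpsychotic` (licensed via a
#' drug-specific nonpsychotic indication) or `no_eligible_diagnosis`
#' (off-label). A drug matching no policy row is flagged
#' `no_eligible_diagnosis` with a warning, not an error.
#'
#' @param diagnoses Diagnosis tibble (`patient_id`, `icd10`, `rank`).
#' @param rx Resolved prescriptions, see [resolve_prescriptions()].
#' @param policy Policy tibble, see [default_label_policy()].
#' @return Tibble: `patient_id`, `drug`, `atc`, `on_label`, `rationale`.
#' @export
flag_offlabel <- function(diagnoses, rx, policy = default_label_policy()) {
  ap <- rx |>
    dplyr::filter(.data$is_antipsychotic) |>
    dplyr::distinct(.data$patient_id, .data$drug, .data$atc)
  if (nrow(ap) == 0) {
    return(tibble::tibble(
      patient_id = character(0), drug = character(0), atc = character(0),
      on_label = logical(0), rationale = character(0)
    ))
  }
  pat_cats <- diagnoses |>
    dplyr::mutate(category = as.character(categorize_icd10(.data$icd10))) |>
    dplyr::distinct(.data$patient_id, .data$category)
  cats_by_patient <- split(pat_cats$category, pat_cats$patient_id)

  allowed_sets <- strsplit(policy$allowed_categories, ";", fixed = TRUE) |>
    lapply(trimws)
  bad <- setdiff(unlist(allowed_sets), diagnosis_categories)
  if (length(bad) > 0) {
    stop(sprintf(
      "policy names unknown categories: %s", paste(bad, collapse = ", ")
    ), call. = FALSE)
  }

  unmatched <- character(0)
  out <- purrr::pmap(ap, function(patient_id, drug, atc) {
    rows <- startsWith(atc, policy$atc_prefix)
    allowed <- unique(unlist(allowed_sets[rows]))
    if (!any(rows)) unmatched <<- c(unmatched, drug)
    cats <- cats_by_patient[[patient_id]] %||% character(0)
    hit <- intersect(cats, allowed)
    if (length(hit) == 0) {
      tibble::tibble(
        patient_id = patient_id, drug = drug, atc = atc,
        on_label = FALSE, rationale = "no_eligible_diagnosis"
      )
    } else {
      tibble::tibble(
        patient_id = patient_id, drug = drug, atc = atc,
        on_label = TRUE,
        rationale = if ("schizophrenia_psychosis" %in% hit) {
          "psychotic_diagnosis"
        } else {
          "approved_nonpsychotic"
        }
      )
    }
  }) |>
    purrr::list_rbind()
  if (length(unmatched) > 0) {
    warning(sprintf(
      "no policy row matches drug(s): %s; flagged no_eligible_diagnosis",
      paste(unique(unmatched), collapse = ", ")
    ), call. = FALSE)
  }
  out
}
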