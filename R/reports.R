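#' Percentage with report rounding
#'
#' `100 * num / den`, rounded to 1 decimal half away from zero, the rounding
#' used throughout the cohort report. A nonpositive denominator yields the
#' undefined-percent sentinel `NA`.
#'
#' @param num Numerator count.
#' @param den Denominator count.
#' @return Percentage at 1 dp, or `NA_real_`.
#' @examples
#' percent(217, 353) # 61.5
#' @export
percent <- function(num, den) {
  out <- round_half_away(100 * num / den, 1)
  out[rep_len(!(den > 0), length(out))] <- NA_real_
  out
}

pretty_category <- c(
  organic = "Organic disorders",
  substance_use = "Substance use disorders",
  schizophrenia_psychosis = "Schizophrenia and other psychosis",
  mood = "Mood disorders",
  anxiety_related = "Anxiety-related disorders",
  personality = "Personality disorders",
  other = "Rest of the diagnoses"
)

# Pearson chi-square without continuity correction; stats::chisq.test warns
# when expected cell counts are small, which is passed through.
chisq_p <- function(tab) {
  if (any(dim(tab) < 2) || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(NA_real_)
  }
  stats::chisq.test(tab, correct = FALSE)$p.value
}

patient_categories <- function(patients, diagnoses) {
  diagnoses |>
    dplyr::mutate(category = as.character(categorize_icd10(.data$icd10))) |>
    dplyr::distinct(.data$patient_id, .data$category) |>
    dplyr::inner_join(patients, by = "patient_id")
}

#' Demographics-by-diagnosis table (Table 1 layout)
#'
#' One row per diagnosis category with at least one patient: the number of
#' patients carrying any diagnosis in the category (comorbid patients count
#' once per category), the category's share of the cohort, the
#' within-category age-band and sex distributions (percent), and Pearson
#' chi-square P values testing category membership (in-category vs rest of
#' cohort) against age band and against sex. `test_scope = "global"` instead
#' tests the full category-by-band (and category-by-sex) contingency table
#' and reports that single P value on every row.
#'
#' @param patients Patient tibble.
#' @param diagnoses Diagnosis tibble.
#' @param test_scope `"vs_rest"` (default) or `"global"`.
#' @return Tibble with one row per category plus a `Total` row (P values `NA`
#'   on the total row).
#' @export
build_table1 <- function(patients, diagnoses, test_scope = c("vs_rest", "global")) {
  test_scope <- match.arg(test_scope)
  patients <- dplyr::mutate(patients,
    band = assign_age_band(.data$age),
    sex = factor(.data$sex, levels = c("F", "M"))
  )
  pc <- patient_categories(patients, diagnoses)
  n_total <- nrow(patients)

  band_pct <- function(df) {
    tab <- table(df$band)
    as.list(stats::setNames(
      percent(as.integer(tab), nrow(df)),
      paste0("age_", names(tab))
    ))
  }
  sex_pct <- function(df) {
    tab <- table(df$sex)
    as.list(stats::setNames(
      percent(as.integer(tab), nrow(df)),
      paste0("sex_", names(tab))
    ))
  }

  global_p_age <- global_p_sex <- NULL
  if (test_scope == "global") {
    global_p_age <- chisq_p(table(pc$category, pc$band))
    global_p_sex <- chisq_p(table(pc$category, pc$sex))
  }

  cats <- intersect(diagnosis_categories, unique(pc$category))
  rows <- purrr::map(cats, function(cat) {
    members <- unique(pc$patient_id[pc$category == cat])
    df <- patients[patients$patient_id %in% members, ]
    in_cat <- factor(patients$patient_id %in% members, levels = c(TRUE, FALSE))
    p_age <- if (test_scope == "global") {
      global_p_age
    } else {
      chisq_p(table(in_cat, patients$band))
    }
    p_sex <- if (test_scope == "global") {
      global_p_sex
    } else {
      chisq_p(table(in_cat, patients$sex))
    }
    tibble::as_tibble(c(
      list(
        category = unname(pretty_category[[cat]]),
        n = nrow(df),
        pct = percent(nrow(df), n_total)
      ),
      band_pct(df),
      list(p_age = p_age),
      sex_pct(df),
      list(p_sex = p_sex)
    ))
  })
  total <- tibble::as_tibble(c(
    list(category = "Total", n = n_total, pct = 100),
    band_pct(patients),
    list(p_age = NA_real_),
    sex_pct(patients),
    list(p_sex = NA_real_)
  ))
  dplyr::bind_rows(rows, total)
}

# Table 2 stratum for one patient: single-diagnosis categories, then named
# comorbidity pairs, then catch-alls.
known_pairs <- c(
  "Organic disorders + mood disorders",
  "Substance use disorders + schizophrenia and other psychosis",
  "Substance use disorders + mood disorders",
  "Substance use disorders + personality disorders",
  "Schizophrenia and other psychosis + personality disorders",
  "Mood disorders + personality disorders",
  "Anxiety-related disorders + personality disorders"
)

stratum_for <- function(cats) {
  cats <- unique(cats)
  if (length(cats) == 1) {
    label <- unname(pretty_category[[cats]])
    if (cats %in% c("organic", "other")) label <- "Rest of the diagnoses"
    return(list(group = "one_diagnosis", stratum = label))
  }
  if (length(cats) == 2) {
    ord <- order(match(cats, diagnosis_categories))
    pretty <- unname(pretty_category[cats[ord]])
    candidate <- paste(pretty[1], "+", tolower(substr(pretty[2], 1, 1)) |>
      paste0(substr(pretty[2], 2, nchar(pretty[2]))))
    if (candidate %in% known_pairs) {
      return(list(group = "comorbidity", stratum = candidate))
    }
  }
  list(group = "comorbidity", stratum = "Other combinations")
}

#' Diagnosis-by-regimen table (Table 2 layout)
#'
#' Every patient falls in exactly one stratum: patients with one diagnosis
#' are stratified by its category (organic and unclassified singles pool
#' into "Rest of the diagnoses"); patients with two or more distinct
#' diagnosis categories form comorbidity strata keyed by the unordered
#' category pair, with unrecognized combinations pooling into "Other
#' combinations". Columns count patients, antipsychotic users, monotherapy
#' and polypharmacy regimens; a `Total` row closes the table.
#'
#' @param patients Patient tibble.
#' @param diagnoses Diagnosis tibble.
#' @param regimens Regimen tibble from [classify_cohort()].
#' @return Tibble: `group`, `stratum`, `n`, `pct`, `users`, `mono`, `poly`.
#' @export
build_table2 <- function(patients, diagnoses, regimens) {
  cats_by_patient <- diagnoses |>
    dplyr::mutate(category = as.character(categorize_icd10(.data$icd10))) |>
    dplyr::arrange(.data$patient_id, .data$rank)
  cats_by_patient <- split(cats_by_patient$category, cats_by_patient$patient_id)

  strata <- purrr::map(as.character(patients$patient_id), function(pid) {
    cats <- cats_by_patient[[pid]]
    if (is.null(cats)) {
      return(tibble::tibble(
        patient_id = pid, group = "one_diagnosis",
        stratum = "Rest of the diagnoses"
      ))
    }
    s <- stratum_for(cats)
    tibble::tibble(patient_id = pid, group = s$group, stratum = s$stratum)
  }) |>
    purrr::list_rbind() |>
    dplyr::bind_rows(tibble::tibble(
      patient_id = character(0), group = character(0), stratum = character(0)
    )) |>
    dplyr::left_join(
      dplyr::select(regimens, "patient_id", "regimen"),
      by = "patient_id"
    )

  order_key <- c(
    paste0("one_diagnosis.", c(
      "Substance use disorders", "Schizophrenia and other psychosis",
      "Mood disorders", "Anxiety-related disorders",
      "Personality disorders", "Rest of the diagnoses"
    )),
    paste0("comorbidity.", c(known_pairs, "Other combinations"))
  )

  body <- strata |>
    dplyr::summarise(
      n = dplyr::n(),
      users = sum(.data$regimen != "none"),
      mono = sum(.data$regimen == "monotherapy"),
      poly = sum(.data$regimen == "polypharmacy"),
      .by = c("group", "stratum")
    ) |>
    dplyr::mutate(
      pct = percent(.data$n, nrow(patients)),
      .after = "n"
    ) |>
    dplyr::arrange(match(paste(.data$group, .data$stratum, sep = "."), order_key))

  total <- tibble::tibble(
    group = "total", stratum = "Total",
    n = nrow(patients), pct = 100,
    users = sum(body$users), mono = sum(body$mono), poly = sum(body$poly)
  )
  dplyr::bind_rows(body, total)
}

#' Drug-utilization table (Table 3 layout)
#'
#' Delegates to [summarize_utilization()]; rows ordered by drug name.
#'
#' @param exposures Exposure tibble from [compute_exposures()].
#' @param registry A `drug_registry`.
#' @inheritParams summarize_utilization
#' @return Tibble of utilization rows.
#' @export
build_table3 <- function(exposures, registry, count_mode = "exposure", rx = NULL) {
  summarize_utilization(exposures, registry, count_mode = count_mode, rx = rx)
}

#' Run the full cohort analysis
#'
#' Resolves prescriptions, computes per-patient drug exposures and regimens,
#' screens for off-label use, and assembles the three report tables plus the
#' cohort headline (patients, antipsychotic users, user percentage, total
#' antipsychotic prescriptions).
#'
#' @param patients,diagnoses,prescriptions Cohort tibbles (see the
#'   `read_*` readers or [generate_cohort()]).
#' @param registry A `drug_registry` (default [default_registry()]).
#' @param policy Off-label policy table (default [default_label_policy()]).
#' @param min_overlap_days Concurrency tolerance, see [max_concurrency()].
#' @param count_mode Prescription counting mode, see [summarize_utilization()].
#' @return A `cohort_report` list: `headline`, `table1`, `table2`, `table3`,
#'   `regimens`, `app_shares`, `offlabel`, `exposures`.
#' @export
analyze_cohort <- function(patients, diagnoses, prescriptions,
                           registry = default_registry(),
                           policy = default_label_policy(),
                           min_overlap_days = 1L,
                           count_mode = c("exposure", "order")) {
  count_mode <- match.arg(count_mode)
  rx <- resolve_prescriptions(prescriptions, registry)
  exposures <- compute_exposures(rx)
  regimens <- classify_cohort(rx, patients, min_overlap_days = min_overlap_days)
  table1 <- build_table1(patients, diagnoses)
  table2 <- build_table2(patients, diagnoses, regimens)
  table3 <- build_table3(exposures, registry, count_mode = count_mode, rx = rx)
  offlabel <- flag_offlabel(diagnoses, rx, policy)
  app_shares <- app_share_by_drug(exposures, regimens)

  n_users <- sum(regimens$regimen != "none")
  headline <- list(
    n_patients = nrow(patients),
    n_antipsychotic_users = n_users,
    percent_users = percent(n_users, nrow(patients)),
    n_prescriptions = sum(table3$n)
  )
  structure(
    list(
      headline = headline, table1 = table1, table2 = table2, table3 = table3,
      regimens = regimens, app_shares = app_shares, offlabel = offlabel,
      exposures = exposures
    ),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  h <- x$headline
  cat(sprintf(
    "Cohort report: %d patients, %d antipsychotic users (%.1f%%), %d prescriptions\n",
    h$n_patients, h$n_antipsychotic_users, h$percent_users, h$n_prescriptions
  ))
  cat(sprintf(
    "Regimens: %d monotherapy, %d polypharmacy\n",
    sum(x$regimens$regimen == "monotherapy"),
    sum(x$regimens$regimen == "polypharmacy")
  ))
  cat("\nDrug utilization (PDD in mg/day, displayed at 2 dp):\n")
  t3 <- x$table3
  disp <- tibble::tibble(
    n = t3$n, drug = t3$drug, atc = t3$atc, ddd_mg = t3$ddd_mg,
    median_pdd = round_half_away(t3$median_pdd, 2),
    mean_pdd = round_half_away(t3$mean_pdd, 2),
    ci = sprintf(
      "%s-%s", round_half_away(t3$ci_low, 2), round_half_away(t3$ci_high, 2)
    ),
    ratio = round_half_away(t3$mean_pdd_over_ddd, 2),
    excessive = t3$excessive
  )
  print(as.data.frame(disp), row.names = FALSE)
  invisible(x)
}

#' Write a cohort report to disk
#'
#' Emits one CSV per table (`table1.csv`, `table2.csv`, `table3.csv`,
#' `regimens.csv`, `app_shares.csv`, `offlabel.csv`) plus a combined
#' `report.json`. Dose columns in `table3.csv` are display-rounded (2 dp,
#' half away from zero); the JSON carries unrounded values.
#'
#' @param report A `cohort_report` from [analyze_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t3 <- dplyr::mutate(report$table3, dplyr::across(
    c("median_pdd", "mean_pdd", "ci_low", "ci_high", "mean_pdd_over_ddd"),
    \(x) round_half_away(x, 2)
  ))
  readr::write_csv(report$table1, file.path(dir, "table1.csv"))
  readr::write_csv(report$table2, file.path(dir, "table2.csv"))
  readr::write_csv(t3, file.path(dir, "table3.csv"))
  readr::write_csv(report$regimens, file.path(dir, "regimens.csv"))
  readr::write_csv(report$app_shares, file.path(dir, "app_shares.csv"))
  readr::write_csv(report$offlabel, file.path(dir, "offlabel.csv"))
  jsonlite::write_json(
    list(
      headline = report$headline, table1 = report$table1,
      table2 = report$table2, table3 = report$table3,
      app_shares = report$app_shares
    ),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
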