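#' Synthetic inpatient cohort specification
#'
#' Parameter object for [generate_cohort()]. The defaults emulate the
#' structure of a two-unit brief psychiatric inpatient cohort: the diagnosis
#' category mix and comorbidity rate, per-category antipsychotic use
#' probabilities, the monotherapy/polypharmacy split among users, per-drug
#' prescription frequencies, and per-drug dose distributions centered on
#' multiples of the DDD (lognormal, so doses are positive and right-skewed,
#' with means above medians as real dosing data show).
#'
#' @param n_patients Number of patients (default 353).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param category_weights Named probability vector over diagnosis
#'   categories (must sum to 1).
#' @param comorbidity_prob Probability a patient carries a second diagnosis
#'   from a different category (default 0.312).
#' @param antipsychotic_use_prob_by_category Named probability map; a
#'   patient's use probability is the maximum over their categories.
#' @param use_prob Optional scalar overriding the per-category map (handy
#'   for parameter-recovery experiments).
#' @param polypharmacy_prob Probability an antipsychotic user receives two
#'   concurrently overlapping antipsychotic chemicals (default 0.369).
#' @param other_psychotropic_prob Probability a patient additionally
#'   receives a non-antipsychotic psychotropic (default 0.714).
#' @param dose_lognormal_sigma Log-scale SD of the dose distribution
#'   (default 0.4).
#' @param mean_ratio_by_drug Named map drug name -> target mean PDD/DDD
#'   multiplier; defaults to the shipped per-drug utilization ratios.
#' @param drug_weights Named sampling weights over registry drug names;
#'   defaults to the shipped per-drug prescription frequencies.
#' @param stay_days Length-2 integer range of stay lengths (default 7-30).
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 353,
                        seed = 1,
                        category_weights = c(
                          substance_use = 0.066,
                          schizophrenia_psychosis = 0.415,
                          mood = 0.284,
                          anxiety_related = 0.099,
                          personality = 0.086,
                          organic = 0.008,
                          other = 0.042
                        ),
                        comorbidity_prob = 0.312,
                        antipsychotic_use_prob_by_category = c(
                          substance_use = 0.50,
                          schizophrenia_psychosis = 1.00,
                          mood = 0.74,
                          anxiety_related = 0.21,
                          personality = 0.57,
                          organic = 0.40,
                          other = 0.00
                        ),
                        use_prob = NULL,
                        polypharmacy_prob = 0.369,
                        other_psychotropic_prob = 0.714,
                        dose_lognormal_sigma = 0.4,
                        mean_ratio_by_drug = NULL,
                        drug_weights = NULL,
                        stay_days = c(7L, 30L)) {
  printed <- utils::read.csv(
    system.file("extdata", "table3_printed.csv", package = "rxddd", mustWork = TRUE)
  )
  if (is.null(mean_ratio_by_drug)) {
    mean_ratio_by_drug <- stats::setNames(printed$ratio, printed$drug)
  }
  if (is.null(drug_weights)) {
    drug_weights <- stats::setNames(printed$n / sum(printed$n), printed$drug)
  }
  spec <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    category_weights = category_weights,
    comorbidity_prob = comorbidity_prob,
    antipsychotic_use_prob_by_category = antipsychotic_use_prob_by_category,
    use_prob = use_prob,
    polypharmacy_prob = polypharmacy_prob,
    other_psychotropic_prob = other_psychotropic_prob,
    dose_lognormal_sigma = dose_lognormal_sigma,
    mean_ratio_by_drug = mean_ratio_by_drug,
    drug_weights = drug_weights,
    stay_days = as.integer(stay_days)
  )
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  if (spec$n_patients < 1) stop("n_patients must be positive", call. = FALSE)
  if (abs(sum(spec$category_weights) - 1) > 1e-6) {
    stop("category_weights must sum to 1", call. = FALSE)
  }
  if (!all(names(spec$category_weights) %in% diagnosis_categories)) {
    stop("category_weights names must be diagnosis categories", call. = FALSE)
  }
  probs <- c(
    spec$comorbidity_prob, spec$antipsychotic_use_prob_by_category,
    spec$use_prob, spec$polypharmacy_prob, spec$other_psychotropic_prob
  )
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (spec$dose_lognormal_sigma <= 0) {
    stop("dose_lognormal_sigma must be positive", call. = FALSE)
  }
  if (length(spec$stay_days) != 2 || spec$stay_days[1] < 1 ||
    spec$stay_days[1] > spec$stay_days[2]) {
    stop("stay_days must be an ordered positive range", call. = FALSE)
  }
  class(spec) <- "cohort_spec"
  spec
}

# small per-category ICD-10 code pools for the generator
.icd_pool <- list(
  organic = c("F05.0", "F06.7"),
  substance_use = c("F10.2", "F12.1", "F19.2"),
  schizophrenia_psychosis = c("F20.0", "F20.5", "F22.0", "F23.1", "F25.0", "F29"),
  mood = c("F31.1", "F32.2", "F33.1"),
  anxiety_related = c("F41.0", "F41.1", "F43.1"),
  personality = c("F60.3", "F60.7"),
  other = c("F50.0", "F84.0", "G30.9")
)

# concomitant non-antipsychotic psychotropics used by the generator
.aux_drugs <- tibble::tibble(
  drug = c("Sertraline", "Lorazepam", "Valproic acid", "Diazepam"),
  atc = c("N06AB06", "N05BA06", "N03AG01", "N05BA01"),
  dose_mg = c(100, 1, 500, 10),
  times_per_day = c(1, 3, 2, 2)
)

# age-band mix and sex mix used for demographics
.age_band_probs <- c(0.273, 0.355, 0.273, 0.099)
.age_band_ranges <- list(c(18L, 34L), c(35L, 49L), c(50L, 64L), c(65L, 89L))
.female_prob <- 0.487

#' Generate a synthetic inpatient cohort
#'
#' Draws patients (age, sex, admission window), one or two diagnoses per
#' patient, and prescriptions: with the category-dependent probability the
#' patient receives one antipsychotic spanning the stay, or — with
#' `polypharmacy_prob` — a second, chemically distinct antipsychotic whose
#' date range overlaps the first by at least five days; daily doses are drawn
#' lognormally with mean `mean_ratio * DDD`; long-acting forms become depot
#' orders (28-day interval) carrying the equivalent per-injection dose.
#' Output tables use exactly the column sets the `read_*` readers consume,
#' so the generator doubles as the integration-test driver. Generation is
#' deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param registry A `drug_registry` (default [default_registry()]).
#' @return List of tibbles: `patients`, `diagnoses`, `prescriptions`.
#' @export
generate_cohort <- function(spec, registry = default_registry()) {
  spec <- validate_cohort_spec(unclass(spec))
  withr::with_seed(spec$seed, generate_cohort_impl(spec, registry))
}

generate_cohort_impl <- function(spec, registry) {
  n <- spec$n_patients
  ids <- sprintf("P%05d", seq_len(n))

  band <- sample(seq_along(.age_band_probs), n,
    replace = TRUE,
    prob = .age_band_probs / sum(.age_band_probs)
  )
  age <- vapply(band, function(b) {
    r <- .age_band_ranges[[b]]
    sample(r[1]:r[2], 1L)
  }, integer(1))
  sex <- ifelse(stats::runif(n) < .female_prob, "F", "M")
  admission <- as.Date("2014-06-01") + sample(0:120, n, replace = TRUE)
  stay <- sample(spec$stay_days[1]:spec$stay_days[2], n, replace = TRUE)
  discharge <- admission + stay - 1L

  patients <- tibble::tibble(
    patient_id = ids, age = age, sex = sex,
    admission_date = admission, discharge_date = discharge
  )

  cats <- names(spec$category_weights)
  cat1 <- sample(cats, n, replace = TRUE, prob = spec$category_weights)
  comorbid <- stats::runif(n) < spec$comorbidity_prob
  cat2 <- rep(NA_character_, n)
  for (i in which(comorbid)) {
    others <- setdiff(cats, cat1[i])
    w <- spec$category_weights[others]
    cat2[i] <- sample(others, 1L, prob = w / sum(w))
  }
  pick_icd <- function(cat) sample(.icd_pool[[cat]], 1L)
  diagnoses <- dplyr::bind_rows(
    tibble::tibble(
      patient_id = ids, icd10 = vapply(cat1, pick_icd, character(1)), rank = 1L
    ),
    tibble::tibble(
      patient_id = ids[comorbid],
      icd10 = vapply(cat2[comorbid], pick_icd, character(1)), rank = 2L
    )
  ) |>
    dplyr::arrange(.data$patient_id, .data$rank)

  # registry presentations sampled by drug name
  reg <- registry[registry$name %in% names(spec$drug_weights), ]
  w_drug <- spec$drug_weights[reg$name]
  ratio_of <- spec$mean_ratio_by_drug

  use_p <- if (!is.null(spec$use_prob)) {
    rep(spec$use_prob, n)
  } else {
    p1 <- spec$antipsychotic_use_prob_by_category[cat1]
    p2 <- ifelse(is.na(cat2), 0, spec$antipsychotic_use_prob_by_category[cat2])
    pmax(p1, p2, na.rm = TRUE)
  }
  is_user <- stats::runif(n) < use_p
  is_poly <- is_user & (stats::runif(n) < spec$polypharmacy_prob)

  rx_list <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- NULL
    if (is_user[i]) {
      j1 <- sample(nrow(reg), 1L, prob = w_drug)
      picks <- j1
      if (is_poly[i]) {
        # second agent must be a different chemical (level-7 ATC)
        ok <- reg$atc != reg$atc[j1]
        j2 <- sample(which(ok), 1L, prob = w_drug[ok])
        picks <- c(j1, j2)
      }
      rows <- purrr::map(seq_along(picks), function(k) {
        j <- picks[k]
        target <- ratio_of[[reg$name[j]]] * reg$ddd_mg[j]
        daily <- stats::rlnorm(
          1,
          meanlog = log(target) - spec$dose_lognormal_sigma^2 / 2,
          sdlog = spec$dose_lognormal_sigma
        )
        depot <- reg$form[j] == "long_acting"
        start <- if (k == 1) {
          admission[i]
        } else {
          admission[i] + sample(0:max(0L, stay[i] %/% 3L), 1L)
        }
        tibble::tibble(
          patient_id = ids[i],
          drug = reg$name[j],
          atc = reg$atc[j],
          dose_mg = if (depot) daily * 28 else daily,
          route = reg$route[j],
          form = reg$form[j],
          times_per_day = if (depot) NA_real_ else 1,
          interval_days = if (depot) 28L else NA_integer_,
          start_date = start,
          end_date = discharge[i]
        )
      }) |> purrr::list_rbind()
    }
    if (stats::runif(1) < spec$other_psychotropic_prob) {
      a <- .aux_drugs[sample(nrow(.aux_drugs), 1L), ]
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        patient_id = ids[i], drug = a$drug, atc = a$atc, dose_mg = a$dose_mg,
        route = "oral", form = "standard", times_per_day = a$times_per_day,
        interval_days = NA_integer_, start_date = admission[i],
        end_date = discharge[i]
      ))
    }
    rx_list[[i]] <- rows
  }
  prescriptions <- purrr::list_rbind(purrr::compact(rx_list))

  list(patients = patients, diagnoses = diagnoses, prescriptions = prescriptions)
}

#' Write a generated cohort to delimited text
#'
#' @param cohort List from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$patients, file.path(dir, "patients.csv"))
  readr::write_csv(cohort$diagnoses, file.path(dir, "diagnoses.csv"))
  readr::write_csv(cohort$prescriptions, file.path(dir, "prescriptions.csv"))
  invisible(dir)
}

#' Deterministic mini-cohort reproducing reference utilization rows
#'
#' A hand-constructed cohort whose per-drug exposures land exactly on
#' several reference utilization-table rows: eleven clozapine patients with
#' mean PDD 345.45 mg (median 350, ratio 1.15), one ziprasidone patient at
#' 120 mg/day (point CI, ratio exactly 1.50), three fluphenazine depot
#' patients at 25 mg/28 days (median 0.89 mg/day), one long-acting
#' paliperidone patient at 100 mg/28 days (3.57 mg/day), one long-acting
#' risperidone patient at 7.14 mg/day (ratio 2.64), two zuclopenthixol
#' acufase patients at 25 mg/day (degenerate CI 25-25, ratio 0.83) and two
#' amisulpride patients at 800 mg/day (ratio 2.00, excessive). All patients
#' carry a psychotic-spectrum diagnosis and 20-day stays.
#'
#' @return List of tibbles: `patients`, `diagnoses`, `prescriptions`.
#' @export
fixture_table3_cohort <- function() {
  clozapine_doses <- c(150, 200, 250, 300, 350, 350, 400, 400, 450, 450, 500)
  specs <- tibble::tibble(
    drug = c(
      rep("Clozapine", 11), "Ziprasidone", rep("Fluphenazine", 3),
      "Long-acting paliperidone", "Long-acting risperidone",
      rep("Zuclopenthixol acufase", 2), rep("Amisulpride", 2)
    ),
    atc = c(
      rep("N05AH02", 11), "N05AE04", rep("N05AB02", 3),
      "N05AX13", "N05AX08", rep("N05AF05", 2), rep("N05AL05", 2)
    ),
    route = c(
      rep("oral", 11), "oral", rep("injectable", 3),
      "injectable", "injectable", rep("injectable", 2), rep("oral", 2)
    ),
    form = c(
      rep("standard", 11), "standard", rep("long_acting", 3),
      "long_acting", "long_acting", rep("standard", 2), rep("standard", 2)
    ),
    dose_mg = c(
      clozapine_doses, 120, rep(25, 3), 100, 199.92, rep(25, 2), rep(800, 2)
    ),
    times_per_day = c(
      rep(1, 11), 1, rep(NA, 3), NA, NA, rep(1, 2), rep(1, 2)
    ),
    interval_days = c(
      rep(NA_integer_, 11), NA_integer_, rep(28L, 3), 28L, 28L,
      rep(NA_integer_, 2), rep(NA_integer_, 2)
    )
  )
  n <- nrow(specs)
  ids <- sprintf("F%03d", seq_len(n))
  start <- as.Date("2014-07-01")
  end <- start + 19L
  patients <- tibble::tibble(
    patient_id = ids,
    age = rep(c(28L, 41L, 57L), length.out = n),
    sex = rep(c("F", "M"), length.out = n),
    admission_date = start, discharge_date = end
  )
  diagnoses <- tibble::tibble(
    patient_id = ids,
    icd10 = rep(c("F20.0", "F25.0", "F29"), length.out = n),
    rank = 1L
  )
  prescriptions <- tibble::tibble(
    patient_id = ids,
    drug = specs$drug, atc = specs$atc, dose_mg = specs$dose_mg,
    route = specs$route, form = specs$form,
    times_per_day = specs$times_per_day, interval_days = specs$interval_days,
    start_date = start, end_date = end
  )
  list(patients = patients, diagnoses = diagnoses, prescriptions = prescriptions)
}
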