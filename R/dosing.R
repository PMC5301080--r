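#' Convert a prescription schedule to a daily dose
#'
#' Daily schedules give `dose_mg * times_per_day` mg/day. Depot (long-acting
#' injectable) schedules spread each injection uniformly over its interval:
#' `dose_mg / interval_days` mg/day, using calendar days and ignoring
#' pharmacokinetics — 25 mg fluphenazine every 28 days is 0.89 mg/day.
#' Exactly one of `times_per_day` / `interval_days` must be given per element.
#'
#' @param dose_mg Positive dose in mg (per administration).
#' @param times_per_day Administrations per day (daily schedules), or `NA`.
#' @param interval_days Days between injections (depot schedules), or `NA`.
#' @return Daily dose in mg/day.
#' @examples
#' daily_dose(25, interval_days = 28) # 0.8928571
#' daily_dose(5, times_per_day = 2) # 10
#' @export
daily_dose <- function(dose_mg, times_per_day = NA_real_, interval_days = NA_real_) {
  k <- max(length(dose_mg), length(times_per_day), length(interval_days))
  dose_mg <- rep_len(as.numeric(dose_mg), k)
  times_per_day <- rep_len(as.numeric(times_per_day), k)
  interval_days <- rep_len(as.numeric(interval_days), k)

  has_daily <- !is.na(times_per_day)
  has_depot <- !is.na(interval_days)
  if (any(has_daily == has_depot)) {
    stop("exactly one of times_per_day/interval_days must be given per prescription",
      call. = FALSE
    )
  }
  if (any(!is.finite(dose_mg) | dose_mg <= 0)) {
    stop("dose_mg must be positive", call. = FALSE)
  }
  if (any(has_daily & times_per_day <= 0)) {
    stop("times_per_day must be positive", call. = FALSE)
  }
  if (any(has_depot & (interval_days < 1 | interval_days != round(interval_days)))) {
    stop("interval_days must be a positive integer", call. = FALSE)
  }
  ifelse(has_daily, dose_mg * times_per_day, dose_mg / interval_days)
}

# Expand resolved prescriptions into one row per (patient, presentation, day)
# with that row's daily-dose contribution. Same-drug orders overlapping on a
# day are summed downstream.
rx_day_ledger <- function(rx) {
  if (nrow(rx) == 0) {
    return(tibble::tibble(
      patient_id = character(0), drug = character(0), atc = character(0),
      route = character(0), form = character(0), ddd_mg = numeric(0),
      is_antipsychotic = logical(0), date = as.Date(character(0)),
      dose = numeric(0)
    ))
  }
  days <- as.integer(rx$end_date - rx$start_date) + 1L
  idx <- rep.int(seq_len(nrow(rx)), days)
  offset <- sequence(days) - 1L
  tibble::tibble(
    patient_id = rx$patient_id[idx],
    drug = rx$drug[idx],
    atc = rx$atc[idx],
    route = rx$route[idx],
    form = rx$form[idx],
    ddd_mg = rx$ddd_mg[idx],
    is_antipsychotic = rx$is_antipsychotic[idx],
    date = rx$start_date[idx] + offset,
    dose = rx$daily_dose_mg[idx]
  )
}

#' Per-patient prescribed daily dose (PDD) by drug presentation
#'
#' Builds a day-by-day dose ledger for every (patient, drug presentation)
#' pair and averages over *exposed* days — days with a nonzero dose of that
#' presentation — not over the whole admission. Overlapping orders of the
#' same presentation on the same day sum. Date ranges are inclusive on both
#' ends: a one-day order contributes one exposed day.
#'
#' @param rx Resolved prescriptions, see [resolve_prescriptions()].
#' @param window Optional length-2 Date vector; ledger days outside
#'   `[window[1], window[2]]` are discarded before averaging.
#' @return A tibble with one row per (patient_id, drug, atc, route, form):
#'   `pdd_mg_per_day`, `exposed_days`, `ddd_mg`, `is_antipsychotic`.
#' @export
compute_exposures <- function(rx, window = NULL) {
  ledger <- rx_day_ledger(rx)
  if (!is.null(window)) {
    if (length(window) != 2 || window[1] > window[2]) {
      stop("window must be two ordered dates", call. = FALSE)
    }
    ledger <- dplyr::filter(ledger, .data$date >= window[1], .data$date <= window[2])
  }
  ledger |>
    dplyr::summarise(
      dose = sum(.data$dose),
      .by = c(
        "patient_id", "drug", "atc", "route", "form", "ddd_mg",
        "is_antipsychotic", "date"
      )
    ) |>
    dplyr::filter(.data$dose > 0) |>
    dplyr::summarise(
      pdd_mg_per_day = mean(.data$dose),
      exposed_days = dplyr::n(),
      .by = c("patient_id", "drug", "atc", "route", "form", "ddd_mg", "is_antipsychotic")
    )
}

#' PDD for one patient and one drug presentation
#'
#' Convenience wrapper around [compute_exposures()] for prescriptions that
#' all share one patient and one drug presentation. An empty prescription
#' list is not an error: it yields a no-exposure row with `pdd_mg_per_day`
#' 0, `exposed_days` 0 and `no_exposure = TRUE`.
#'
#' @inheritParams compute_exposures
#' @return A one-row tibble: `patient_id`, `pdd_mg_per_day`, `exposed_days`,
#'   `no_exposure`.
#' @export
patient_pdd <- function(rx, window = NULL) {
  if (nrow(rx) == 0) {
    return(tibble::tibble(
      patient_id = NA_character_, pdd_mg_per_day = 0,
      exposed_days = 0L, no_exposure = TRUE
    ))
  }
  if (dplyr::n_distinct(rx$patient_id) > 1 ||
    dplyr::n_distinct(paste(rx$atc, rx$route, rx$form)) > 1) {
    stop("patient_pdd expects prescriptions of one patient and one drug presentation",
      call. = FALSE
    )
  }
  out <- compute_exposures(rx, window = window)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      patient_id = rx$patient_id[1], pdd_mg_per_day = 0,
      exposed_days = 0L, no_exposure = TRUE
    ))
  }
  tibble::tibble(
    patient_id = out$patient_id,
    pdd_mg_per_day = out$pdd_mg_per_day,
    exposed_days = out$exposed_days,
    no_exposure = FALSE
  )
}
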