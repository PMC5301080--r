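# Independent brute-force oracles and small builders used across tests.

# raw prescription row(s) in the reader column layout
rx_raw <- function(patient_id, drug, dose_mg, start, end,
                   times_per_day = 1, interval_days = NA_integer_,
                   atc = NA_character_, route = NULL, form = NULL) {
  reg <- default_registry()
  i <- match(normalize_name_for_tests(drug), normalize_name_for_tests(reg$name))
  if (is.na(i)) {
    route <- route %||% "oral"
    form <- form %||% "standard"
  }
  tibble::tibble(
    patient_id = patient_id,
    drug = drug,
    atc = atc,
    dose_mg = dose_mg,
    route = route %||% reg$route[i],
    form = form %||% reg$form[i],
    times_per_day = if (is.na(interval_days)) times_per_day else NA_real_,
    interval_days = interval_days,
    start_date = as.Date(start),
    end_date = as.Date(end)
  )
}

normalize_name_for_tests <- function(x) trimws(gsub("[^a-z0-9]+", " ", tolower(x)))
`%||%` <- function(x, y) if (is.null(x)) y else x

resolve_test <- function(rx) resolve_prescriptions(rx, default_registry())

# naive per-day ledger average of one patient-presentation prescription set
ledger_pdd_oracle <- function(rx) {
  dose_by_day <- list()
  for (i in seq_len(nrow(rx))) {
    daily <- if (!is.na(rx$times_per_day[i])) {
      rx$dose_mg[i] * rx$times_per_day[i]
    } else {
      rx$dose_mg[i] / rx$interval_days[i]
    }
    for (d in seq(rx$start_date[i], rx$end_date[i], by = "day")) {
      key <- as.character(d)
      dose_by_day[[key]] <- (dose_by_day[[key]] %||% 0) + daily
    }
  }
  doses <- unlist(dose_by_day)
  mean(doses[doses > 0])
}

# naive day-sweep count of the max number of distinct antipsychotic chemicals
# active on any single calendar day (min_overlap_days = 1 semantics)
day_sweep_oracle <- function(rx) {
  ap <- rx[is_antipsychotic(rx$atc), , drop = FALSE]
  if (nrow(ap) == 0) {
    return(0L)
  }
  days <- seq(min(ap$start_date), max(ap$end_date), by = "day")
  best <- 0L
  for (d in days) {
    active <- ap$start_date <= d & ap$end_date >= d
    best <- max(best, length(unique(substr(ap$atc[active], 1, 7))))
  }
  as.integer(best)
}

# random small prescription instance over a handful of chemicals
random_rx_instance <- function(n_orders, chemicals) {
  starts <- sample(0:20, n_orders, replace = TRUE)
  lens <- sample(1:15, n_orders, replace = TRUE)
  base <- as.Date("2014-06-01")
  tibble::tibble(
    patient_id = "X",
    drug = "synthetic",
    atc = sample(chemicals, n_orders, replace = TRUE),
    route = "oral",
    form = "standard",
    is_antipsychotic = NA, # filled below
    start_date = base + starts,
    end_date = base + starts + lens - 1L,
    dose_mg = 10,
    times_per_day = 1,
    interval_days = NA_integer_,
    daily_dose_mg = 10,
    ddd_mg = NA_real_
  ) |>
    dplyr::mutate(is_antipsychotic = is_antipsychotic(atc))
}

printed_table3 <- function() {
  readr::read_csv(
    system.file("extdata", "table3_printed.csv", package = "rxddd", mustWork = TRUE),
    show_col_types = FALSE
  )
}

printed_table2 <- function() {
  readr::read_csv(
    system.file("extdata", "table2_printed.csv", package = "rxddd", mustWork = TRUE),
    show_col_types = FALSE
  )
}
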