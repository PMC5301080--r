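#' Antipsychotic polypharmacy (APP) detection
#'
#' APP is the concurrent use of two or more antipsychotic *chemicals*
#' (level-7 ATC substances) by one patient. Two presentations of the same
#' chemical — oral plus long-acting risperidone, say — count as one agent.
#' Concurrency is resolved at calendar-day granularity: by default a single
#' day of overlap makes two agents concurrent; `min_overlap_days` raises the
#' number of consecutive shared days required, which tolerates cross-taper
#' switches.
#'
#' @name regimen
NULL

# union of [start, end] integer intervals (both ends inclusive)
merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out_s <- integer(0)
  out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1L) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

#' Maximum number of concurrently active antipsychotic chemicals
#'
#' Event-sweep over each chemical's merged active intervals: the maximum,
#' over calendar days, of the number of distinct antipsychotic chemicals
#' active on `min_overlap_days` consecutive days starting that day.
#' Non-antipsychotic prescriptions are ignored.
#'
#' @param rx Resolved prescriptions of one patient, see
#'   [resolve_prescriptions()].
#' @param min_overlap_days Consecutive shared days required for concurrency
#'   (default 1).
#' @return Nonnegative integer.
#' @examples
#' # two drugs with disjoint ranges -> 1 (switching is not concurrency)
#' @export
max_concurrency <- function(rx, min_overlap_days = 1L) {
  if (min_overlap_days < 1) stop("min_overlap_days must be >= 1", call. = FALSE)
  ap <- rx[rx$is_antipsychotic, , drop = FALSE]
  if (nrow(ap) == 0) {
    return(0L)
  }
  max_conc_core(
    atc_level(ap$atc, 7),
    as.integer(ap$start_date), as.integer(ap$end_date),
    as.integer(min_overlap_days)
  )
}

# event-sweep core on plain vectors (chem: chemical id per order; s/e: integer
# day interval, inclusive; k: consecutive shared days required)
max_conc_core <- function(chem, s, e, k) {
  starts <- integer(0)
  ends <- integer(0)
  for (ch in unique(chem)) {
    rows <- chem == ch
    merged <- merge_intervals(s[rows], e[rows])
    # a k-day window fits inside one merged interval iff it starts by end-k+1
    ms <- merged$start
    me <- merged$end - (k - 1L)
    keep <- me >= ms
    starts <- c(starts, ms[keep])
    ends <- c(ends, me[keep])
  }
  if (length(starts) == 0) {
    return(0L)
  }
  at <- c(starts, ends + 1L)
  delta <- rep(c(1L, -1L), c(length(starts), length(ends)))
  # removals (at end+1) precede additions at the same day: an interval ending
  # at d and one starting at d+1 never coexist
  o <- order(at, delta)
  as.integer(max(cummax(cumsum(delta[o]))))
}

#' Classify one patient's antipsychotic regimen
#'
#' `none` (no antipsychotic prescribed), `monotherapy` (antipsychotics used,
#' never two chemicals concurrently) or `polypharmacy` (>= 2 chemicals
#' concurrent). `antipsychotic_only` is `TRUE` when the patient received at
#' least one antipsychotic and every prescribed drug was an antipsychotic —
#' i.e. antipsychotics were the only psychotropics prescribed.
#'
#' @param rx Resolved prescriptions of one patient (possibly zero rows).
#' @param min_overlap_days See [max_concurrency()].
#' @return One-row tibble: `patient_id`, `n_antipsychotics_total` (distinct
#'   chemicals), `n_antipsychotics_concurrent_max`, `regimen`,
#'   `antipsychotic_only`.
#' @export
classify_regimen <- function(rx, min_overlap_days = 1L) {
  ap <- rx[rx$is_antipsychotic, , drop = FALSE]
  n_total <- if (nrow(ap) == 0) 0L else dplyr::n_distinct(atc_level(ap$atc, 7))
  conc <- max_concurrency(rx, min_overlap_days = min_overlap_days)
  regimen <- if (n_total == 0) {
    "none"
  } else if (conc >= 2) {
    "polypharmacy"
  } else {
    "monotherapy"
  }
  tibble::tibble(
    patient_id = if (nrow(rx) > 0) rx$patient_id[1] else NA_character_,
    n_antipsychotics_total = as.integer(n_total),
    n_antipsychotics_concurrent_max = as.integer(conc),
    regimen = regimen,
    antipsychotic_only = n_total > 0 && all(rx$is_antipsychotic)
  )
}

#' Classify every patient in a cohort
#'
#' Patients with no prescriptions at all are classified `none`.
#'
#' @param rx Resolved prescriptions for the whole cohort.
#' @param patients Patient tibble (supplies patients without prescriptions).
#' @param min_overlap_days See [max_concurrency()].
#' @return Tibble with one [classify_regimen()] row per patient.
#' @export
classify_cohort <- function(rx, patients, min_overlap_days = 1L) {
  if (min_overlap_days < 1) stop("min_overlap_days must be >= 1", call. = FALSE)
  k <- as.integer(min_overlap_days)
  out <- tibble::tibble(
    patient_id = patients$patient_id,
    n_antipsychotics_total = 0L,
    n_antipsychotics_concurrent_max = 0L,
    regimen = "none",
    antipsychotic_only = FALSE
  )
  if (nrow(rx) > 0) {
    pure <- tapply(rx$is_antipsychotic, rx$patient_id, all)
    ap <- rx[rx$is_antipsychotic, , drop = FALSE]
    if (nrow(ap) > 0) {
      chem <- atc_level(ap$atc, 7)
      s <- as.integer(ap$start_date)
      e <- as.integer(ap$end_date)
      idx <- split(seq_len(nrow(ap)), ap$patient_id)
      stats <- vapply(idx, function(ii) {
        c(length(unique(chem[ii])), max_conc_core(chem[ii], s[ii], e[ii], k))
      }, integer(2))
      j <- match(colnames(stats), out$patient_id)
      out$n_antipsychotics_total[j] <- stats[1, ]
      out$n_antipsychotics_concurrent_max[j] <- stats[2, ]
      out$regimen[j] <- ifelse(stats[2, ] >= 2, "polypharmacy", "monotherapy")
      out$antipsychotic_only[j] <- unname(pure[colnames(stats)])
    }
  }
  dplyr::arrange(out, .data$patient_id)
}

#' Share of each antipsychotic's users who were in polypharmacy
#'
#' For every antipsychotic presentation with at least one user: the number of
#' users, the number whose regimen is polypharmacy, and the percentage
#' (1 dp, half away from zero). Drugs with zero users are omitted.
#'
#' @param exposures Exposure tibble from [compute_exposures()].
#' @param regimens Regimen tibble from [classify_cohort()].
#' @return Tibble: `drug`, `atc`, `route`, `form`, `n_users`,
#'   `n_in_polypharmacy`, `percent`.
#' @export
app_share_by_drug <- function(exposures, regimens) {
  exposures |>
    dplyr::filter(.data$is_antipsychotic) |>
    dplyr::left_join(
      dplyr::select(regimens, "patient_id", "regimen"),
      by = "patient_id"
    ) |>
    dplyr::summarise(
      n_users = dplyr::n_distinct(.data$patient_id),
      n_in_polypharmacy = dplyr::n_distinct(
        .data$patient_id[.data$regimen == "polypharmacy"]
      ),
      .by = c("drug", "atc", "route", "form")
    ) |>
    dplyr::mutate(
      percent = round_half_away(100 * .data$n_in_polypharmacy / .data$n_users, 1)
    ) |>
    dplyr::arrange(.data$drug)
}
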