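#' PDD/DDD dose-intensity ratio
#'
#' The prescribed-to-defined daily dose ratio normalizes dose intensity
#' across chemicals: a ratio of 1 means the cohort's mean prescribed daily
#' dose equals the WHO maintenance dose assumption.
#'
#' @param mean_pdd_mg Mean prescribed daily dose, mg/day.
#' @param ddd_mg Defined daily dose, mg/day (positive).
#' @return Unrounded ratio; round with [round_half_away()] (2 dp) for display.
#' @examples
#' pdd_ratio(811.76, 400) # 2.0294
#' @export
pdd_ratio <- function(mean_pdd_mg, ddd_mg) {
  if (any(!is.finite(ddd_mg)) || any(ddd_mg <= 0)) {
    stop("ddd_mg must be positive", call. = FALSE)
  }
  mean_pdd_mg / ddd_mg
}

#' Excessive-dosing classification
#'
#' A PDD/DDD ratio strictly greater than 1.5 is classified as excessive
#' dosing. The threshold is strict: a ratio of exactly 1.50 is not excessive.
#' Classification uses the unrounded ratio, not its 2-dp display value.
#'
#' @param ratio Finite PDD/DDD ratio(s).
#' @return Logical vector.
#' @examples
#' is_excessive(c(2.03, 1.5, 0.44)) # TRUE FALSE FALSE
#' @export
is_excessive <- function(ratio) {
  if (any(!is.finite(ratio))) stop("ratio must be finite", call. = FALSE)
  ratio > 1.5
}

#' 95% confidence interval for a mean PDD
#'
#' t-based interval: `mean +/- qt(0.975, n - 1) * sd / sqrt(n)`. Degenerate
#' cases collapse to a point interval: a single value gives `(v, v)`, and a
#' zero-variance sample gives `(mean, mean)`.
#'
#' @param values Nonempty numeric vector of per-patient PDDs.
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' ci95(c(25, 25)) # 25 25
#' @export
ci95 <- function(values) {
  if (length(values) == 0) stop("ci95 requires at least one value", call. = FALSE)
  n <- length(values)
  m <- mean(values)
  if (n == 1) {
    return(c(low = m, high = m))
  }
  s <- stats::sd(values)
  if (s == 0) {
    return(c(low = m, high = m))
  }
  half <- stats::qt(0.975, df = n - 1) * s / sqrt(n)
  c(low = m - half, high = m + half)
}

#' Summarize one drug presentation into a utilization row
#'
#' @param exposures Exposure tibble (see [compute_exposures()]) restricted to
#'   one drug presentation.
#' @param registry A `drug_registry`; the presentation must be present.
#' @return One-row tibble: `n`, `drug`, `atc`, `route`, `form`, `ddd_mg`,
#'   `median_pdd`, `mean_pdd`, `ci_low`, `ci_high`, `mean_pdd_over_ddd`,
#'   `excessive` (all dose columns unrounded mg/day).
#' @export
summarize_drug <- function(exposures, registry) {
  if (nrow(exposures) == 0) stop("no exposures to summarize", call. = FALSE)
  if (dplyr::n_distinct(paste(exposures$atc, exposures$route, exposures$form)) > 1) {
    stop("summarize_drug expects exposures of a single drug presentation", call. = FALSE)
  }
  ddd <- lookup_ddd(registry, exposures$atc[1], exposures$route[1], exposures$form[1])
  pdds <- exposures$pdd_mg_per_day
  ci <- ci95(pdds)
  m <- mean(pdds)
  ratio <- pdd_ratio(m, ddd)
  tibble::tibble(
    n = length(pdds),
    drug = exposures$drug[1],
    atc = exposures$atc[1],
    route = exposures$route[1],
    form = exposures$form[1],
    ddd_mg = ddd,
    median_pdd = stats::median(pdds),
    mean_pdd = m,
    ci_low = ci[["low"]],
    ci_high = ci[["high"]],
    mean_pdd_over_ddd = ratio,
    excessive = is_excessive(ratio)
  )
}

#' Per-drug utilization table
#'
#' One [summarize_drug()] row per antipsychotic presentation with at least
#' one exposure, ordered by drug name. The prescription count column `n` is,
#' by default, the number of patient-presentation *exposures* (one per
#' patient per presentation); set `count_mode = "order"` (and supply `rx`) to
#' count raw prescription rows instead.
#'
#' @param exposures Exposure tibble from [compute_exposures()].
#' @param registry A `drug_registry`.
#' @param count_mode `"exposure"` (default) or `"order"`.
#' @param rx Resolved prescriptions; required when `count_mode = "order"`.
#' @return Tibble of utilization rows.
#' @export
summarize_utilization <- function(exposures, registry,
                                  count_mode = c("exposure", "order"),
                                  rx = NULL) {
  count_mode <- match.arg(count_mode)
  ap <- dplyr::filter(exposures, .data$is_antipsychotic)
  if (nrow(ap) == 0) {
    return(tibble::tibble(
      n = integer(0), drug = character(0), atc = character(0),
      route = character(0), form = character(0), ddd_mg = numeric(0),
      median_pdd = numeric(0), mean_pdd = numeric(0), ci_low = numeric(0),
      ci_high = numeric(0), mean_pdd_over_ddd = numeric(0),
      excessive = logical(0)
    ))
  }
  rows <- ap |>
    dplyr::group_by(.data$atc, .data$route, .data$form) |>
    dplyr::group_split() |>
    purrr::map(summarize_drug, registry = registry) |>
    purrr::list_rbind()
  if (count_mode == "order") {
    if (is.null(rx)) stop("count_mode = 'order' requires rx", call. = FALSE)
    orders <- rx |>
      dplyr::filter(.data$is_antipsychotic) |>
      dplyr::count(.data$atc, .data$route, .data$form, name = "n_orders")
    rows <- rows |>
      dplyr::left_join(orders, by = c("atc", "route", "form")) |>
      dplyr::mutate(n = dplyr::coalesce(.data$n_orders, 0L)) |>
      dplyr::select(-"n_orders")
  }
  dplyr::arrange(rows, .data$drug)
}
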