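#' Round half away from zero
#'
#' Decimal rounding used for all displayed report numbers. Unlike [round()]
#' (banker's rounding), ties are rounded away from zero, so `0.725` becomes
#' `0.73` at two decimals. Internal computations are never rounded; this is
#' applied only at serialization/display.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_away(0.725, 2) # 0.73
#' round_half_away(-0.725, 2) # -0.73
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  y <- abs(x) * m
  # nudge compensates binary representation of decimal inputs near .5 ties
  sign(x) * floor(y + 0.5 + 1e-8 * pmax(1, y)) / m
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Delimiter autodetection for the delimited-text interfaces: tab wins if the
# header line contains one, else comma.
detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_delim_auto <- function(path) {
  readr::read_delim(
    path,
    delim = detect_delim(path),
    show_col_types = FALSE,
    progress = FALSE,
    trim_ws = TRUE
  )
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}

as_date_strict <- function(x, what) {
  out <- tryCatch(as.Date(x), error = function(e) NA)
  if (anyNA(out) && !all(is.na(x))) {
    stop(sprintf("%s contains unparseable dates", what), call. = FALSE)
  }
  out
}
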