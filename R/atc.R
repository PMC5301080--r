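#' ATC code parsing and the DDD drug registry
#'
#' The WHO Anatomical Therapeutic Chemical (ATC) classification assigns every
#' drug a 7-character code (1 letter, 2 digits, 2 letters, 2 digits), e.g.
#' `N05AH02` for clozapine. Prefixes of length 1/3/4/5 address the anatomical,
#' therapeutic, pharmacological and chemical subgroup levels and are accepted
#' for group queries. The registry maps each drug *presentation* — the
#' `(atc, route, form)` triple — to its defined daily dose (DDD) in mg/day;
#' route and form are part of the key because WHO DDDs differ between oral and
#' long-acting presentations of the same chemical (risperidone 5 vs 2.7 mg).
#'
#' @name atc
NULL

# expected character class at each position of a full ATC code
.atc_class <- c("letter", "digit", "digit", "letter", "letter", "digit", "digit")
.atc_lengths <- c(1L, 3L, 4L, 5L, 7L)

#' Parse and validate ATC codes
#'
#' Accepts full 7-character codes or group prefixes of length 1, 3, 4 or 5.
#' Input is case-normalized to upper case. Malformed codes (wrong length or a
#' character of the wrong class) raise an error naming the offending position.
#'
#' @param text Character vector of candidate ATC codes.
#' @return Validated, upper-cased character vector.
#' @examples
#' parse_atc("N05AL05")
#' parse_atc("n05ax08") # "N05AX08"
#' @export
parse_atc <- function(text) {
  if (length(text) == 0 || any(is.na(text)) || any(!nzchar(text))) {
    stop("ATC code must be a nonempty string", call. = FALSE)
  }
  code <- toupper(trimws(text))
  for (i in seq_along(code)) {
    x <- code[[i]]
    n <- nchar(x)
    if (!n %in% .atc_lengths) {
      stop(sprintf(
        "invalid ATC code '%s': length %d is not one of %s",
        x, n, paste(.atc_lengths, collapse = "/")
      ), call. = FALSE)
    }
    chars <- strsplit(x, "")[[1]]
    for (pos in seq_len(n)) {
      ok <- if (.atc_class[[pos]] == "letter") {
        grepl("^[A-Z]$", chars[[pos]])
      } else {
        grepl("^[0-9]$", chars[[pos]])
      }
      if (!ok) {
        stop(sprintf(
          "invalid ATC code '%s': expected a %s at position %d, got '%s'",
          x, .atc_class[[pos]], pos, chars[[pos]]
        ), call. = FALSE)
      }
    }
  }
  code
}

#' Extract an ATC hierarchy level as a prefix
#'
#' @param code Validated ATC code(s), see [parse_atc()].
#' @param level Prefix length identifying the level: 1 (anatomical group),
#'   3 (therapeutic subgroup), 4 (pharmacological subgroup), 5 (chemical
#'   subgroup) or 7 (chemical substance).
#' @return Character vector of prefixes.
#' @examples
#' atc_level("N05AL05", 5) # "N05AL"
#' atc_level("N05AL05", 3) # "N05"
#' @export
atc_level <- function(code, level) {
  if (!level %in% .atc_lengths) {
    stop("level must be one of 1, 3, 4, 5, 7", call. = FALSE)
  }
  code <- parse_atc(code)
  if (any(nchar(code) < level)) {
    stop("code is shorter than the requested level", call. = FALSE)
  }
  substr(code, 1L, level)
}

#' Is a code an antipsychotic?
#'
#' True for codes under the `N05A` group, excluding the `N05AN` chemical
#' subgroup (lithium), which the ATC files under antipsychotics but which is
#' not an antipsychotic drug. Codes shorter than 4 characters cannot decide
#' membership and raise an error.
#'
#' @param code Character vector of ATC codes (length >= 4).
#' @return Logical vector.
#' @examples
#' is_antipsychotic("N05AH02") # clozapine, TRUE
#' is_antipsychotic("N05AN01") # lithium, FALSE
#' @export
is_antipsychotic <- function(code) {
  code <- parse_atc(code)
  if (any(nchar(code) < 4)) {
    stop(
      "ATC code shorter than 4 characters cannot decide antipsychotic membership",
      call. = FALSE
    )
  }
  startsWith(code, "N05A") & !startsWith(code, "N05AN")
}

normalize_drug_name <- function(name) {
  trimws(gsub("[^a-z0-9]+", " ", tolower(name)))
}

validate_registry <- function(df) {
  require_columns(df, c("atc", "name", "route", "form", "ddd_mg"), "drug registry")
  df <- tibble::as_tibble(df[, c("atc", "name", "route", "form", "ddd_mg")])
  df$atc <- parse_atc(df$atc)
  if (any(nchar(df$atc) != 7)) {
    stop("registry entries must carry full 7-character ATC codes", call. = FALSE)
  }
  bad_route <- setdiff(unique(df$route), c("oral", "injectable"))
  if (length(bad_route) > 0) {
    stop(sprintf("unknown route(s): %s", paste(bad_route, collapse = ", ")),
      call. = FALSE
    )
  }
  bad_form <- setdiff(unique(df$form), c("standard", "long_acting"))
  if (length(bad_form) > 0) {
    stop(sprintf("unknown form(s): %s", paste(bad_form, collapse = ", ")),
      call. = FALSE
    )
  }
  df$ddd_mg <- as.numeric(df$ddd_mg)
  if (any(!is.finite(df$ddd_mg)) || any(df$ddd_mg <= 0)) {
    stop("ddd_mg must be positive for every registry entry", call. = FALSE)
  }
  key <- paste(df$atc, df$route, df$form)
  if (anyDuplicated(key)) {
    stop(sprintf(
      "duplicate (atc, route, form) registry entries: %s",
      paste(unique(key[duplicated(key)]), collapse = "; ")
    ), call. = FALSE)
  }
  df$name_key <- normalize_drug_name(df$name)
  class(df) <- c("drug_registry", class(df))
  df
}

#' Read a drug registry from delimited text
#'
#' The registry file is comma- or tab-delimited (autodetected), UTF-8, with a
#' header. Required columns: `atc`, `name`, `route` (`oral`/`injectable`),
#' `form` (`standard`/`long_acting`), `ddd_mg` (DDD in mg/day). Extra columns
#' are ignored, so the file can be extended beyond antipsychotics without code
#' changes.
#'
#' @param path Path to the registry file.
#' @return A `drug_registry` tibble.
#' @export
read_drug_registry <- function(path) {
  validate_registry(read_delim_auto(path))
}

#' The default antipsychotic DDD registry
#'
#' Ships the 18 antipsychotic presentations observed in the reference
#' inpatient cohort (tiapride, dispensed both orally and by injection, is
#' stored once per route with the same DDD, giving 19 entries). DDDs are in
#' mg/day. The registry is fixture-defined — it reflects the presentations and
#' DDD values used by that cohort's analysis, not an authoritative WHO index
#' year.
#'
#' @return A `drug_registry` tibble.
#' @examples
#' default_registry()
#' @export
default_registry <- function() {
  read_drug_registry(
    system.file("extdata", "table3_registry.csv", package = "rxddd", mustWork = TRUE)
  )
}

#' Look up a DDD by drug presentation
#'
#' @param registry A `drug_registry`.
#' @param atc Full 7-character ATC code.
#' @param route `"oral"` or `"injectable"`.
#' @param form `"standard"` or `"long_acting"`.
#' @return The DDD in mg/day (positive scalar).
#' @examples
#' reg <- default_registry()
#' lookup_ddd(reg, "N05AL05", "oral", "standard") # amisulpride, 400
#' lookup_ddd(reg, "N05AX13", "injectable", "long_acting") # 2.5
#' @export
lookup_ddd <- function(registry, atc, route, form) {
  atc <- parse_atc(atc)
  hit <- registry$atc == atc & registry$route == route & registry$form == form
  if (!any(hit)) {
    near <- registry$atc[startsWith(registry$atc, substr(atc, 1, 5))]
    if (length(near) == 0) near <- registry$atc[startsWith(registry$atc, substr(atc, 1, 4))]
    stop(sprintf(
      "unknown drug presentation (%s, %s, %s); nearest registry codes: %s",
      atc, route, form,
      if (length(near)) paste(unique(near), collapse = ", ") else "none"
    ), call. = FALSE)
  }
  registry$ddd_mg[hit][[1]]
}
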