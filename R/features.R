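# Per-patient-per-year clinical feature vectors extracted from consolidated
# bundles: demographics, respiratory ED/inpatient visit counts, medication
# and condition flags.

#' Feature-extraction configuration
#'
#' Code sets are configuration, not code: respiratory diagnosis codes (ICD-10
#' prefixes; a code matches when any configured prefix starts it), condition
#' code sets, medication name substrings (matched case-insensitively), and
#' maps from source race/ethnicity codes to display labels.  The defaults are
#' small illustrative sets; studies supply their own.
#'
#' @param respiratory_codes Diagnosis-code prefixes counted as respiratory.
#' @param condition_sets Named list of code-prefix vectors; each yields a 0/1
#'   flag column named `cond_<name>`.
#' @param medications Character vector of drug-name substrings; each yields a
#'   0/1 flag column named `med_<name>`.
#' @param race_map,ethnicity_map Named character vectors mapping source codes
#'   to display labels; unmapped codes pass through unchanged.
#' @return A `feature_config` list.
#' @export
feature_config <- function(respiratory_codes = c("J00", "J06", "J18", "J20",
                                                 "J21", "J22", "J44", "J45"),
                           condition_sets = list(asthma_like = c("J44", "J45")),
                           medications = "prednisone",
                           race_map = c("2054-5" = "AfricanAmerican",
                                        "2106-3" = "Caucasian"),
                           ethnicity_map = c("2135-2" = "Hispanic",
                                             "2186-5" = "NotHispanic")) {
  if (!length(respiratory_codes)) {
    stop_clinexpo("respiratory code set must be non-empty", "config_error")
  }
  structure(
    list(
      respiratory_codes = respiratory_codes,
      condition_sets = condition_sets,
      medications = medications,
      race_map = race_map,
      ethnicity_map = ethnicity_map
    ),
    class = "feature_config"
  )
}

code_in_set <- function(codes, prefixes) {
  any(purrr::map_lgl(codes, function(cd) any(startsWith(cd, prefixes))))
}

#' Count respiratory emergency/inpatient visits in a calendar year
#'
#' An encounter qualifies when its class is emergency or inpatient, its start
#' falls in the calendar year (half-open `[Jan 1, next Jan 1)`), and it
#' carries at least one diagnosis code in the configured set.  Multiple
#' qualifying diagnoses on one encounter count once: the count is a count of
#' visits, matching the "two or more annual emergency department or inpatient
#' visits" exacerbation threshold.
#'
#' @param bundle A `patient_bundle`.
#' @param code_set Character vector of diagnosis-code prefixes (non-empty).
#' @param year Integer calendar year.
#' @return Integer count.
#' @export
count_respiratory_visits <- function(bundle, code_set, year) {
  if (!length(code_set)) {
    stop_clinexpo("empty diagnosis code set", "config_error")
  }
  e <- bundle$encounters
  if (!nrow(e)) return(0L)
  in_year <- iso_year(e$start) == year & !is.na(e$start)
  in_class <- e$class %in% c("emergency", "inpatient")
  has_code <- purrr::map_lgl(e$diagnosis_codes, code_in_set, prefixes = code_set)
  sum(in_year & in_class & has_code, na.rm = TRUE)
}

#' Extract the clinical feature vector for one patient-year
#'
#' @param bundle A `patient_bundle`.
#' @param year Integer study year.
#' @param config A [feature_config()].
#' @return One-row tibble: `patient_id`, `year`, `age_in_years` (completed
#'   years at Jan 1; `NA` with `invalid_age = 1` when the birth date
#'   postdates Jan 1), `sex`, `race`, `ethnicity`,
#'   `total_ed_inpatient_visits`, one `med_*` flag per configured medication
#'   (1 iff any order authored in the year), and one `cond_*` flag per
#'   configured condition set (1 iff any matching condition with onset in or
#'   before the year).
#' @export
to_vector <- function(bundle, year, config = feature_config()) {
  dem <- bundle$demographics
  remap <- function(x, map) {
    if (!is.na(x) && x %in% names(map)) unname(map[[x]]) else x
  }
  jan1 <- as.Date(sprintf("%d-01-01", year))
  bd <- suppressWarnings(as.Date(dem$birth_date))
  invalid <- !is.na(bd) && bd > jan1
  age <- if (is.na(bd) || invalid) {
    NA_integer_
  } else {
    as.integer(floor(as.numeric(jan1 - bd) / 365.2425))
  }

  row <- list(
    patient_id = bundle$patient_id,
    year = as.integer(year),
    age_in_years = age,
    invalid_age = as.integer(invalid),
    sex = dem$sex %||% NA_character_,
    race = remap(dem$race, config$race_map),
    ethnicity = remap(dem$ethnicity, config$ethnicity_map),
    total_ed_inpatient_visits =
      count_respiratory_visits(bundle, config$respiratory_codes, year)
  )

  meds <- bundle$medications
  for (m in config$medications) {
    hit <- nrow(meds) > 0 &&
      any(grepl(m, meds$drug, ignore.case = TRUE) &
            iso_year(meds$authored) == year, na.rm = TRUE)
    row[[paste0("med_", tolower(m))]] <- as.integer(hit)
  }
  cond <- bundle$conditions
  for (nm in names(config$condition_sets)) {
    hit <- nrow(cond) > 0 && any(
      purrr::map_lgl(cond$code, ~ code_in_set(.x, config$condition_sets[[nm]])) &
        (is.na(iso_year(cond$onset)) | iso_year(cond$onset) <= year)
    )
    row[[paste0("cond_", nm)]] <- as.integer(hit)
  }
  fast_tbl(row)
}

#' Clinical feature table over a bundle set
#'
#' One row per (patient, study year); no duplicate keys by construction.
#'
#' @param bundles Output of [consolidate()].
#' @param years Integer vector of study years.
#' @inheritParams to_vector
#' @return Tibble of [to_vector()] rows.
#' @export
clinical_features <- function(bundles, years, config = feature_config()) {
  purrr::map_dfr(as.integer(years), function(y) {
    purrr::map_dfr(bundles, to_vector, year = y, config = config)
  })
}
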