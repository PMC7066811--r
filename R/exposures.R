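# Pollutant-grid preprocessing: temporal aggregation of hourly/daily/annual
# series and nearest-cell attachment of exposures to patient geocodes.

#' Read an exposure grid from long-format CSV
#'
#' Expected columns: `cell_id`, `lat`, `lon` (cell center, WGS84 decimal
#' degrees), `timestamp` (ISO 8601: `YYYY` for annual, `YYYY-MM-DD` for
#' daily, `YYYY-MM-DDThh:00:00` for hourly), `pollutant`, `value`.
#'
#' @param path CSV file path.
#' @param native_resolution `"hourly"`, `"daily"`, or `"annual"`; inferred
#'   from the timestamp format when `NULL`.
#' @return An `exposure_grid`: list with `cells` (tibble `cell_id`, `lat`,
#'   `lon`), `series` (long tibble), and `native_resolution`.
#' @export
read_exposure_grid <- function(path, native_resolution = NULL) {
  series <- readr::read_csv(
    path,
    col_types = readr::cols(
      cell_id = readr::col_character(), lat = readr::col_double(),
      lon = readr::col_double(), timestamp = readr::col_character(),
      pollutant = readr::col_character(), value = readr::col_double()
    )
  )
  if (is.null(native_resolution)) {
    ts <- series$timestamp[1] %||% ""
    native_resolution <-
      if (grepl("T", ts)) "hourly" else if (nchar(ts) >= 10) "daily" else "annual"
  }
  cells <- dplyr::distinct(series, .data$cell_id, .data$lat, .data$lon)
  if (anyDuplicated(cells$cell_id)) {
    stop_clinexpo("grid cells with inconsistent centers", "grid_error")
  }
  structure(
    list(
      cells = dplyr::arrange(cells, .data$cell_id),
      series = dplyr::select(series, -"lat", -"lon"),
      native_resolution = match.arg(native_resolution, c("hourly", "daily", "annual"))
    ),
    class = "exposure_grid"
  )
}

#' Aggregate one cell-day of hourly values to a daily mean and max
#'
#' The daily statistic is reported only when at least 75% of the 24 hours are
#' present (the standard completeness rule in air-quality summaries);
#' otherwise both statistics are missing and missingness propagates.
#'
#' @param hourly Numeric vector of up to 24 hourly values; gaps may appear as
#'   absent entries or `NA`.
#' @param min_coverage Minimum fraction of 24 hours that must be present.
#' @return One-row tibble `mean`, `max` (both `NA` under-coverage).
#' @export
aggregate_daily <- function(hourly, min_coverage = 0.75) {
  v <- hourly[!is.na(hourly)]
  if (length(v) < min_coverage * 24) {
    return(tibble::tibble(mean = NA_real_, max = NA_real_))
  }
  tibble::tibble(mean = mean(v), max = max(v))
}

#' Aggregate daily means for one cell-year
#'
#' @param daily Numeric vector of daily means for a year (`NA` gaps allowed).
#' @return One-row tibble `avg_daily` (mean of non-missing daily means) and
#'   `max_daily` (their max); both `NA` when every day is missing.
#' @export
aggregate_annual <- function(daily) {
  v <- daily[!is.na(daily)]
  if (!length(v)) {
    return(tibble::tibble(avg_daily = NA_real_, max_daily = NA_real_))
  }
  tibble::tibble(avg_daily = mean(v), max_daily = max(v))
}

# Characteristic spacing of a grid: the smallest distance between two
# distinct cell centers (meters).
grid_spacing <- function(grid) {
  cells <- grid$cells
  if (nrow(cells) < 2) return(Inf)
  mins <- purrr::map_dbl(seq_len(nrow(cells)), function(i) {
    d <- geosphere::distHaversine(
      c(cells$lon[i], cells$lat[i]), cbind(cells$lon[-i], cells$lat[-i])
    )
    min(d)
  })
  min(mins)
}

#' Assign a point to its nearest grid cell
#'
#' Nearest cell center by great-circle (haversine) distance; ties go to the
#' lexicographically smallest `cell_id`.  A point farther than the coverage
#' radius from every center is out of coverage.
#'
#' @param grid An `exposure_grid`.
#' @param lat,lon Point coordinates (WGS84 decimal degrees); vectorized.
#' @param coverage_radius Meters; default 1.5 times the grid spacing.
#' @return Character vector of cell ids, `NA` where out of coverage (a
#'   missing-exposure signal).
#' @export
lookup_cell <- function(grid, lat, lon, coverage_radius = NULL) {
  cells <- grid$cells
  if (!nrow(cells)) stop_clinexpo("empty exposure grid", "grid_error")
  if (is.null(coverage_radius)) coverage_radius <- 1.5 * grid_spacing(grid)
  # cells are sorted by cell_id, so which.min's first-minimum rule is the
  # lexicographic tie-break.
  purrr::map2_chr(lat, lon, function(la, lo) {
    if (is.na(la) || is.na(lo)) return(NA_character_)
    d <- geosphere::distHaversine(c(lo, la), cbind(cells$lon, cells$lat))
    i <- which.min(d)
    if (d[i] > coverage_radius) NA_character_ else cells$cell_id[i]
  })
}

# Per cell/pollutant annual exposure statistics for one year, honoring the
# grid's native resolution: hourly series are first reduced to daily means
# (75% completeness rule), daily series are used as-is, annual values pass
# through as both statistics.
annual_cell_stats <- function(grid, year, min_coverage = 0.75) {
  s <- grid$series
  s <- s[!is.na(s$value) & iso_year(s$timestamp) == year, , drop = FALSE]
  if (grid$native_resolution == "annual") {
    return(dplyr::transmute(
      s, .data$cell_id, .data$pollutant,
      avg_daily = .data$value, max_daily = .data$value
    ))
  }
  if (grid$native_resolution == "hourly") {
    s <- s |>
      dplyr::mutate(date = substr(.data$timestamp, 1, 10)) |>
      dplyr::summarise(
        value = if (dplyr::n() >= min_coverage * 24) mean(.data$value) else NA_real_,
        .by = c("cell_id", "pollutant", "date")
      )
  }
  s |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::summarise(
      avg_daily = mean(.data$value), max_daily = max(.data$value),
      .by = c("cell_id", "pollutant")
    )
}

#' Attach annual exposure statistics to a clinical feature table
#'
#' Each (patient, year) row is assigned the grid cell nearest its residence
#' geocode and receives, per pollutant, the mean and max over the year of the
#' cell's daily means (`<pollutant>_avg_daily`, `<pollutant>_max_daily`).
#' Rows with a missing geocode or an out-of-coverage location are retained
#' with missing exposures; the join never duplicates rows.
#'
#' @param features Tibble with at least `patient_id` and `year`.
#' @param geocodes Tibble `patient_id`, `lat`, `lon`.
#' @param grid An `exposure_grid`.
#' @param coverage_radius Meters; see [lookup_cell()].
#' @param min_coverage Hourly completeness fraction; see [aggregate_daily()].
#' @return Tibble `patient_id`, `year`, one column pair per pollutant.
#' @export
attach_exposures <- function(features, geocodes, grid,
                             coverage_radius = NULL, min_coverage = 0.75) {
  keys <- dplyr::distinct(features, .data$patient_id, .data$year)
  geo <- dplyr::distinct(geocodes, .data$patient_id, .keep_all = TRUE)
  keys <- dplyr::left_join(keys, geo[c("patient_id", "lat", "lon")], by = "patient_id")
  cell_of <- dplyr::distinct(keys, .data$lat, .data$lon)
  cell_of$cell_id <- lookup_cell(grid, cell_of$lat, cell_of$lon, coverage_radius)
  keys <- dplyr::left_join(keys, cell_of, by = c("lat", "lon"))

  out <- purrr::map_dfr(unique(keys$year), function(y) {
    stats <- annual_cell_stats(grid, y, min_coverage)
    wide <- tidyr::pivot_wider(
      stats,
      names_from = "pollutant",
      values_from = c("avg_daily", "max_daily"),
      names_glue = "{pollutant}_{.value}"
    )
    dplyr::left_join(keys[keys$year == y, ], wide, by = "cell_id")
  })
  dplyr::select(out, -"lat", -"lon", -"cell_id")
}
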