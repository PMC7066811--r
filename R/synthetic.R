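# Deterministic generators for every input family the pipeline consumes:
# FHIR resources, pollutant grids, road networks, census polygons, and ACS
# tables, with a plantable clinical-exposure association so the end-to-end
# pipeline and its statistics can be exercised with no external data.

#' Specification of a synthetic study fixture
#'
#' One seed drives everything; each generator derives its own substream from
#' a fixed offset, so adding a generator never perturbs the others.  The
#' planted effect makes patients residing in `high_exposure_region` (a
#' sub-bbox, by default the western half of the study area) both breathe
#' higher PM2.5 and exacerbate (reach two or more annual ED/inpatient
#' respiratory visits) with higher probability, emulating the qualitative
#' exposure-outcome association the pipeline exists to surface.
#'
#' @param seed Integer master seed.
#' @param n_patients Cohort size (> 0).
#' @param bbox `c(lat_min, lat_max, lon_min, lon_max)` in WGS84 degrees.
#' @param grid_shape `c(rows, cols)` of the pollutant grid (also used for
#'   the census-unit partition).
#' @param years Character vector of study years.
#' @param high_exposure_region Sub-bbox, same layout as `bbox`.
#' @param baseline_exacerbation_prob,high_exposure_exacerbation_prob Planted
#'   annual exacerbation probabilities outside/inside the high region.
#' @param prednisone_prob Length-2 probabilities of an in-year prednisone
#'   order given (no exacerbation, exacerbation); defaults 0.10/0.17, the
#'   order of magnitude seen in asthma cohorts.
#' @param pm25_mean Length-2 daily PM2.5 means (ug/m3) for (low, high)
#'   region cells; defaults 7 and 14, spanning typical US urban levels.
#' @param pm25_sd Daily noise standard deviation.
#' @param resolution Native grid resolution: `"daily"` (default),
#'   `"hourly"`, or `"annual"`.
#' @param n_days Days simulated per year (365 by default; small values keep
#'   hourly fixtures light).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L,
                         n_patients = 2000L,
                         bbox = c(35, 36, -80, -79),
                         grid_shape = c(4L, 4L),
                         years = "2010",
                         high_exposure_region = c(35, 36, -80, -79.5),
                         baseline_exacerbation_prob = 0.1,
                         high_exposure_exacerbation_prob = 0.4,
                         prednisone_prob = c(0.10, 0.17),
                         pm25_mean = c(7, 14),
                         pm25_sd = 2,
                         resolution = c("daily", "hourly", "annual"),
                         n_days = 365L) {
  if (n_patients <= 0) stop_clinexpo("n_patients must be positive", "spec_error")
  stopifnot(
    bbox[1] < bbox[2], bbox[3] < bbox[4],
    baseline_exacerbation_prob >= 0, baseline_exacerbation_prob <= 1,
    high_exposure_exacerbation_prob >= baseline_exacerbation_prob,
    high_exposure_exacerbation_prob <= 1
  )
  structure(
    list(
      seed = as.integer(seed), n_patients = as.integer(n_patients),
      bbox = bbox, grid_shape = as.integer(grid_shape), years = as.character(years),
      high_exposure_region = high_exposure_region,
      baseline_exacerbation_prob = baseline_exacerbation_prob,
      high_exposure_exacerbation_prob = high_exposure_exacerbation_prob,
      prednisone_prob = prednisone_prob,
      pm25_mean = pm25_mean, pm25_sd = pm25_sd,
      resolution = match.arg(resolution), n_days = as.integer(n_days)
    ),
    class = "fixture_spec"
  )
}

in_region <- function(lat, lon, region) {
  lat >= region[1] & lat <= region[2] & lon >= region[3] & lon <= region[4]
}

random_dates <- function(n, year) {
  days <- sample.int(365L, n, replace = TRUE) - 1L
  format(as.Date(sprintf("%s-01-01", year)) + days, "%Y-%m-%d")
}

#' Generate a synthetic FHIR cohort
#'
#' Writes one NDJSON file of FHIR R4 resources (Patient, Encounter,
#' Condition, MedicationRequest).  Patients are placed uniformly in the
#' bbox; those inside the high-exposure region exacerbate with the planted
#' high probability.  Exacerbating patients receive two or more in-year
#' emergency/inpatient encounters with respiratory diagnosis codes; all
#' patients also carry noise encounters (ambulatory, or non-respiratory).
#' Deterministic: the same spec yields byte-identical output.
#'
#' @param spec A [fixture_spec()].
#' @param path Output NDJSON path.
#' @return `path`, invisibly; attribute `truth` carries a tibble of the
#'   planted per-patient state (region, exacerbation, visit count).
#' @export
generate_cohort <- function(spec, path) {
  set.seed(spec$seed + 1L)
  n <- spec$n_patients
  pid <- sprintf("p%05d", seq_len(n))
  lat <- runif(n, spec$bbox[1], spec$bbox[2])
  lon <- runif(n, spec$bbox[3], spec$bbox[4])
  high <- in_region(lat, lon, spec$high_exposure_region)
  age <- sample(2:95, n, replace = TRUE)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  race <- sample(c("2054-5", "2106-3"), n, replace = TRUE)
  year <- spec$years[1]
  byear <- as.integer(year) - age
  birth <- sprintf("%04d-%02d-%02d", byear,
                   sample.int(12L, n, replace = TRUE),
                   sample.int(28L, n, replace = TRUE))

  p_ex <- ifelse(high, spec$high_exposure_exacerbation_prob,
                 spec$baseline_exacerbation_prob)
  exac <- rbinom(n, 1L, p_ex) == 1L
  resp_visits <- ifelse(exac, 2L + rpois(n, 1), rbinom(n, 1L, 0.3))
  pred <- rbinom(n, 1L, spec$prednisone_prob[1 + exac]) == 1L

  resp_codes <- c("J45.21", "J45.41", "J45.901", "J45.909", "J44.1", "J18.9")
  other_codes <- c("E11.9", "I10", "M54.5", "K21.9")

  con <- file(path, open = "wb")
  on.exit(close(con))
  emit <- function(x) {
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), con)
  }
  truth <- tibble::tibble(patient_id = pid, lat = lat, lon = lon,
                          high_region = high, exacerbated = exac,
                          resp_visits = as.integer(resp_visits),
                          prednisone = pred, race = race)
  for (i in seq_len(n)) {
    emit(list(
      resourceType = "Patient", id = pid[i], gender = sex[i], birthDate = birth[i],
      extension = list(
        list(url = "http://example.org/fhir/race", valueString = race[i]),
        list(url = "http://example.org/fhir/ethnicity", valueString = "2186-5")
      ),
      address = list(list(
        use = "home",
        period = list(start = sprintf("%d-01-01", as.integer(year) - 3L)),
        extension = list(list(
          url = GEOLOC_URL,
          extension = list(
            list(url = "latitude", valueDecimal = lat[i]),
            list(url = "longitude", valueDecimal = lon[i])
          )
        ))
      ))
    ))
    emit(list(
      resourceType = "Condition", id = sprintf("%s-cond", pid[i]),
      subject = list(reference = paste0("Patient/", pid[i])),
      code = list(coding = list(list(system = "icd10", code = "J45.909"))),
      onsetDateTime = sprintf("%d-06-15", byear[i] + 1L)
    ))
    nv <- resp_visits[i]
    if (nv > 0) {
      starts <- sort(random_dates(nv, year))
      classes <- sample(c("EMER", "IMP"), nv, replace = TRUE, prob = c(0.7, 0.3))
      for (k in seq_len(nv)) {
        emit(list(
          resourceType = "Encounter", id = sprintf("%s-e%d", pid[i], k),
          subject = list(reference = paste0("Patient/", pid[i])),
          class = list(system = "v3-ActCode", code = classes[k]),
          period = list(start = paste0(starts[k], "T08:00:00")),
          reasonCode = list(list(coding = list(list(
            system = "icd10", code = sample(resp_codes, 1)
          ))))
        ))
      }
    }
    # noise: an ambulatory visit with a non-respiratory code
    if (runif(1) < 0.5) {
      emit(list(
        resourceType = "Encounter", id = sprintf("%s-amb", pid[i]),
        subject = list(reference = paste0("Patient/", pid[i])),
        class = list(system = "v3-ActCode", code = "AMB"),
        period = list(start = paste0(random_dates(1, year), "T10:00:00")),
        reasonCode = list(list(coding = list(list(
          system = "icd10", code = sample(other_codes, 1)
        ))))
      ))
    }
    if (pred[i]) {
      emit(list(
        resourceType = "MedicationRequest", id = sprintf("%s-rx", pid[i]),
        subject = list(reference = paste0("Patient/", pid[i])),
        medicationCodeableConcept = list(text = "prednisone 20 MG oral tablet"),
        authoredOn = random_dates(1, year)
      ))
    }
  }
  out <- path
  attr(out, "truth") <- truth
  invisible(out)
}

grid_centers <- function(spec) {
  rows <- spec$grid_shape[1]; cols <- spec$grid_shape[2]
  dlat <- (spec$bbox[2] - spec$bbox[1]) / rows
  dlon <- (spec$bbox[4] - spec$bbox[3]) / cols
  g <- expand.grid(r = seq_len(rows), c = seq_len(cols))
  tibble::tibble(
    cell_id = sprintf("c%02d%02d", g$r, g$c),
    lat = spec$bbox[1] + (g$r - 0.5) * dlat,
    lon = spec$bbox[3] + (g$c - 0.5) * dlon
  )
}

#' Generate a synthetic pollutant grid
#'
#' Long-format CSV of PM2.5 estimates over a regular grid of cell centers.
#' Cells inside the high-exposure region draw daily means around the high
#' planted mean, others around the low one; the hourly mode adds within-day
#' variation around each daily level, and the annual mode emits one value
#' per cell-year.
#'
#' @param spec A [fixture_spec()].
#' @param path Output CSV path.
#' @param resolution Overrides `spec$resolution` when given.
#' @return `path`, invisibly.
#' @export
generate_env_grid <- function(spec, path, resolution = NULL) {
  set.seed(spec$seed + 2L)
  resolution <- resolution %||% spec$resolution
  cells <- grid_centers(spec)
  cells$mu <- ifelse(in_region(cells$lat, cells$lon, spec$high_exposure_region),
                     spec$pm25_mean[2], spec$pm25_mean[1])
  rows <- purrr::map_dfr(spec$years, function(y) {
    if (resolution == "annual") {
      return(dplyr::mutate(cells, timestamp = y,
                           value = pmax(0.1, mu + stats::rnorm(dplyr::n(), 0, spec$pm25_sd / 4))))
    }
    days <- format(as.Date(sprintf("%s-01-01", y)) + seq_len(spec$n_days) - 1L, "%Y-%m-%d")
    daily <- tidyr::crossing(cells, date = days)
    daily$daily_mu <- pmax(0.1, daily$mu + stats::rnorm(nrow(daily), 0, spec$pm25_sd))
    if (resolution == "daily") {
      return(dplyr::transmute(daily, .data$cell_id, .data$lat, .data$lon,
                              timestamp = .data$date, value = .data$daily_mu))
    }
    hourly <- tidyr::crossing(daily, hour = 0:23)
    dplyr::transmute(
      hourly, .data$cell_id, .data$lat, .data$lon,
      timestamp = sprintf("%sT%02d:00:00", .data$date, .data$hour),
      value = pmax(0.05, .data$daily_mu + stats::rnorm(dplyr::n(), 0, spec$pm25_sd / 2))
    )
  })
  rows$pollutant <- "pm25"
  readr::write_csv(
    rows[c("cell_id", "lat", "lon", "timestamp", "pollutant", "value")], path
  )
  invisible(path)
}

#' Generate synthetic road, census, and ACS layers
#'
#' Roads: a lattice of LineStrings along the grid lines of the bbox, written
#' twice -- a census-geometry-like file carrying a `road_class` attribute and
#' a highway-monitoring-like file (the major axes only) carrying an `aadt`
#' traffic count -- so both nearest-road sources can run on shared geometry.
#' Census: a rectangular polygon partition of the bbox (same shape as the
#' pollutant grid) with an ACS table keyed by `unit_id` carrying a household
#' income bracket, residential density, and an urban/rural `ur` field.
#'
#' @param spec A [fixture_spec()].
#' @param roads_path,highways_path,census_path,acs_path Output paths.
#' @return Named list of the four paths, invisibly.
#' @export
generate_geo_layers <- function(spec, roads_path, highways_path,
                                census_path, acs_path) {
  set.seed(spec$seed + 3L)
  b <- spec$bbox
  rows <- spec$grid_shape[1]; cols <- spec$grid_shape[2]
  lat_lines <- seq(b[1], b[2], length.out = rows + 1)
  lon_lines <- seq(b[3], b[4], length.out = cols + 1)

  feats <- c(
    purrr::imap(lat_lines, function(la, i) {
      geojson_linestring(
        cbind(lon = c(b[3], b[4]), lat = c(la, la)),
        list(segment_id = sprintf("rh%02d", i),
             road_class = sample(c("residential", "secondary"), 1))
      )
    }),
    purrr::imap(lon_lines, function(lo, i) {
      geojson_linestring(
        cbind(lon = c(lo, lo), lat = c(b[1], b[2])),
        list(segment_id = sprintf("rv%02d", i),
             road_class = sample(c("residential", "secondary"), 1))
      )
    })
  )
  write_geojson(feats, roads_path)

  mid_lat <- (b[1] + b[2]) / 2; mid_lon <- (b[3] + b[4]) / 2
  hw <- list(
    geojson_linestring(cbind(lon = c(b[3], b[4]), lat = c(mid_lat, mid_lat)),
                       list(segment_id = "hw01", aadt = sample(20000:60000, 1))),
    geojson_linestring(cbind(lon = c(mid_lon, mid_lon), lat = c(b[1], b[2])),
                       list(segment_id = "hw02", aadt = sample(20000:60000, 1)))
  )
  write_geojson(hw, highways_path)

  units <- list()
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      la0 <- lat_lines[r]; la1 <- lat_lines[r + 1]
      lo0 <- lon_lines[cc]; lo1 <- lon_lines[cc + 1]
      ring <- cbind(lon = c(lo0, lo1, lo1, lo0, lo0),
                    lat = c(la0, la0, la1, la1, la0))
      units[[length(units) + 1L]] <- geojson_polygon(
        list(ring), list(unit_id = sprintf("u%02d%02d", r, cc))
      )
    }
  }
  write_geojson(units, census_path)

  ids <- purrr::map_chr(units, ~ .x$properties$unit_id)
  acs <- tibble::tibble(
    unit_id = ids,
    income_bracket = sample(c("<25k", "25-50k", "50-100k", ">100k"),
                            length(ids), replace = TRUE),
    residential_density = round(runif(length(ids), 50, 5000), 1),
    ur = sample(c("urban", "rural"), length(ids), replace = TRUE)
  )
  readr::write_csv(acs, acs_path)
  invisible(list(roads = roads_path, highways = highways_path,
                 census = census_path, acs = acs_path))
}

#' Generate the complete fixture set for a study
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created).
#' @return Named list of all generated paths.
#' @export
generate_fixtures <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  generate_cohort(spec, p("resources.ndjson"))
  generate_env_grid(spec, p("pm25_grid.csv"))
  generate_geo_layers(spec, p("roads.geojson"), p("highways.geojson"),
                      p("census.geojson"), p("acs.csv"))
  list(
    fhir = p("resources.ndjson"), grid = p("pm25_grid.csv"),
    roads = p("roads.geojson"), highways = p("highways.geojson"),
    census = p("census.geojson"), acs = p("acs.csv")
  )
}
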