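# Built-in pipeline plugins.  Each is a function(arguments, global) doing
# file-based I/O on the paths named in `arguments`, so that the output of one
# step feeds the next.  Relative paths are resolved against `global$workdir`
# when set.

resolve_path <- function(p, global) {
  wd <- global$workdir %||% NULL
  if (is.null(wd) || grepl("^(/|[A-Za-z]:)", p)) p else file.path(wd, p)
}

read_step_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
}

plugin_fhir <- function(args, global) {
  rp <- function(p) resolve_path(p, global)
  files <- if (dir.exists(rp(args$input))) {
    list.files(rp(args$input), pattern = "\\.ndjson$", full.names = TRUE)
  } else {
    rp(args$input)
  }
  bundles <- consolidate(sort(files))
  write_bundles(bundles, rp(args$output_dir))
  geo <- geocode_table(bundles, as.integer(args$year))
  readr::write_csv(geo, rp(args$geocodes_output))
  invisible(NULL)
}

plugin_tovector <- function(args, global) {
  rp <- function(p) resolve_path(p, global)
  bundles <- read_bundles(rp(args$input_dir))
  cfg_args <- args[intersect(names(args), c("respiratory_codes", "medications"))]
  cfg <- do.call(feature_config, purrr::map(cfg_args, ~ as.character(unlist(.x))))
  feats <- clinical_features(bundles, as.integer(args$year), config = cfg)
  readr::write_csv(feats, rp(args$output))
  invisible(NULL)
}

plugin_envdata <- function(args, global) {
  rp <- function(p) resolve_path(p, global)
  grid <- read_exposure_grid(rp(args$input), args$resolution %||% NULL)
  geo <- read_step_csv(rp(args$geocodes))
  keys <- tibble::tibble(patient_id = geo$patient_id, year = as.integer(args$year))
  out <- attach_exposures(keys, geo, grid,
                          coverage_radius = args$coverage_radius %||% NULL)
  readr::write_csv(out, rp(args$output))
  invisible(NULL)
}

make_plugin_nearest_road <- function(prefix) {
  function(args, global) {
    rp <- function(p) resolve_path(p, global)
    roads <- read_roads_geojson(rp(args$roads))
    geo <- read_step_csv(rp(args$geocodes))
    out <- nearest_road_table(geo, roads, prefix = args$prefix %||% prefix)
    readr::write_csv(out, rp(args$output))
    invisible(NULL)
  }
}

make_plugin_acs <- function(version) {
  function(args, global) {
    rp <- function(p) resolve_path(p, global)
    units <- read_census_geojson(rp(args$census))
    acs <- read_step_csv(rp(args$acs))
    geo <- read_step_csv(rp(args$geocodes))
    out <- census_acs_table(geo, units, acs, version = version)
    readr::write_csv(out, rp(args$output))
    invisible(NULL)
  }
}

plugin_csvtable <- function(args, global) {
  rp <- function(p) resolve_path(p, global)
  clinical <- read_step_csv(rp(args$clinical))
  sources <- list()
  for (nm in c("exposures", "roads", "highways", "acs")) {
    if (!is.null(args[[nm]])) sources[[nm]] <- read_step_csv(rp(args[[nm]]))
  }
  merged <- do.call(merge_sources, c(list(clinical), sources))
  bins <- purrr::map(args$bins %||% list(), unlist)
  binned <- apply_bins(merged, bins)
  deid <- deidentify(binned$data, deid_policy())
  year <- args$year %||% unique(clinical$year)[1]
  out_dir <- rp(args$output_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(deid, file.path(out_dir, sprintf("icees_features_%s.csv", year)))
  write_bins_manifest(binned$manifest, file.path(out_dir, sprintf("bins_%s.yaml", year)))
  invisible(NULL)
}

plugin_noop <- function(args, global) invisible(NULL)

#' Built-in plugin registry
#'
#' Maps plugin function names usable in a configuration's `step.function`
#' to their implementations: `FHIR` (consolidate resources, extract
#' geocodes), `ToVector` (clinical feature extraction), `EnvData`
#' (pollutant-grid exposure attachment), `NearestRoad`/`NearestRoad2` (the
#' two road sources, shared geometry core, different attributes),
#' `ACS`/`ACS2` (census polygon + attribute join; v2 adds the urban/rural
#' `ur` field), `CSVTable` (merge, bin, de-identify, write the integrated
#' feature table), and `NOOP`.
#'
#' @return Named list of plugin functions.
#' @export
default_plugins <- function() {
  list(
    FHIR = plugin_fhir,
    ToVector = plugin_tovector,
    EnvData = plugin_envdata,
    CSVTable = plugin_csvtable,
    ACS = make_plugin_acs(1),
    ACS2 = make_plugin_acs(2),
    NearestRoad = make_plugin_nearest_road("road"),
    NearestRoad2 = make_plugin_nearest_road("highway"),
    NOOP = plugin_noop
  )
}
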