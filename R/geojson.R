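# Minimal GeoJSON FeatureCollection reader/writer over jsonlite.  Roads are
# LineString features, census units Polygon/MultiPolygon; coordinates are
# [lon, lat] pairs in WGS84 decimal degrees, per the GeoJSON convention.

#' Read road segments from a GeoJSON FeatureCollection
#'
#' @param path GeoJSON file of LineString features.  The id property
#'   (`segment_id` or `id`) and all other properties are carried through.
#' @return Tibble with `segment_id`, a `coords` list column (matrices with
#'   columns `lon`, `lat`), and one column per property.
#' @export
read_roads_geojson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- purrr::map(fc$features, function(f) {
    if (!identical(f$geometry$type, "LineString")) return(NULL)
    coords <- do.call(rbind, purrr::map(f$geometry$coordinates, ~ as.numeric(unlist(.x))))
    colnames(coords) <- c("lon", "lat")
    if (nrow(coords) < 2 || any(!is.finite(coords))) {
      stop_clinexpo("road segment needs >= 2 finite vertices", "geometry_error")
    }
    props <- f$properties %||% list()
    sid <- as.character(props$segment_id %||% props$id %||% f$id)
    props$segment_id <- NULL; props$id <- NULL
    dplyr::bind_cols(
      tibble::tibble(segment_id = sid, coords = list(coords)),
      tibble::as_tibble(props)
    )
  })
  dplyr::bind_rows(rows)
}

#' Read census units from a GeoJSON FeatureCollection
#'
#' @param path GeoJSON file of Polygon or MultiPolygon features keyed by the
#'   `unit_id` (or `id`) property.
#' @return Tibble with `unit_id` and a `rings` list column; each element is a
#'   list of ring matrices (columns `lon`, `lat`, first vertex repeated last).
#' @export
read_census_geojson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ring_mat <- function(ring) {
    m <- do.call(rbind, purrr::map(ring, ~ as.numeric(unlist(.x))))
    colnames(m) <- c("lon", "lat")
    m
  }
  rows <- purrr::map(fc$features, function(f) {
    g <- f$geometry
    rings <- switch(
      g$type,
      Polygon = purrr::map(g$coordinates, ring_mat),
      MultiPolygon = purrr::flatten(purrr::map(g$coordinates, ~ purrr::map(.x, ring_mat))),
      return(NULL)
    )
    props <- f$properties %||% list()
    tibble::tibble(
      unit_id = as.character(props$unit_id %||% props$id %||% f$id),
      rings = list(rings)
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$unit_id)
}

# Write a FeatureCollection; `features` is a list of lists with `geometry`
# (type + coordinates) and `properties`.
write_geojson <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

geojson_linestring <- function(coords, properties) {
  list(
    type = "Feature",
    geometry = list(
      type = "LineString",
      coordinates = purrr::map(seq_len(nrow(coords)), ~ as.list(unname(coords[.x, ])))
    ),
    properties = properties
  )
}

geojson_polygon <- function(rings, properties) {
  list(
    type = "Feature",
    geometry = list(
      type = "Polygon",
      coordinates = purrr::map(rings, function(m) {
        purrr::map(seq_len(nrow(m)), ~ as.list(unname(m[.x, ])))
      })
    ),
    properties = properties
  )
}
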