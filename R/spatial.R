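# Nearest-road distance against polyline sources and census polygon / ACS
# attribute joins, all on WGS84 decimal-degree coordinates.

EARTH_RADIUS_M <- 6378137

# Project lon/lat to meters in a local equirectangular frame centered at
# (lat0, lon0).  At sub-10-km scales relevant to nearest-road exposure the
# error versus full geodesics is negligible.
local_xy <- function(lat, lon, lat0, lon0) {
  rad <- pi / 180
  cbind(
    x = (lon - lon0) * cos(lat0 * rad) * EARTH_RADIUS_M * rad,
    y = (lat - lat0) * EARTH_RADIUS_M * rad
  )
}

# Min distance (meters) from the origin of a local frame to a polyline given
# in that frame: perpendicular foot where it falls inside an edge, else the
# nearest vertex.
polyline_dist_origin <- function(xy) {
  n <- nrow(xy)
  x1 <- xy[-n, 1]; y1 <- xy[-n, 2]
  x2 <- xy[-1, 1]; y2 <- xy[-1, 2]
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- ifelse(len2 > 0, pmin(1, pmax(0, -(x1 * dx + y1 * dy) / len2)), 0)
  px <- x1 + t * dx; py <- y1 + t * dy
  sqrt(min(px^2 + py^2))
}

#' Nearest road segment to a point
#'
#' Finds the segment minimizing point-to-polyline distance: perpendicular to
#' an edge where the foot of the perpendicular lies within the edge,
#' otherwise the nearest vertex.  Distances are computed in meters in a local
#' planar projection centered at the query point; ties go to the smallest
#' `segment_id`.  The same core serves both road sources (census-geometry
#' TIGER-like and traffic-count HPMS-like): results on identical geometry
#' differ only in the attribute columns carried through.
#'
#' @param lat,lon Query point (WGS84 decimal degrees).
#' @param roads Tibble from [read_roads_geojson()]: `segment_id`, `coords`
#'   list column, attribute columns.
#' @return One-row tibble: `segment_id`, `distance_m`, and the segment's
#'   attributes.
#' @export
nearest_road <- function(lat, lon, roads) {
  if (!nrow(roads)) stop_clinexpo("empty road segment list", "config_error")
  hit <- nearest_road_many(lat, lon, roads)
  i <- hit$index
  dplyr::bind_cols(
    tibble::tibble(segment_id = roads$segment_id[i], distance_m = hit$distance),
    dplyr::select(roads[i, ], -"segment_id", -"coords")
  )
}

# Vectorized over query points: for each point, the row index in `roads` of
# the nearest segment (smallest segment_id on ties) and the distance in
# meters, each point's distances computed in its own local planar frame.
nearest_road_many <- function(lat, lon, roads) {
  rad <- pi / 180
  scale <- EARTH_RADIUS_M * rad
  coslat <- cos(lat * rad)
  best_d <- rep(Inf, length(lat))
  best_i <- rep(NA_integer_, length(lat))
  for (i in order(roads$segment_id)) {
    coords <- roads$coords[[i]]
    seg_d <- rep(Inf, length(lat))
    for (e in seq_len(nrow(coords) - 1L)) {
      x1 <- (coords[e, "lon"] - lon) * coslat * scale
      y1 <- (coords[e, "lat"] - lat) * scale
      x2 <- (coords[e + 1L, "lon"] - lon) * coslat * scale
      y2 <- (coords[e + 1L, "lat"] - lat) * scale
      dx <- x2 - x1; dy <- y2 - y1
      len2 <- dx^2 + dy^2
      t <- ifelse(len2 > 0, pmin(1, pmax(0, -(x1 * dx + y1 * dy) / len2)), 0)
      px <- x1 + t * dx; py <- y1 + t * dy
      seg_d <- pmin(seg_d, sqrt(px^2 + py^2))
    }
    better <- seg_d < best_d  # strict: ties keep the earlier (smaller) id
    best_d[better] <- seg_d[better]
    best_i[better] <- i
  }
  list(index = best_i, distance = best_d)
}

#' Nearest-road table for a set of geocoded patients
#'
#' @param geocodes Tibble `patient_id`, `lat`, `lon` (NA geocodes yield a row
#'   with missing results).
#' @param roads See [nearest_road()].
#' @param prefix Prefix for the result columns (e.g. `"roadway"`), so the two
#'   road sources can coexist in one merged table.
#' @return Tibble `patient_id`, `<prefix>_segment_id`, `<prefix>_distance_m`,
#'   plus prefixed attribute columns.
#' @export
nearest_road_table <- function(geocodes, roads, prefix = "road") {
  ok <- !is.na(geocodes$lat) & !is.na(geocodes$lon)
  hit <- nearest_road_many(geocodes$lat[ok], geocodes$lon[ok], roads)
  attrs <- dplyr::select(roads, -"coords")[hit$index, , drop = FALSE]
  attrs$distance_m <- hit$distance
  res <- tibble::tibble(patient_id = geocodes$patient_id)
  for (nm in names(attrs)) {
    col <- attrs[[nm]][rep(NA_integer_, nrow(res))]  # typed NA column
    col[ok] <- attrs[[nm]]
    res[[nm]] <- col
  }
  dplyr::relocate(
    dplyr::rename_with(res, ~ paste0(prefix, "_", .x), -"patient_id"),
    dplyr::all_of(paste0(prefix, c("_segment_id", "_distance_m"))),
    .after = "patient_id"
  )
}

# Even-odd ray-casting containment of (lat, lon) in a list of ring matrices.
point_in_rings <- function(lat, lon, rings) {
  inside <- FALSE
  for (m in rings) {
    xs <- m[, "lon"]; ys <- m[, "lat"]
    n <- length(xs)
    j <- n
    for (i in seq_len(n)) {
      if ((ys[i] > lat) != (ys[j] > lat)) {
        xint <- xs[i] + (lat - ys[i]) * (xs[j] - xs[i]) / (ys[j] - ys[i])
        if (lon < xint) inside <- !inside
      }
      j <- i
    }
  }
  inside
}

#' Assign points to census units by polygon containment
#'
#' Even-odd (ray-casting) rule; units are tested in `unit_id` order, so a
#' boundary point shared by adjacent polygons is assigned deterministically
#' to the unit earliest in that ordering.
#'
#' @param lat,lon Point coordinates; vectorized.
#' @param units Tibble from [read_census_geojson()] (`unit_id`, `rings`).
#' @return Character vector of unit ids; `NA` where no polygon contains the
#'   point (unassigned is a value, not an error).
#' @export
assign_census_unit <- function(lat, lon, units) {
  if (!nrow(units)) stop_clinexpo("empty census unit list", "config_error")
  units <- dplyr::arrange(units, .data$unit_id)
  purrr::map2_chr(lat, lon, function(la, lo) {
    if (is.na(la) || is.na(lo)) return(NA_character_)
    for (i in seq_len(nrow(units))) {
      if (point_in_rings(la, lo, units$rings[[i]])) return(units$unit_id[i])
    }
    NA_character_
  })
}

#' Attach socio-environmental (ACS-style) attributes by census unit
#'
#' @param unit_ids Character vector of unit ids (NA allowed).
#' @param acs Tibble keyed uniquely by `unit_id`; version 2 tables carry a
#'   `ur` ("urban"/"rural") column.
#' @param version 1 or 2; version 2 requires the `ur` field.
#' @return Tibble with one row per input id: the matched attributes, all-NA
#'   where the id is unmatched or NA.
#' @export
attach_acs <- function(unit_ids, acs, version = 1) {
  if (anyDuplicated(acs$unit_id)) {
    stop_clinexpo("ACS table has duplicate unit_id keys", "integrity_error")
  }
  if (version == 2 && !"ur" %in% names(acs)) {
    stop_clinexpo("ACS v2 table must include a `ur` field", "integrity_error")
  }
  dplyr::left_join(tibble::tibble(unit_id = unit_ids), acs, by = "unit_id")
}

#' Census + ACS attribute table for a set of geocoded patients
#'
#' @inheritParams nearest_road_table
#' @param units See [assign_census_unit()].
#' @param acs,version See [attach_acs()].
#' @return Tibble `patient_id`, `census_unit`, and the ACS attributes.
#' @export
census_acs_table <- function(geocodes, units, acs, version = 1) {
  ids <- assign_census_unit(geocodes$lat, geocodes$lon, units)
  out <- attach_acs(ids, acs, version)
  dplyr::bind_cols(
    tibble::tibble(patient_id = geocodes$patient_id),
    dplyr::rename(out, census_unit = "unit_id")
  )
}
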