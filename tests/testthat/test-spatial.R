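test_that("a point on a segment vertex is at distance zero", {
  roads <- make_roads(list(
    list(id = "s1", coords = cbind(lon = c(-79.5, -79.4), lat = c(35.2, 35.3))),
    list(id = "s2", coords = cbind(lon = c(-79.9, -79.8), lat = c(35.9, 35.8)))
  ))
  hit <- nearest_road(35.2, -79.5, roads)
  expect_equal(hit$segment_id, "s1")
  expect_equal(hit$distance_m, 0, tolerance = 1e-9)
  expect_equal(hit$road_class, "residential")

  expect_error(nearest_road(35, -79, make_roads(list())), class = "config_error")
})

test_that("nearest road matches a brute-force dense-sampling oracle", {
  # sub-10-km scale, the stated domain of the local planar projection
  set.seed(12)
  roads <- make_roads(random_segments(100, c(35.45, 35.55), c(-79.55, -79.45)))
  sampler <- dense_road_sampler(roads)
  lat <- runif(100, 35.45, 35.55); lon <- runif(100, -79.55, -79.45)
  for (i in seq_along(lat)) {
    hit <- nearest_road(lat[i], lon[i], roads)
    orc <- dense_road_oracle(lat[i], lon[i], sampler)
    # slack: oracle sampling resolution plus projection error at this scale
    tol <- max(sampler$resolution, 0.005 * orc$dist[orc$index])
    expect_lt(abs(hit$distance_m - min(orc$dist)), tol)
    # the chosen segment must be within tolerance of optimal
    expect_lt(orc$dist[match(hit$segment_id, roads$segment_id)] - min(orc$dist), tol)
  }
})

test_that("equidistant mirror segments resolve to the smaller segment_id", {
  roads <- make_roads(list(
    list(id = "s2", coords = cbind(lon = c(-79.51, -79.51), lat = c(35.1, 35.3))),
    list(id = "s1", coords = cbind(lon = c(-79.49, -79.49), lat = c(35.1, 35.3)))
  ))
  hit <- nearest_road(35.2, -79.5, roads)
  expect_equal(hit$segment_id, "s1")
})

test_that("nearest-road distance is stable under a small coordinate translation", {
  set.seed(13)
  segs <- lapply(1:20, function(i) {
    list(id = sprintf("s%02d", i),
         coords = cbind(lon = runif(2, -79.6, -79.4), lat = runif(2, 35.4, 35.6)))
  })
  roads <- make_roads(segs)
  shift <- function(df, dlat, dlon) {
    df$coords <- lapply(df$coords, function(m) {
      m[, "lat"] <- m[, "lat"] + dlat; m[, "lon"] <- m[, "lon"] + dlon; m
    })
    df
  }
  lat <- runif(25, 35.4, 35.6); lon <- runif(25, -79.6, -79.4)
  for (i in seq_along(lat)) {
    d0 <- nearest_road(lat[i], lon[i], roads)$distance_m
    d1 <- nearest_road(lat[i] + 0.01, lon[i] + 0.01,
                       shift(roads, 0.01, 0.01))$distance_m
    expect_lt(abs(d1 - d0), max(0.001 * d0, 1e-6))
  }
})

test_that("both road sources share the geometry core, differing in attributes", {
  coords <- cbind(lon = c(-79.6, -79.4), lat = c(35.5, 35.5))
  tiger <- tibble::tibble(segment_id = "t1", coords = list(coords),
                          road_class = "secondary")
  hpms <- tibble::tibble(segment_id = "t1", coords = list(coords),
                         aadt = 42000L)
  geo <- tibble::tibble(patient_id = "p", lat = 35.45, lon = -79.5)
  a <- nearest_road_table(geo, tiger, prefix = "road")
  b <- nearest_road_table(geo, hpms, prefix = "highway")
  expect_equal(a$road_distance_m, b$highway_distance_m)
  expect_equal(a$road_road_class, "secondary")
  expect_equal(b$highway_aadt, 42000L)
})

test_that("census assignment matches an independent point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  dir <- withr::local_tempdir()
  spec <- fixture_spec(seed = 20, grid_shape = c(4L, 4L))
  generate_geo_layers(spec, file.path(dir, "r.geojson"), file.path(dir, "h.geojson"),
                      file.path(dir, "c.geojson"), file.path(dir, "a.csv"))
  units <- read_census_geojson(file.path(dir, "c.geojson"))
  expect_equal(nrow(units), 16)

  # centroid of each unit maps to that unit
  for (i in seq_len(nrow(units))) {
    ring <- units$rings[[i]][[1]]
    expect_equal(assign_census_unit(mean(ring[-1, "lat"]), mean(ring[-1, "lon"]), units),
                 units$unit_id[i])
  }

  set.seed(21)
  lat <- runif(1000, 34.9, 36.1); lon <- runif(1000, -80.1, -78.9)
  got <- assign_census_unit(lat, lon, units)
  oracle <- rep(NA_character_, length(lat))
  for (i in seq_len(nrow(units))) {
    ring <- units$rings[[i]][[1]]
    inside <- mgcv::in.out(cbind(ring[, "lon"], ring[, "lat"]), cbind(lon, lat))
    oracle[inside & is.na(oracle)] <- units$unit_id[i]
  }
  expect_equal(got, oracle)
  # points outside the bbox are unassigned
  expect_true(all(is.na(got[lat > 36 | lon < -80.05])))
})

test_that("a polygon partition assigns every interior point to exactly one unit", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(seed = 22, grid_shape = c(3L, 3L))
  generate_geo_layers(spec, file.path(dir, "r.geojson"), file.path(dir, "h.geojson"),
                      file.path(dir, "c.geojson"), file.path(dir, "a.csv"))
  units <- read_census_geojson(file.path(dir, "c.geojson"))
  set.seed(23)
  lat <- runif(500, 35.001, 35.999); lon <- runif(500, -79.999, -79.001)
  n_containing <- vapply(seq_along(lat), function(i) {
    sum(vapply(units$rings, function(r) {
      clinexpo:::point_in_rings(lat[i], lon[i], r)
    }, TRUE))
  }, 0L)
  expect_true(all(n_containing == 1))
})

test_that("ACS joins are keyed lookups with version-2 urban/rural support", {
  acs <- tibble::tibble(unit_id = c("u1", "u2"), income_bracket = c("<25k", ">100k"),
                        ur = c("urban", "rural"))
  got <- attach_acs(c("u2", "u1", "zz", NA), acs, version = 2)
  expect_equal(got$ur, c("rural", "urban", NA, NA))
  expect_equal(got$income_bracket[3], NA_character_)

  expect_error(attach_acs("u1", dplyr::bind_rows(acs, acs[1, ])),
               "duplicate", class = "integrity_error")
  expect_error(attach_acs("u1", acs[, c("unit_id", "income_bracket")], version = 2),
               "ur", class = "integrity_error")

  set.seed(24)
  big <- tibble::tibble(unit_id = sprintf("u%02d", 1:50), val = rnorm(50))
  keys <- sample(c(big$unit_id, "nope"), 200, replace = TRUE)
  got2 <- attach_acs(keys, big)
  expect_equal(got2$val, big$val[match(keys, big$unit_id)])
})
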