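# Builds a grid through the public CSV interface.
write_grid_csv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "grid.csv")
  readr::write_csv(df, path)
  path
}

grid_df <- function(cell_id, lat, lon, timestamp, value, pollutant = "pm25") {
  tibble::tibble(cell_id = cell_id, lat = lat, lon = lon,
                 timestamp = timestamp, pollutant = pollutant, value = value)
}

test_that("daily aggregation honors the 75% completeness rule", {
  const <- aggregate_daily(rep(7.5, 24))
  expect_equal(const$mean, 7.5)
  expect_equal(const$max, 7.5)

  set.seed(1)
  v <- runif(24, 0, 40)
  agg <- aggregate_daily(v)
  expect_equal(agg$mean, mean(v))
  expect_equal(agg$max, max(v))

  expect_true(is.na(aggregate_daily(runif(10))$mean))   # 10/24 < 75%
  v18 <- runif(18)
  expect_equal(aggregate_daily(v18)$mean, mean(v18))    # 18/24 = 75%
  expect_true(is.na(aggregate_daily(c(v18, rep(NA, 6)))$max) == FALSE)
})

test_that("annual aggregation is the mean and max of daily means", {
  const <- aggregate_annual(rep(9, 365))
  expect_equal(c(const$avg_daily, const$max_daily), c(9, 9))

  set.seed(2)
  v <- rlnorm(365, 2, 0.4)
  agg <- aggregate_annual(v)
  expect_equal(agg$avg_daily, mean(v))
  expect_equal(agg$max_daily, max(v))
  expect_gte(agg$max_daily, agg$avg_daily)

  single <- aggregate_annual(5.5)
  expect_equal(c(single$avg_daily, single$max_daily), c(5.5, 5.5))
  expect_true(is.na(aggregate_annual(c(NA, NA))$avg_daily))
})

test_that("points map to the nearest cell center by great-circle distance", {
  centers <- expand.grid(r = 1:5, c = 1:5)
  cells <- grid_df(
    sprintf("g%d%d", centers$r, centers$c),
    lat = 35 + centers$r / 10, lon = -80 + centers$c / 10,
    timestamp = "2010", value = 1
  )
  grid <- read_exposure_grid(write_grid_csv(cells), "annual")

  expect_equal(lookup_cell(grid, 35.3, -79.8), "g32")

  # 500 random points vs an exhaustive haversine scan
  set.seed(3)
  lat <- runif(500, 35.05, 35.55); lon <- runif(500, -79.95, -79.45)
  got <- lookup_cell(grid, lat, lon)
  cc <- dplyr::arrange(dplyr::distinct(cells, cell_id, lat, lon), cell_id)
  oracle <- vapply(seq_along(lat), function(i) {
    d <- geosphere::distHaversine(c(lon[i], lat[i]), cbind(cc$lon, cc$lat))
    cc$cell_id[which.min(d)]
  }, "")
  expect_equal(got, oracle)

  # far away -> out of coverage
  expect_true(is.na(lookup_cell(grid, 45, -79.8)))
})

test_that("exposure attachment joins each patient to its nearest cell's year stats", {
  days <- format(as.Date("2010-01-01") + 0:364, "%Y-%m-%d")
  two_cells <- dplyr::bind_rows(
    grid_df("west", 35.5, -79.75, days, 12),
    grid_df("east", 35.5, -79.25, days, 6)
  )
  grid <- read_exposure_grid(write_grid_csv(two_cells), "daily")
  feats <- tibble::tibble(patient_id = c("a", "b", "c"), year = 2010L)
  geo <- tibble::tibble(patient_id = c("a", "b", "c"),
                        lat = c(35.5, 35.45, NA),
                        lon = c(-79.75, -79.3, NA))
  out <- attach_exposures(feats, geo, grid)
  expect_equal(nrow(out), 3)
  expect_equal(out$pm25_avg_daily[out$patient_id == "a"], 12)
  expect_equal(out$pm25_avg_daily[out$patient_id == "b"], 6)
  expect_true(is.na(out$pm25_avg_daily[out$patient_id == "c"]))
})

test_that("native resolutions are idempotent: pre-aggregated input passes through", {
  # same underlying daily series delivered at hourly vs daily resolution
  days <- format(as.Date("2010-01-01") + 0:9, "%Y-%m-%d")
  set.seed(4)
  daily_vals <- runif(10, 5, 15)
  hourly <- do.call(rbind, lapply(seq_along(days), function(i) {
    grid_df("c1", 35, -79, sprintf("%sT%02d:00:00", days[i], 0:23), daily_vals[i])
  }))
  g_hourly <- read_exposure_grid(write_grid_csv(hourly))
  expect_equal(g_hourly$native_resolution, "hourly")
  daily <- grid_df("c1", 35, -79, days, daily_vals)
  g_daily <- read_exposure_grid(write_grid_csv(daily))
  expect_equal(g_daily$native_resolution, "daily")

  feats <- tibble::tibble(patient_id = "p", year = 2010L)
  geo <- tibble::tibble(patient_id = "p", lat = 35, lon = -79)
  from_hourly <- attach_exposures(feats, geo, g_hourly)
  from_daily <- attach_exposures(feats, geo, g_daily)
  expect_equal(from_hourly$pm25_avg_daily, mean(daily_vals))
  expect_equal(from_hourly$pm25_max_daily, max(daily_vals))
  expect_equal(from_daily, from_hourly)

  annual <- grid_df("c1", 35, -79, "2010", 8.25)
  g_annual <- read_exposure_grid(write_grid_csv(annual))
  from_annual <- attach_exposures(feats, geo, g_annual)
  expect_equal(from_annual$pm25_avg_daily, 8.25)
  expect_equal(from_annual$pm25_max_daily, 8.25)
})

test_that("under-covered hourly days drop out of the annual statistics", {
  stamps <- c(sprintf("2010-03-01T%02d:00:00", 0:23),   # full day, value 10
              sprintf("2010-03-02T%02d:00:00", 0:9))    # 10 h only, value 99
  df <- grid_df("c1", 35, -79, stamps, c(rep(10, 24), rep(99, 10)))
  grid <- read_exposure_grid(write_grid_csv(df))
  feats <- tibble::tibble(patient_id = "p", year = 2010L)
  geo <- tibble::tibble(patient_id = "p", lat = 35, lon = -79)
  out <- attach_exposures(feats, geo, grid)
  expect_equal(out$pm25_avg_daily, 10)
  expect_equal(out$pm25_max_daily, 10)
})

test_that("joins never duplicate rows: one output row per (patient, year)", {
  spec <- fixture_spec(seed = 10, n_patients = 40, n_days = 30)
  dir <- withr::local_tempdir()
  generate_env_grid(spec, file.path(dir, "g.csv"))
  grid <- read_exposure_grid(file.path(dir, "g.csv"))
  feats <- tibble::tibble(patient_id = sprintf("p%02d", 1:40), year = 2010L)
  set.seed(11)
  geo <- tibble::tibble(patient_id = feats$patient_id,
                        lat = runif(40, 35, 36), lon = runif(40, -80, -79))
  out <- attach_exposures(feats, geo, grid)
  expect_equal(nrow(out), 40)
  expect_equal(anyDuplicated(out[c("patient_id", "year")]), 0L)
})
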