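test_that("source tables merge onto the clinical spine without row loss", {
  clinical <- tibble::tibble(patient_id = c("a", "b", "c"), year = 2010L,
                             visits = c(0L, 2L, 1L))
  expo <- tibble::tibble(patient_id = c("a", "b", "c"), year = 2010L,
                         pm25 = c(7, 12, 9))
  acs <- tibble::tibble(patient_id = c("a", "b"), ur = c("urban", "rural"))
  m <- merge_sources(clinical, exposures = expo, acs = acs)
  expect_equal(nrow(m), 3)
  expect_equal(m$pm25, c(7, 12, 9))
  expect_true(is.na(m$ur[m$patient_id == "c"]))

  dup <- dplyr::bind_rows(expo, expo[1, ])
  expect_error(merge_sources(clinical, exposures = dup),
               "exposures", class = "integrity_error")
})

test_that("merging equals a per-key dictionary-merge oracle on random input", {
  set.seed(30)
  ids <- sprintf("p%03d", 1:100)
  clinical <- tibble::tibble(patient_id = ids, year = 2010L, x = rnorm(100))
  src1 <- tibble::tibble(patient_id = sample(ids, 80), y = rnorm(80))
  src2 <- tibble::tibble(patient_id = sample(ids, 60), year = 2010L, z = rnorm(60))
  m <- merge_sources(clinical, s1 = src1, s2 = src2)
  expect_equal(nrow(m), 100)
  for (i in sample(100, 25)) {
    pid <- m$patient_id[i]
    expect_equal(m$y[i], if (pid %in% src1$patient_id) src1$y[src1$patient_id == pid] else NA_real_)
    expect_equal(m$z[i], if (pid %in% src2$patient_id) src2$z[src2$patient_id == pid] else NA_real_)
  }
})

test_that("quantile binning reproduces empirical quantile edges and balance", {
  b <- bin_quantiles(c(1, 2, 3, 4), 2)
  expect_equal(as.integer(table(b$labels)[b$levels]), c(2L, 2L))
  expect_equal(b$edges, c(1, 2.5, 4))

  set.seed(31)
  v <- runif(1000)
  b5 <- bin_quantiles(v, 5)
  counts <- table(b5$labels)
  expect_true(all(abs(counts - 200) <= 1))
  # independent sorted-order linear-interpolation oracle
  s <- sort(v); n <- length(s)
  oracle_q <- vapply(seq(0, 1, 0.2), function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }, 0)
  expect_equal(b5$edges, oracle_q, tolerance = 1e-12)
  # totals preserved through binning
  expect_equal(sum(counts), sum(!is.na(v)))
})

test_that("degenerate binning inputs collapse with a warning", {
  expect_warning(b <- bin_quantiles(rep(3, 50), 5), "collapsed")
  expect_equal(length(b$levels), 1)
  expect_true(all(b$labels == b$levels))
  expect_warning(bin_quantiles(rep(NA_real_, 5), 3), "missing")
})

test_that("range labels are right-closed with the minimum kept in the first bin", {
  b <- bin_quantiles(c(10, 20, 30, 40, 50, 60), 3)
  expect_equal(b$labels[1], b$levels[1])   # the minimum lands in bin 1
  expect_match(b$levels[2], "^\\(")
  expect_match(b$levels[2], "\\]$")
  # each value's label brackets contain it
  low <- clinexpo:::parse_bin_lower(b$labels)
  expect_true(all(low <= c(10, 20, 30, 40, 50, 60)))
})

test_that("de-identification strips identifiers, truncates dates, caps age", {
  df <- tibble::tibble(
    patient_id = "p1", lat = 35.1, lon = -79.2, year = 2010L,
    age_in_years = 92L, visit_date = "2010-03-04",
    total_ed_inpatient_visits = 3L
  )
  out <- deidentify(df, deid_policy(date_cols = "visit_date"))
  expect_false(any(c("patient_id", "lat", "lon") %in% names(out)))
  expect_equal(out$age_in_years, "90+")
  expect_equal(out$visit_date, 2010L)
  expect_equal(out$year, 2010L)

  # ages at or below 89 keep their value as a label
  df$age_in_years <- 89L
  expect_equal(deidentify(df, deid_policy(date_cols = "visit_date"))$age_in_years, "89")

  # idempotence
  once <- deidentify(df, deid_policy(date_cols = "visit_date"))
  expect_identical(deidentify(once, deid_policy(date_cols = "visit_date")), once)
})

test_that("policy gaps on identifier-like columns refuse to de-identify", {
  df <- tibble::tibble(year = 2010L, home_latitude = 35.0)
  expect_error(deidentify(df), "home_latitude", class = "policy_gap")
})

test_that("feature tables write deterministically and round-trip", {
  dir <- withr::local_tempdir()
  p0 <- file.path(dir, "empty.csv")
  write_feature_table(tibble::tibble(a = character(), b = integer()), p0)
  expect_equal(readLines(p0), "a,b")

  df <- tibble::tibble(b = c(2L, 1L), a = c("y", "x"), v = c(1.25, NA))
  p1 <- file.path(dir, "t1.csv"); p2 <- file.path(dir, "t2.csv")
  write_feature_table(df, p1)
  back <- readr::read_csv(p1, show_col_types = FALSE)
  expect_setequal(back$a, df$a)
  expect_equal(sort(back$b), sort(df$b))

  write_feature_table(df[c(2, 1), ], p2)   # permuted input, same bytes
  expect_equal(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  expect_error(
    write_feature_table(list(tibble::tibble(a = 1), tibble::tibble(b = 2)),
                        file.path(dir, "bad.csv")),
    class = "schema_error"
  )
})

test_that("binning a merged table records an interpretable manifest", {
  set.seed(33)
  df <- tibble::tibble(patient_id = sprintf("p%d", 1:60), year = 2010L,
                       pm25_avg_daily = rlnorm(60, 2, 0.3))
  res <- apply_bins(df, list(pm25_avg_daily = 3L))
  expect_equal(res$manifest$pm25_avg_daily$method, "quantile")
  expect_length(res$manifest$pm25_avg_daily$edges, 4)
  expect_true(all(res$data$pm25_avg_daily %in% res$manifest$pm25_avg_daily$levels))
  # per-bin counts sum to the non-missing total
  expect_equal(sum(table(res$data$pm25_avg_daily)), 60)

  path <- file.path(withr::local_tempdir(), "bins.yaml")
  write_bins_manifest(res$manifest, path)
  expect_equal(yaml::read_yaml(path)$pm25_avg_daily$method, "quantile")
})
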