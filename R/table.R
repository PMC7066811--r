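# Final integration: merge the per-source tables onto the clinical spine,
# bin/recode variables, de-identify (HIPAA Safe-Harbor style), and write the
# integrated feature table.

#' Merge clinical, exposure, road, and ACS tables
#'
#' Left-joins every source onto the clinical table by `(patient_id, year)`
#' (or `patient_id` for year-invariant sources), so the result has exactly
#' one row per clinical row; patients absent from a source keep their row
#' with that source's fields missing.
#'
#' @param clinical Clinical feature tibble keyed by `(patient_id, year)`.
#' @param ... Named source tibbles keyed by `patient_id` (and optionally
#'   `year`).  The names label integrity errors.
#' @return The merged, still-identified wide tibble.
#' @export
merge_sources <- function(clinical, ...) {
  sources <- rlang::list2(...)
  if (anyDuplicated(clinical[c("patient_id", "year")])) {
    stop_clinexpo("duplicate (patient_id, year) keys in source 'clinical'", "integrity_error")
  }
  out <- clinical
  for (nm in names(sources)) {
    src <- sources[[nm]]
    if (is.null(src)) next
    keys <- intersect(c("patient_id", "year"), names(src))
    if (anyDuplicated(src[keys])) {
      stop_clinexpo(
        sprintf("duplicate (%s) keys in source '%s'", paste(keys, collapse = ", "), nm),
        "integrity_error"
      )
    }
    out <- dplyr::left_join(out, src, by = keys)
  }
  out
}

#' Quantile-bin a numeric vector into range labels
#'
#' Edges are empirical quantiles at `k / n_bins` with linear interpolation
#' (`stats::quantile` type 7, the same rule as pandas `qcut`); intervals are
#' right-closed `"(a, b]"` with the minimum included in the first bin, so for
#' all-distinct inputs the bins have near-equal occupancy.  Duplicate edges
#' (heavily tied data) are collapsed, with a warning, into fewer bins.
#'
#' @param values Numeric vector (NAs stay NA).
#' @param n_bins Number of quantile bins (>= 2).
#' @param digits Significant digits used in the range labels.
#' @return A `binned` object: list with `labels` (character vector parallel
#'   to `values`), `edges` (numeric), `levels` (label set in order), and
#'   `method = "quantile"`.
#' @export
bin_quantiles <- function(values, n_bins = 5, digits = 6) {
  stopifnot(n_bins >= 2)
  if (all(is.na(values))) {
    rlang::warn("all values missing; binning is a no-op")
    return(structure(
      list(labels = rep(NA_character_, length(values)), edges = numeric(),
           levels = character(), method = "quantile"),
      class = "binned"
    ))
  }
  edges <- unname(quantile(values, probs = seq(0, 1, length.out = n_bins + 1),
                           na.rm = TRUE, type = 7))
  uniq <- unique(edges)
  if (length(uniq) < length(edges)) {
    rlang::warn(sprintf(
      "duplicate quantile edges collapsed: %d bins requested, %d produced",
      n_bins, max(1L, length(uniq) - 1L)
    ))
    edges <- uniq
  }
  out <- bin_fixed(values, edges, digits)
  out$method <- "quantile"
  out
}

#' Bin a numeric vector at fixed edges
#'
#' @param values Numeric vector.
#' @param edges Strictly increasing numeric edges spanning the data.
#' @param digits Significant digits for labels.
#' @return A `binned` object (see [bin_quantiles()]) with `method = "fixed_edges"`.
#' @export
bin_fixed <- function(values, edges, digits = 6) {
  if (is.unsorted(edges, strictly = TRUE)) {
    stop_clinexpo("bin edges must be strictly increasing", "config_error")
  }
  if (length(edges) < 2) {
    lab <- format_edge(edges, digits)
    lev <- sprintf("[%s, %s]", lab, lab)
    return(structure(
      list(labels = ifelse(is.na(values), NA_character_, lev),
           edges = edges, levels = lev, method = "fixed_edges"),
      class = "binned"
    ))
  }
  e <- format_edge(edges, digits)
  lev <- sprintf("(%s, %s]", head(e, -1), tail(e, -1))
  lev[1] <- sprintf("[%s, %s]", e[1], e[2])
  idx <- findInterval(values, edges, left.open = TRUE, rightmost.closed = FALSE)
  idx[values == edges[1]] <- 1L  # minimum included in the first bin
  idx[idx < 1 | idx >= length(edges)] <- NA_integer_
  structure(
    list(labels = lev[idx], edges = edges, levels = lev, method = "fixed_edges"),
    class = "binned"
  )
}

format_edge <- function(x, digits) {
  formatC(x, format = "g", digits = digits)
}

#' Apply bin specifications to table columns
#'
#' @param df Tibble.
#' @param specs Named list: per variable either an integer (quantile bin
#'   count) or a numeric vector of fixed edges.
#' @return List with `data` (the tibble with those columns replaced by range
#'   labels) and `manifest` (per variable: method and edges, suitable for
#'   [write_bins_manifest()]).
#' @export
apply_bins <- function(df, specs) {
  manifest <- list()
  for (v in names(specs)) {
    if (!v %in% names(df)) stop_clinexpo(sprintf("unknown variable '%s'", v), "config_error")
    sp <- specs[[v]]
    b <- if (length(sp) == 1 && sp == as.integer(sp) && sp >= 2) {
      bin_quantiles(df[[v]], n_bins = as.integer(sp))
    } else {
      bin_fixed(df[[v]], sp)
    }
    df[[v]] <- b$labels
    manifest[[v]] <- list(method = b$method, edges = b$edges, levels = b$levels)
  }
  list(data = df, manifest = manifest)
}

#' Write the binning manifest
#'
#' Records method and edges per binned variable so that range labels in the
#' feature table remain interpretable downstream.
#'
#' @param manifest The `manifest` element of [apply_bins()].
#' @param path YAML file path.
#' @export
write_bins_manifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' De-identification policy
#'
#' The Safe-Harbor subset relevant to a tabular schema: direct identifiers
#' and geocodes are dropped, dates are truncated to year, and ages over 89
#' are recoded to a top category `"90+"`.  Columns whose names look
#' identifier- or coordinate-like (the deny patterns) must be covered by the
#' policy, otherwise de-identification refuses to run.
#'
#' @param id_cols Columns to drop outright.
#' @param date_cols Columns truncated to their year.
#' @param age_col Age column recoded with the `"90+"` top category.
#' @param deny_patterns Regexes that flag must-be-covered columns.
#' @return A `deid_policy` list.
#' @export
deid_policy <- function(id_cols = c("patient_id", "lat", "lon", "census_unit",
                                    "road_segment_id", "highway_segment_id"),
                        date_cols = character(),
                        age_col = "age_in_years",
                        deny_patterns = c("(^|_)id$", "patient_id", "^lat$", "^lon$",
                                          "latitude", "longitude", "address",
                                          "birth", "geocode")) {
  structure(
    list(id_cols = id_cols, date_cols = date_cols, age_col = age_col,
         deny_patterns = deny_patterns),
    class = "deid_policy"
  )
}

#' De-identify an integrated table
#'
#' Drops identifier and geocode columns, truncates date columns to year,
#' recodes ages over 89 to `"90+"`, and verifies that no column matching a
#' deny pattern survives.  Idempotent: applying it twice equals applying it
#' once.
#'
#' @param df Identified wide tibble.
#' @param policy A [deid_policy()].
#' @return The de-identified tibble (`year` is retained; nothing finer).
#' @export
deidentify <- function(df, policy = deid_policy()) {
  out <- df[setdiff(names(df), policy$id_cols)]
  for (v in intersect(policy$date_cols, names(out))) {
    out[[v]] <- iso_year(out[[v]])
  }
  a <- policy$age_col
  if (a %in% names(out)) {
    age <- out[[a]]
    if (is.numeric(age)) {
      out[[a]] <- ifelse(is.na(age), NA_character_,
                         ifelse(age > 89, "90+", as.character(age)))
    }
  }
  leftover <- purrr::keep(names(out), function(nm) {
    any(purrr::map_lgl(policy$deny_patterns, ~ grepl(.x, nm, ignore.case = TRUE)))
  })
  if (length(leftover)) {
    stop_clinexpo(
      paste0("de-identification policy gap: identifier-like column(s) not covered: ",
             paste(leftover, collapse = ", ")),
      "policy_gap"
    )
  }
  out
}

#' Write an integrated feature table as CSV
#'
#' RFC 4180 CSV, UTF-8, header row, missing values as empty fields, rows
#' sorted by all columns so repeated runs are byte-identical (and source row
#' order cannot aid re-identification).
#'
#' @param rows Tibble (all rows share its schema) or a list of one-row
#'   tibbles with identical schemas.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  if (!is.data.frame(rows)) {
    schemas <- unique(purrr::map(rows, names))
    if (length(schemas) > 1) {
      stop_clinexpo("rows do not share one schema", "schema_error")
    }
    rows <- dplyr::bind_rows(rows)
  }
  rows <- dplyr::arrange(rows, dplyr::across(dplyr::everything()))
  readr::write_csv(rows, path, na = "")
  invisible(path)
}
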