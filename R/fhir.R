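# Consolidation of FHIR R4 JSON resources into per-patient bundles, and
# extraction of the residence geocode from the standard address geolocation
# extension.

GEOLOC_URL <- "http://hl7.org/fhir/StructureDefinition/geolocation"

#' Consolidate FHIR resources into per-patient bundles
#'
#' Groups a stream of FHIR R4 JSON resources (Patient, Encounter, Condition,
#' MedicationRequest) by patient: one bundle per Patient resource, with every
#' resource that references that patient attached.  Resources referencing no
#' known Patient are counted and excluded as orphans.
#'
#' @param resources Either a character vector of NDJSON file paths (one JSON
#'   resource per line) or a list of already-parsed resource objects.
#' @return A named list of `patient_bundle` objects keyed by patient id, with
#'   attribute `orphans`: a tibble of excluded resources (`resource_type`,
#'   `reference`).  Each bundle holds `patient_id`, `demographics`
#'   (`birth_date`, `sex`, `race`, `ethnicity`), `addresses` (tibble with
#'   `lat`, `lon`, `period_start`, `period_end`), `encounters` (tibble sorted
#'   by `start`, with a `diagnosis_codes` list column), `conditions`, and
#'   `medications`.
#' @export
consolidate <- function(resources) {
  if (is.character(resources)) {
    resources <- unlist(
      purrr::map(resources, function(path) {
        lines <- readLines(path, warn = FALSE)
        lines <- lines[nzchar(trimws(lines))]
        purrr::imap(lines, function(l, i) {
          r <- jsonlite::fromJSON(l, simplifyVector = FALSE)
          attr(r, "src") <- sprintf("%s:%d", basename(path), i)
          r
        })
      }),
      recursive = FALSE
    )
  }
  for (r in resources) {
    if (is.null(r$resourceType)) {
      stop_clinexpo(
        sprintf("resource missing resourceType (%s)", attr(r, "src") %||% "inline input"),
        "malformed_resource"
      )
    }
  }
  types <- purrr::map_chr(resources, "resourceType")

  bundles <- list()
  for (r in resources[types == "Patient"]) {
    bundles[[r$id]] <- new_patient_bundle(r)
  }

  orphan_type <- character(0); orphan_ref <- character(0)
  # accumulate plain vectors and bind once per resource type (one tibble per
  # resource does not scale to cohort-sized inputs)
  enc <- list(pid = character(), id = character(), class = character(),
              start = character(), codes = list())
  con <- list(pid = character(), code = character(), onset = character())
  med <- list(pid = character(), drug = character(), authored = character())
  for (r in resources[types != "Patient"]) {
    ref <- r$subject$reference %||% r$patient$reference %||% ""
    pid <- sub("^Patient/", "", ref)
    if (!pid %in% names(bundles)) {
      orphan_type <- c(orphan_type, r$resourceType)
      orphan_ref <- c(orphan_ref, ref)
      next
    }
    if (r$resourceType == "Encounter") {
      i <- length(enc$pid) + 1L
      enc$pid[i] <- pid
      enc$id[i] <- r$id %||% NA_character_
      enc$class[i] <- fhir_encounter_class(r)
      enc$start[i] <- r$period$start %||% NA_character_
      enc$codes[[i]] <- fhir_codes(r$reasonCode)
    } else if (r$resourceType == "Condition") {
      i <- length(con$pid) + 1L
      con$pid[i] <- pid
      con$code[i] <- fhir_codes(list(r$code))[1] %||% NA_character_
      con$onset[i] <- r$onsetDateTime %||% NA_character_
    } else if (r$resourceType %in% c("MedicationRequest", "MedicationStatement")) {
      i <- length(med$pid) + 1L
      med$pid[i] <- pid
      med$drug[i] <- r$medicationCodeableConcept$text %||%
        fhir_codes(list(r$medicationCodeableConcept))[1] %||% NA_character_
      med$authored[i] <- r$authoredOn %||% r$effectiveDateTime %||% NA_character_
    } else {
      orphan_type <- c(orphan_type, r$resourceType)
      orphan_ref <- c(orphan_ref, ref)
    }
  }

  enc_ord <- order(enc$start)
  enc_df <- fast_tbl(list(patient_id = enc$pid[enc_ord],
                          encounter_id = enc$id[enc_ord],
                          class = enc$class[enc_ord], start = enc$start[enc_ord],
                          diagnosis_codes = enc$codes[enc_ord]))
  con_df <- fast_tbl(list(patient_id = con$pid, code = con$code, onset = con$onset))
  med_df <- fast_tbl(list(patient_id = med$pid, drug = med$drug, authored = med$authored))
  for (field in c("encounters", "conditions", "medications")) {
    df <- switch(field, encounters = enc_df, conditions = con_df, medications = med_df)
    idx <- split(seq_len(nrow(df)), df$patient_id)
    for (pid in names(idx)) {
      bundles[[pid]][[field]] <- fast_slice(df[-1L], idx[[pid]])
    }
  }

  attr(bundles, "orphans") <- tibble::tibble(
    resource_type = orphan_type, reference = orphan_ref
  )
  bundles
}

empty_addresses <- function() {
  fast_tbl(list(lat = double(), lon = double(),
                period_start = character(), period_end = character()))
}
empty_encounters <- function() {
  fast_tbl(list(encounter_id = character(), class = character(),
                start = character(), diagnosis_codes = list()))
}
empty_conditions <- function() fast_tbl(list(code = character(), onset = character()))
empty_medications <- function() fast_tbl(list(drug = character(), authored = character()))

new_patient_bundle <- function(patient) {
  ext <- patient$extension %||% list()
  ext_val <- function(suffix) {
    for (e in ext) {
      if (endsWith(e$url %||% "", suffix)) {
        return(e$valueString %||% e$valueCode %||% NA_character_)
      }
    }
    NA_character_
  }
  addr <- patient$address %||% list()
  n <- length(addr)
  lat <- lon <- rep(NA_real_, n)
  ps <- pe <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    a <- addr[[k]]
    for (ae in a$extension %||% list()) {
      if (identical(ae$url, GEOLOC_URL)) {
        for (g in ae$extension %||% list()) {
          if (identical(g$url, "latitude")) lat[k] <- as.numeric(g$valueDecimal)
          if (identical(g$url, "longitude")) lon[k] <- as.numeric(g$valueDecimal)
        }
      }
    }
    ps[k] <- a$period$start %||% NA_character_
    pe[k] <- a$period$end %||% NA_character_
  }
  structure(
    list(
      patient_id = patient$id,
      demographics = list(
        birth_date = patient$birthDate %||% NA_character_,
        sex = patient$gender %||% NA_character_,
        race = ext_val("race"),
        ethnicity = ext_val("ethnicity")
      ),
      addresses = fast_tbl(list(lat = lat, lon = lon,
                                period_start = ps, period_end = pe)),
      encounters = empty_encounters(),
      conditions = empty_conditions(),
      medications = empty_medications()
    ),
    class = "patient_bundle"
  )
}

fhir_encounter_class <- function(r) {
  code <- r$class$code %||% r$class %||% NA_character_
  if (!is.character(code)) code <- NA_character_
  dplyr::case_match(
    toupper(code),
    c("EMER", "EMERGENCY") ~ "emergency",
    c("IMP", "ACUTE", "INPATIENT") ~ "inpatient",
    c("AMB", "AMBULATORY", "OUTPATIENT") ~ "ambulatory",
    .default = "other"
  )
}

# All codes carried by a list of CodeableConcepts.
fhir_codes <- function(concepts) {
  out <- unlist(purrr::map(concepts %||% list(), function(cc) {
    purrr::map_chr(cc$coding %||% list(), ~ .x$code %||% NA_character_)
  }))
  as.character(out[!is.na(out)])
}

#' Extract the residence geocode for a study year
#'
#' Returns the latitude/longitude of the primary home address whose validity
#' period covers the study year; when several qualify, the one with the
#' latest period start wins.  Addresses with no period are treated as always
#' valid.
#'
#' @param bundle A `patient_bundle`.
#' @param study_year Integer year.
#' @return One-row tibble `lat`, `lon`; both `NA` (a missing-geocode flag,
#'   the patient is not dropped) when no address carries a geolocation.
#' @export
extract_geocode <- function(bundle, study_year) {
  a <- bundle$addresses
  keep <- which(!is.na(a$lat) & !is.na(a$lon))
  if (length(keep)) {
    ys <- iso_year(a$period_start[keep])
    ye <- iso_year(a$period_end[keep])
    keep <- keep[(is.na(ys) | ys <= study_year) & (is.na(ye) | ye >= study_year)]
  }
  if (!length(keep)) {
    return(fast_tbl(list(lat = NA_real_, lon = NA_real_)))
  }
  key <- a$period_start[keep]
  key[is.na(key)] <- ""
  i <- keep[order(key, decreasing = TRUE)[1]]
  fast_tbl(list(lat = a$lat[i], lon = a$lon[i]))
}

#' Geocode table for a set of bundles
#'
#' @param bundles Output of [consolidate()].
#' @param study_year Integer year.
#' @return Tibble `patient_id`, `lat`, `lon` (NA where missing).
#' @export
geocode_table <- function(bundles, study_year) {
  geo <- purrr::map(bundles, function(b) {
    g <- extract_geocode(b, study_year)
    c(g$lat, g$lon)
  })
  m <- do.call(rbind, geo)
  tibble::tibble(patient_id = names(bundles), lat = m[, 1], lon = m[, 2])
}

#' Write / read per-patient bundles as JSON
#'
#' One `<patient_id>.json` file per bundle, so that consolidation output can
#' be chained into the next pipeline step.
#'
#' @param bundles Output of [consolidate()].
#' @param dir Directory (created if needed).
#' @return `dir` (write) or a named list of bundles (read), invisibly for write.
#' @export
write_bundles <- function(bundles, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in bundles) {
    obj <- list(
      patient_id = b$patient_id,
      demographics = b$demographics,
      addresses = as.list(b$addresses),
      encounters = as.list(b$encounters),
      conditions = as.list(b$conditions),
      medications = as.list(b$medications)
    )
    # column-major serialization of the sub-tables
    writeLines(
      jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", na = "null",
                       digits = NA),
      file.path(dir, paste0(b$patient_id, ".json"))
    )
  }
  invisible(dir)
}

#' @rdname write_bundles
#' @export
read_bundles <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  as_tbl <- function(x, proto) {
    plain <- setdiff(names(proto), "diagnosis_codes")
    n <- max(0L, lengths(x[plain]))
    if (n == 0L) return(proto)
    cols <- lapply(names(proto), function(nm) {
      v <- x[[nm]]
      if (nm == "diagnosis_codes") {
        if (n == 1L) return(list(as.character(unlist(v))))
        if (is.list(v)) return(lapply(v, function(e) as.character(unlist(e))))
        return(as.list(as.character(v)))
      }
      v <- unlist(v) %||% rep(NA, n)
      if (is.numeric(proto[[nm]])) as.numeric(v) else as.character(v)
    })
    names(cols) <- names(proto)
    fast_tbl(cols)
  }
  bundles <- purrr::map(files, function(f) {
    x <- jsonlite::fromJSON(f)
    proto_b <- new_patient_bundle(list(id = x$patient_id))
    structure(
      list(
        patient_id = x$patient_id,
        demographics = purrr::map(x$demographics, ~ .x %||% NA_character_),
        addresses = as_tbl(x$addresses, proto_b$addresses),
        encounters = as_tbl(x$encounters, proto_b$encounters),
        conditions = as_tbl(x$conditions, proto_b$conditions),
        medications = as_tbl(x$medications, proto_b$medications)
      ),
      class = "patient_bundle"
    )
  })
  names(bundles) <- purrr::map_chr(bundles, "patient_id")
  bundles
}
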