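# Builders for in-memory FHIR resources and small pipeline registries used
# across the suite.  All randomness is seeded locally inside each test.

res_patient <- function(id, lat = NULL, lon = NULL, birth = "1980-06-01",
                        sex = "female", race = "2106-3",
                        period_start = NULL, period_end = NULL,
                        addresses = NULL) {
  if (is.null(addresses)) {
    addresses <- if (is.null(lat)) list() else list(list(
      lat = lat, lon = lon, period_start = period_start, period_end = period_end
    ))
  }
  list(
    resourceType = "Patient", id = id, gender = sex, birthDate = birth,
    extension = list(
      list(url = "http://example.org/fhir/race", valueString = race),
      list(url = "http://example.org/fhir/ethnicity", valueString = "2186-5")
    ),
    address = lapply(addresses, function(a) {
      per <- list()
      if (!is.null(a$period_start)) per$start <- a$period_start
      if (!is.null(a$period_end)) per$end <- a$period_end
      list(
        use = "home", period = per,
        extension = list(list(
          url = "http://hl7.org/fhir/StructureDefinition/geolocation",
          extension = list(
            list(url = "latitude", valueDecimal = a$lat),
            list(url = "longitude", valueDecimal = a$lon)
          )
        ))
      )
    })
  )
}

res_encounter <- function(pid, id, class = "EMER",
                          start = "2010-03-04T08:00:00", codes = "J45.909") {
  list(
    resourceType = "Encounter", id = id,
    subject = list(reference = paste0("Patient/", pid)),
    class = list(system = "v3-ActCode", code = class),
    period = list(start = start),
    reasonCode = list(list(coding = lapply(codes, function(cd) {
      list(system = "icd10", code = cd)
    })))
  )
}

res_condition <- function(pid, id, code = "J45.909", onset = "2001-01-01") {
  list(
    resourceType = "Condition", id = id,
    subject = list(reference = paste0("Patient/", pid)),
    code = list(coding = list(list(system = "icd10", code = code))),
    onsetDateTime = onset
  )
}

res_medreq <- function(pid, id, drug = "prednisone 20 MG",
                       authored = "2010-05-01") {
  list(
    resourceType = "MedicationRequest", id = id,
    subject = list(reference = paste0("Patient/", pid)),
    medicationCodeableConcept = list(text = drug),
    authoredOn = authored
  )
}

# A random cohort of parsed resources with known per-patient composition.
random_resources <- function(n, seed, year = 2010) {
  set.seed(seed)
  resources <- list()
  truth <- list()
  for (i in seq_len(n)) {
    pid <- sprintf("p%03d", i)
    n_enc <- sample(0:4, 1)
    resources <- c(resources, list(res_patient(
      pid, lat = runif(1, 35, 36), lon = runif(1, -80, -79)
    )))
    classes <- sample(c("EMER", "IMP", "AMB"), n_enc, replace = TRUE)
    codes <- sample(c("J45.909", "J18.9", "I10", "E11.9"), max(n_enc, 1),
                    replace = TRUE)
    starts <- sprintf("%d-%02d-%02dT09:00:00",
                      sample(c(year, year - 1), max(n_enc, 1), replace = TRUE),
                      sample(1:12, max(n_enc, 1), replace = TRUE),
                      sample(1:28, max(n_enc, 1), replace = TRUE))
    for (k in seq_len(n_enc)) {
      resources <- c(resources, list(res_encounter(
        pid, sprintf("%s-e%d", pid, k), class = classes[k],
        start = starts[k], codes = codes[k]
      )))
    }
    truth[[pid]] <- list(
      n_enc = n_enc, classes = classes[seq_len(n_enc)],
      codes = codes[seq_len(n_enc)], starts = starts[seq_len(n_enc)]
    )
  }
  list(resources = resources, truth = truth)
}

# Registry of tiny instrumented plugins for pipeline-contract tests.
trace_registry <- function(log = NULL) {
  list(
    NOOP = function(args, global) invisible(NULL),
    TOUCH = function(args, global) {
      writeLines(args$payload %||% "x", args$output)
    },
    APPEND = function(args, global) {
      prev <- if (!is.null(args$input) && file.exists(args$input)) {
        readLines(args$input)
      } else {
        character()
      }
      writeLines(c(prev, args$payload), args$output)
    },
    BOOM = function(args, global) stop("boom: plugin exploded")
  )
}

config_from_steps <- function(steps, global = list()) {
  load_config(yaml::as.yaml(list(steps = steps, global = global)),
              registry = trace_registry())
}

yaml_step <- function(name, fun = "NOOP", depends = NULL, skip = NULL,
                      arguments = list()) {
  s <- list(name = name, step = list("function" = fun, arguments = arguments))
  if (!is.null(depends)) s$dependsOn <- as.list(depends)
  if (!is.null(skip)) s$skip <- skip
  s
}
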