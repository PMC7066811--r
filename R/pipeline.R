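#' Parse a YAML pipeline configuration
#'
#' A pipeline configuration is a single YAML document with a `steps:` list and
#' an optional `global:` map.  Each step carries exactly the fields
#' `name`, `dependsOn`, `skip`, and `step: {function, arguments}`:
#'
#' ```yaml
#' global:
#'   workdir: out
#' steps:
#'   - name: fhir
#'     step:
#'       function: FHIR
#'       arguments: {input_dir: fhir, output_dir: bundles}
#'   - name: vector
#'     dependsOn: [fhir]
#'     skip: false
#'     step:
#'       function: ToVector
#'       arguments: {input_dir: bundles, output: clinical.csv, year: 2010}
#' ```
#'
#' `skip` defaults to `FALSE` when absent; a skipped step is not run, which
#' supports partial re-execution of a pipeline whose earlier steps already
#' wrote their outputs.
#'
#' @param yaml_text A length-one character string of YAML, or a path to a
#'   YAML file.
#' @param registry Named list of plugin functions used to validate
#'   `step.function`; defaults to the built-in plugins
#'   (see [default_plugins()]).
#' @return A validated `pipeline_config` object: a list with `steps` (each a
#'   `step_instance`) and `global`.
#' @export
#' @examples
#' cfg <- load_config("steps:\n- name: s1\n  step: {function: NOOP, arguments: {}}\n")
#' resolve_execution_order(cfg)
load_config <- function(yaml_text, registry = default_plugins()) {
  stopifnot(is_scalar_chr(yaml_text))
  doc <- if (!grepl("\n", yaml_text) && file.exists(yaml_text)) {
    yaml::read_yaml(yaml_text)
  } else {
    yaml::yaml.load(yaml_text)
  }
  raw_steps <- doc$steps %||% list()
  steps <- purrr::map(raw_steps, new_step_instance)
  config <- structure(
    list(steps = steps, global = doc$global %||% list()),
    class = "pipeline_config"
  )
  validate_config(config, registry)
}

new_step_instance <- function(x) {
  if (is.null(x$name) || !nzchar(x$name %||% "")) {
    stop_clinexpo("every step requires a non-empty `name`", "config_error")
  }
  structure(
    list(
      name = as.character(x$name),
      depends_on = as.character(unlist(x$dependsOn %||% character())),
      skip = isTRUE(x$skip) || identical(x$skip, "true"),
      fun = as.character(x$step$`function` %||% x$step$fun %||% NA_character_),
      arguments = x$step$arguments %||% list()
    ),
    class = "step_instance"
  )
}

validate_config <- function(config, registry = default_plugins()) {
  nm <- purrr::map_chr(config$steps, "name")
  if (anyDuplicated(nm)) {
    stop_clinexpo(
      paste0("duplicate step names: ", paste(unique(nm[duplicated(nm)]), collapse = ", ")),
      "config_error"
    )
  }
  for (s in config$steps) {
    if (is.na(s$fun) || !s$fun %in% names(registry)) {
      stop_clinexpo(
        sprintf("step '%s' names unknown plugin function '%s'", s$name, s$fun),
        "config_error"
      )
    }
    bad <- setdiff(s$depends_on, nm)
    if (length(bad)) {
      stop_clinexpo(
        sprintf("step '%s' dependsOn undefined step(s): %s", s$name, paste(bad, collapse = ", ")),
        "config_error"
      )
    }
  }
  config
}

#' Resolve the execution order of a pipeline configuration
#'
#' Topologically sorts the steps so that every step appears after all the
#' steps it depends on.  Ties are broken by declaration order, so the result
#' is deterministic for a given configuration.
#'
#' @param config A `pipeline_config` from [load_config()].
#' @return Character vector of step names in execution order.
#' @export
resolve_execution_order <- function(config) {
  nm <- purrr::map_chr(config$steps, "name")
  n <- length(nm)
  if (n == 0L) return(character())
  deps <- purrr::map(config$steps, "depends_on")
  indeg <- purrr::map_int(deps, length)
  # Kahn's algorithm; among ready steps always take the earliest declared.
  order <- character(0)
  done <- rep(FALSE, n)
  repeat {
    ready <- which(!done & indeg == 0L)
    if (!length(ready)) break
    i <- ready[1L]
    done[i] <- TRUE
    order <- c(order, nm[i])
    indeg <- indeg - purrr::map_int(deps, ~ sum(.x == nm[i]))
  }
  if (length(order) < n) {
    stop_clinexpo(
      paste0("dependency cycle among steps: ", paste(nm[!done], collapse = ", ")),
      "cycle_error"
    )
  }
  order
}

#' Execute a pipeline
#'
#' Runs the steps of a configuration in dependency order, dispatching each to
#' its plugin.  Steps with `skip: true` are not executed; steps downstream of
#' a failure are not executed either.  Each plugin reads and writes the file
#' paths named in its `arguments`, so the output of one step feeds the next.
#'
#' @param config A `pipeline_config`.
#' @param registry Named list of plugin functions, each called as
#'   `fun(arguments, global)`.  Defaults to [default_plugins()].
#' @param only Optional character vector restricting execution to these steps
#'   (their co-configured steps are reported as skipped).
#' @return An `execution_report`: a tibble with columns `step`, `status`
#'   (one of `"succeeded"`, `"skipped"`, `"failed"`), `reason` (for skipped:
#'   `"configured_skip"` or `"upstream_failure"`) and `error` (message for
#'   failed steps).  The statuses partition the configured steps.
#' @export
run_pipeline <- function(config, registry = default_plugins(), only = NULL) {
  validate_config(config, registry)
  order <- resolve_execution_order(config)
  steps <- setNames(config$steps, purrr::map_chr(config$steps, "name"))
  status <- setNames(rep(NA_character_, length(order)), order)
  reason <- setNames(rep(NA_character_, length(order)), order)
  errmsg <- setNames(rep(NA_character_, length(order)), order)

  for (nm in order) {
    s <- steps[[nm]]
    # a configured skip does not block downstream steps (its outputs are
    # assumed present from a prior run); a failure does, transitively.
    up <- s$depends_on
    blocked <- up[status[up] == "failed" |
                    (status[up] == "skipped" & reason[up] == "upstream_failure")]
    if (length(blocked)) {
      status[nm] <- "skipped"; reason[nm] <- "upstream_failure"
      next
    }
    if (s$skip || (!is.null(only) && !nm %in% only)) {
      status[nm] <- "skipped"; reason[nm] <- "configured_skip"
      next
    }
    res <- tryCatch(
      {
        registry[[s$fun]](s$arguments, config$global)
        list(ok = TRUE)
      },
      error = function(e) list(ok = FALSE, msg = conditionMessage(e))
    )
    if (res$ok) {
      status[nm] <- "succeeded"
    } else {
      status[nm] <- "failed"; errmsg[nm] <- res$msg
    }
  }

  structure(
    tibble::tibble(step = order, status = unname(status),
                   reason = unname(reason), error = unname(errmsg)),
    class = c("execution_report", "tbl_df", "tbl", "data.frame")
  )
}

#' @export
print.execution_report <- function(x, ...) {
  cat(sprintf(
    "<execution_report> %d succeeded, %d skipped, %d failed\n",
    sum(x$status == "succeeded"), sum(x$status == "skipped"), sum(x$status == "failed")
  ))
  NextMethod()
}

#' Expand a step template over calendar years
#'
#' Environmental sources are typically one file per calendar year; rather
#' than writing one YAML step per year, a single template step carries a
#' `{{year}}` placeholder in its name and arguments, and `expand_years()`
#' instantiates one concrete step per year.
#'
#' @param template A `step_instance` (or the equivalent list) whose `name`
#'   and `arguments` contain the token `{{year}}`.
#' @param years Character (or integer) vector of years; may be empty.
#' @return List of `step_instance`s, one per year, names suffixed by year.
#' @export
expand_years <- function(template, years) {
  if (!inherits(template, "step_instance")) template <- new_step_instance(template)
  purrr::map(as.character(years), function(y) {
    sub_year <- function(v) {
      if (is.character(v)) gsub("{{year}}", y, v, fixed = TRUE) else v
    }
    s <- template
    s$name <- sub_year(s$name)
    if (!grepl(y, s$name, fixed = TRUE)) s$name <- paste0(s$name, "_", y)
    s$depends_on <- vapply(s$depends_on, sub_year, character(1), USE.NAMES = FALSE)
    s$arguments <- purrr::map(s$arguments, ~ if (is.list(.x)) purrr::map(.x, sub_year) else sub_year(.x))
    s
  })
}

#' Serialize an execution report to JSON
#'
#' @param report An `execution_report` from [run_pipeline()].
#' @param path File to write; the JSON carries `succeeded`, `skipped`
#'   (name + reason), and `failed` (name + error) arrays.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(
    succeeded = report$step[report$status == "succeeded"],
    skipped = purrr::map2(
      report$step[report$status == "skipped"],
      report$reason[report$status == "skipped"],
      ~ list(step = .x, reason = .y)
    ),
    failed = purrr::map2(
      report$step[report$status == "failed"],
      report$error[report$status == "failed"],
      ~ list(step = .x, error = .y)
    )
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
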