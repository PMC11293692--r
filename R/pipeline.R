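#' Read a pipeline run configuration
#'
#' YAML (or JSON) with exactly one of `cohort` (path to a cohort CSV)
#' or `synthetic` (arguments to [synthetic_cohort_config()]), plus
#' `model` (path to the original model spec), optional `model_recal`
#' (path to the recalibrated spec; when absent with
#' `recalibrate: true`, the intercept is refit on the cohort), `out`
#' (output directory), and optional `seed`, `shock_rule`, `schema`.
#'
#' @param path Config file path.
#' @return List of class `st_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("run config not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_run_config(raw)
}

#' Build a run configuration from a named list
#'
#' Programmatic counterpart of [read_run_config()]; validates the
#' exactly-one-of cohort/synthetic rule and fills defaults.
#'
#' @param raw Named list with the fields described in
#'   [read_run_config()].
#' @return List of class `st_run_config`.
#' @export
as_run_config <- function(raw) {
  raw <- raw[!vapply(raw, is.null, logical(1))]
  has_cohort <- !is.null(raw$cohort)
  has_synth <- !is.null(raw$synthetic)
  if (has_cohort == has_synth) {
    stop("run config must have exactly one of 'cohort' or 'synthetic'",
         call. = FALSE)
  }
  if (is.null(raw$model)) stop("run config missing 'model' path", call. = FALSE)
  raw$out <- raw$out %||% "."
  raw$shock_rule <- raw$shock_rule %||% "cool_and_any"
  structure(raw, class = "st_run_config")
}

run_config_cohort <- function(config) {
  if (!is.null(config$cohort)) {
    read_cohort(config$cohort, schema = config$schema)
  } else {
    args <- config$synthetic
    if (!is.null(config$seed)) args$seed <- config$seed
    generate_cohort(do.call(synthetic_cohort_config, args))
  }
}

#' Generate and write a synthetic cohort (pipeline step)
#'
#' @param config An `st_run_config`, a path to one, or a
#'   [synthetic_cohort_config()].
#' @param path Output CSV path; defaults to `cohort.csv` under the
#'   config's output directory.
#' @return The written path, invisibly.
#' @export
run_simulate <- function(config, path = NULL) {
  if (inherits(config, "synthetic_cohort_config")) {
    cohort <- generate_cohort(config)
    path <- path %||% "cohort.csv"
  } else {
    if (is.character(config)) config <- read_run_config(config)
    if (is.null(config$synthetic)) {
      stop("run_simulate needs a synthetic cohort configuration", call. = FALSE)
    }
    cohort <- run_config_cohort(config)
    path <- path %||% file.path(config$out, "cohort.csv")
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write_cohort(cohort, path)
  message(sprintf("wrote %d-row cohort to %s", nrow(cohort), path))
  invisible(path)
}

#' Triage a cohort end to end (pipeline step)
#'
#' Loads (or generates) the cohort, loads the model spec(s), runs
#' [triage_cohort()], writes the assignments CSV with the audit trail,
#' and logs per-system category counts.
#'
#' @param config An `st_run_config` or a path to one.
#' @return The assignments tibble, invisibly; the CSV lands at
#'   `assignments.csv` under the config's output directory.
#' @export
run_triage <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cohort <- run_config_cohort(config)
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  model <- read_model_spec(config$model)
  model_recal <- if (!is.null(config$model_recal)) {
    read_model_spec(config$model_recal)
  } else if (isTRUE(config$recalibrate)) {
    recalibrate_model_spec(model, cohort)
  } else {
    model
  }
  asg <- triage_cohort(cohort, model, model_recal,
                       shock_rule = config$shock_rule)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  write_assignments(asg, file.path(config$out, "assignments.csv"))
  for (sys in c("etat", "st_model_only", "st_with_triggers",
                "st_recalibrated_with_triggers")) {
    counts <- table(asg[[sys]])
    message(sys, ": ", paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  invisible(asg)
}

#' Evaluate triage assignments against outcomes (pipeline step)
#'
#' Produces the full comparison artifact set: per-system
#' category-by-outcome tables, dichotomized diagnostic summaries for
#' admission and mortality, and ETAT-versus-Smart-Triage transition
#' tables with Sankey flow JSON.
#'
#' @param config An `st_run_config` or a path to one. The cohort is
#'   re-loaded/generated and re-triaged unless `assignments` is given.
#' @param assignments Optional precomputed [triage_cohort()] tibble.
#' @param cohort Optional cohort tibble matching `assignments`.
#' @return Named list of the result tibbles, invisibly; CSV/JSON files
#'   land under the config's output directory.
#' @export
run_evaluate <- function(config, assignments = NULL, cohort = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(assignments)) {
    cohort <- run_config_cohort(config)
    if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
    assignments <- run_triage(config)
  }
  if (nrow(assignments) == 0) stop("empty cohort", call. = FALSE)
  stopifnot(!is.null(cohort), nrow(cohort) == nrow(assignments))
  dat <- dplyr::inner_join(
    assignments,
    dplyr::select(cohort, dplyr::all_of(c("patient_id", "admitted", "died",
                                          "outcome_known"))),
    by = "patient_id")
  systems <- c("etat", "st_model_only", "st_with_triggers",
               "st_recalibrated_with_triggers")
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)

  outcome_tables <- purrr::map_dfr(systems, function(sys) {
    category_outcome_table(dat, !!rlang::sym(sys), admitted, died,
                           outcome_known) |>
      dplyr::mutate(system = sys, .before = 1)
  })
  readr::write_csv(outcome_tables, file.path(config$out, "outcome_tables.csv"),
                   progress = FALSE)

  diagnostics <- purrr::map_dfr(systems, function(sys) {
    purrr::map_dfr(c(admission = "admitted", mortality = "died"),
                   function(col) {
      confusion_2x2(dat, !!rlang::sym(sys), !!rlang::sym(col), outcome_known) |>
        diagnostic_summary() |>
        tidy()
    }, .id = "outcome") |>
      dplyr::mutate(system = sys, .before = 1)
  })
  readr::write_csv(diagnostics, file.path(config$out, "diagnostics.csv"),
                   progress = FALSE)

  transitions <- list()
  for (sys in setdiff(systems, "etat")) {
    tt <- transition_table(dat, etat, !!rlang::sym(sys))
    transitions[[sys]] <- tt
    write_sankey_json(tt, file.path(config$out, paste0("sankey_etat_vs_",
                                                       sys, ".json")))
  }
  flows <- purrr::map_dfr(transitions, tidy, .id = "system")
  readr::write_csv(flows, file.path(config$out, "transition_flows.csv"),
                   progress = FALSE)

  invisible(list(outcome_tables = outcome_tables, diagnostics = diagnostics,
                 transitions = transitions))
}

#' Refit a model intercept on a cohort (pipeline step)
#'
#' Runs [recalibrate_model_spec()] on the configured cohort and writes
#' the recalibrated spec to YAML.
#'
#' @param config An `st_run_config` or a path to one; optional fields
#'   `recal_low_threshold` / `recal_high_threshold` set the new spec's
#'   thresholds.
#' @param path Output YAML path; defaults to `model_recalibrated.yaml`
#'   under the config's output directory.
#' @return The recalibrated `st_model_spec`, invisibly.
#' @export
run_recalibrate <- function(config, path = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  cohort <- run_config_cohort(config)
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  model <- read_model_spec(config$model)
  recal <- recalibrate_model_spec(
    model, cohort,
    low_threshold = config$recal_low_threshold %||% model$low_threshold,
    high_threshold = config$recal_high_threshold %||% model$high_threshold)
  path <- path %||% file.path(config$out, "model_recalibrated.yaml")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write_model_spec(recal, path)
  message(sprintf("intercept offset delta = %.6f; wrote %s",
                  attr(recal, "delta"), path))
  invisible(recal)
}

#' Reproduce the published diagnostic tables from packaged counts
#'
#' Runs the in-package fixture path end to end: reconstructs the 2x2
#' tables from [reference_counts()] and recomputes every
#' sensitivity/specificity/PPV/NPV with Wilson CIs.
#'
#' @param out Optional directory; when given, writes
#'   `reference_diagnostics.csv` there.
#' @return The tidy diagnostics tibble.
#' @export
reproduce_reference_tables <- function(out = NULL) {
  res <- reference_diagnostics()
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(res, file.path(out, "reference_diagnostics.csv"),
                     progress = FALSE)
  }
  res
}
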