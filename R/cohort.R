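#' Build a cohort tibble from per-patient values
#'
#' Convenience constructor used throughout the package and its tests: fills
#' every column of the canonical cohort schema with a sensible well-child
#' default, then overrides the fields supplied. Defaults: 24-month-old with
#' normal vitals, all signs FALSE, not admitted, alive, outcome known.
#'
#' @param n Number of identical rows to create before applying overrides.
#' @param ... Named column overrides (recycled to `n`).
#' @return Validated cohort tibble, one row per patient.
#' @export
#' @examples
#' new_cohort(2, spo2_percent = c(98, 88))
new_cohort <- function(n = 1, ...) {
  base <- tibble::tibble(
    patient_id = if (n > 0) sprintf("P%05d", seq_len(n)) else character(),
    age_months = rep(24, n),
    sex = rep("unknown", n),
    temperature_c = rep(37.0, n),
    heart_rate_bpm = rep(110, n),
    respiratory_rate_bpm = rep(28, n),
    spo2_percent = rep(98, n),
    muac_mm = rep(150, n),
    admitted = rep(FALSE, n),
    died = rep(FALSE, n),
    outcome_known = rep(TRUE, n)
  )
  for (s in sign_vocabulary()) base[[s]] <- rep(FALSE, n)
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% cohort_columns()) {
      stop("unknown cohort column: ", nm, call. = FALSE)
    }
    base[[nm]] <- rep(dots[[nm]], length.out = n)
  }
  validate_cohort(base[, cohort_columns()])
}

#' Validate a cohort tibble
#'
#' Checks schema completeness, types, physiologic bounds on vitals, and
#' outcome consistency (`died` implies `outcome_known`). Out-of-bounds
#' vitals are a validation error, never silently clipped. Unknown (NA)
#' signs are allowed and flagged with a warning because the rule engines
#' will treat them as FALSE.
#'
#' @param cohort Data frame of patient records.
#' @param bounds Vital validation bounds, as from [vital_bounds()].
#' @param quiet If TRUE, suppress the unknown-sign warning.
#' @return The cohort as a tibble, columns in canonical order, invisibly
#'   unchanged in content.
#' @export
validate_cohort <- function(cohort, bounds = vital_bounds(), quiet = FALSE) {
  cohort <- tibble::as_tibble(cohort)
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(cohort) == 0) {
    return(cohort[, unique(c(cohort_columns(), names(cohort)))])
  }

  if (any(is.na(cohort$age_months)) || any(cohort$age_months < 0)) {
    stop("age_months must be present and nonnegative", call. = FALSE)
  }
  bad_sex <- setdiff(unique(cohort$sex), c("male", "female", "unknown"))
  if (length(bad_sex) > 0) {
    stop("sex must be one of male/female/unknown; found: ",
         paste(bad_sex, collapse = ", "), call. = FALSE)
  }

  for (i in seq_len(nrow(bounds))) {
    v <- bounds$vital[i]
    x <- cohort[[v]]
    if (any(is.na(x))) {
      stop("missing value in vital '", v, "' at row(s) ",
           paste(utils::head(which(is.na(x)), 5), collapse = ", "),
           call. = FALSE)
    }
    out <- x < bounds$lower[i] | x > bounds$upper[i]
    if (any(out)) {
      stop(sprintf(
        "vital '%s' outside validation bounds [%g, %g] at row(s) %s (value %g)",
        v, bounds$lower[i], bounds$upper[i],
        paste(utils::head(which(out), 5), collapse = ", "),
        x[which(out)[1]]), call. = FALSE)
    }
  }

  for (s in sign_vocabulary()) {
    if (!is.logical(cohort[[s]])) {
      stop("sign column '", s, "' must be logical", call. = FALSE)
    }
  }
  n_unknown <- sum(vapply(cohort[sign_vocabulary()],
                          function(x) sum(is.na(x)), integer(1)))
  if (n_unknown > 0 && !quiet) {
    warning(n_unknown, " unknown (NA) sign value(s); rule engines treat ",
            "unknown signs as absent", call. = FALSE)
  }

  if (any(cohort$died & !cohort$outcome_known)) {
    stop("inconsistent outcomes: died = TRUE requires outcome_known = TRUE",
         call. = FALSE)
  }
  cohort[, unique(c(cohort_columns(), names(cohort)))]
}

# parse {0,1,true,false,yes,no,t,f} case-insensitively; "" -> NA
parse_flexible_logical <- function(x, column, allow_missing = TRUE) {
  x0 <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x0))
  out[x0 %in% c("1", "true", "yes", "t")] <- TRUE
  out[x0 %in% c("0", "false", "no", "f")] <- FALSE
  unparsed <- !is.na(x0) & x0 != "" & is.na(out) &
    !x0 %in% c("na", "nan")
  if (any(unparsed)) {
    stop(sprintf("unparseable boolean in column '%s' at data row(s) %s: '%s'",
                 column, paste(utils::head(which(unparsed), 5), collapse = ", "),
                 x[which(unparsed)[1]]), call. = FALSE)
  }
  if (!allow_missing && any(is.na(out))) {
    stop(sprintf("missing value in required boolean column '%s' at row(s) %s",
                 column, paste(utils::head(which(is.na(out)), 5), collapse = ", ")),
         call. = FALSE)
  }
  as.logical(out)
}

#' Read a cohort CSV
#'
#' Reads a UTF-8 comma-separated cohort file with a header row into the
#' canonical cohort schema and validates it. Booleans are accepted as
#' 0/1/true/false/yes/no (case-insensitive). Empty sign cells become
#' unknown (NA); empty vital cells are an error unless the schema marks
#' the vital as missing-allowed (such rows fail validation anyway, so
#' this only changes which error is reported).
#'
#' @param path CSV file path.
#' @param schema Optional column mapping: a named list/character vector
#'   mapping canonical column names to the names used in the file, or a
#'   path to a YAML/JSON file holding such a mapping (optionally under a
#'   `columns` key, with `missing_allowed` as a character vector of vitals
#'   that may be empty). Unmapped canonical names are looked up verbatim.
#' @return Validated cohort tibble, one row per data row, in file order.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  schema <- load_cohort_schema(schema)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)

  required <- setdiff(cohort_columns(), "patient_id")
  file_name <- function(canon) {
    if (!is.null(schema$columns[[canon]])) schema$columns[[canon]] else canon
  }
  missing_cols <- required[!vapply(required, function(cc) file_name(cc) %in% names(raw), logical(1))]
  if (length(missing_cols) > 0) {
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  n <- nrow(raw)
  out <- tibble::tibble(.rows = n)
  pid_col <- file_name("patient_id")
  out$patient_id <- if (pid_col %in% names(raw)) as.character(raw[[pid_col]]) else
    (if (n > 0) sprintf("P%05d", seq_len(n)) else character())

  num_col <- function(canon) {
    x <- raw[[file_name(canon)]]
    blank <- is.na(x) | trimws(x) == ""
    if (any(blank) && !canon %in% schema$missing_allowed) {
      stop(sprintf("missing value in column '%s' at data row(s) %s",
                   canon, paste(utils::head(which(blank), 5), collapse = ", ")),
           call. = FALSE)
    }
    suppress <- suppressWarnings(as.numeric(x))
    badnum <- !blank & is.na(suppress)
    if (any(badnum)) {
      stop(sprintf("unparseable number in column '%s' at data row(s) %s: '%s'",
                   canon, paste(utils::head(which(badnum), 5), collapse = ", "),
                   x[which(badnum)[1]]), call. = FALSE)
    }
    suppress
  }

  out$age_months <- num_col("age_months")
  sex <- tolower(trimws(as.character(raw[[file_name("sex")]])))
  sex[is.na(sex) | sex == ""] <- "unknown"
  out$sex <- sex
  for (v in vital_bounds()$vital) out[[v]] <- num_col(v)
  for (s in sign_vocabulary()) {
    out[[s]] <- parse_flexible_logical(raw[[file_name(s)]], s)
  }
  out$admitted <- parse_flexible_logical(raw[[file_name("admitted")]], "admitted",
                                         allow_missing = FALSE)
  out$died <- parse_flexible_logical(raw[[file_name("died")]], "died",
                                     allow_missing = FALSE)
  out$outcome_known <- parse_flexible_logical(raw[[file_name("outcome_known")]],
                                              "outcome_known", allow_missing = FALSE)
  validate_cohort(out, quiet = TRUE)
}

load_cohort_schema <- function(schema) {
  if (is.null(schema)) return(list(columns = list(), missing_allowed = character()))
  if (is.character(schema) && length(schema) == 1 && file.exists(schema)) {
    schema <- if (grepl("\\.json$", schema, ignore.case = TRUE)) {
      jsonlite::read_json(schema, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(schema)
    }
  }
  if (!is.list(schema)) schema <- as.list(schema)
  if (is.null(schema$columns)) {
    ma <- schema$missing_allowed
    schema$missing_allowed <- NULL
    schema <- list(columns = schema, missing_allowed = ma)
  }
  schema$columns <- lapply(schema$columns, as.character)
  schema$missing_allowed <- as.character(unlist(schema$missing_allowed %||% character()))
  schema
}

#' Write a cohort tibble to CSV
#'
#' Reals keep full precision (>= 6 significant digits), so
#' write-then-read round-trips are lossless.
#'
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort[, intersect(cohort_columns(), names(cohort))], path,
                   progress = FALSE)
  invisible(path)
}

#' Write triage assignments to CSV
#'
#' One row per patient: id, the category assigned by each system, the
#' Smart Triage probabilities, and semicolon-joined audit lists of fired
#' ETAT signs and Smart Triage triggers. Reading the file back with
#' [read_assignments()] reproduces every category exactly.
#'
#' @param assignments Tibble from [triage_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  out <- assignments
  for (nm in names(out)) {
    if (is.list(out[[nm]])) {
      out[[nm]] <- vapply(out[[nm]], function(x) paste(x, collapse = ";"),
                          character(1))
    }
    if (is.factor(out[[nm]])) out[[nm]] <- as.character(out[[nm]])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read triage assignments written by [write_assignments()]
#'
#' @param path CSV path.
#' @return Tibble with ordered-factor categories and list-columns of
#'   fired signs/triggers.
#' @export
read_assignments <- function(path) {
  out <- readr::read_csv(path, progress = FALSE, show_col_types = FALSE)
  cat_cols <- intersect(c("etat", "st_model_only", "st_with_triggers",
                          "st_recalibrated_with_triggers"), names(out))
  for (nm in cat_cols) out[[nm]] <- triage_category(out[[nm]])
  list_cols <- intersect(c("etat_emergency_signs", "etat_priority_signs",
                           "emergency_triggers", "priority_triggers"),
                         names(out))
  for (nm in list_cols) {
    out[[nm]] <- lapply(strsplit(ifelse(is.na(out[[nm]]), "", out[[nm]]), ";",
                                 fixed = TRUE),
                        function(x) x[nzchar(x)])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
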