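#' Smart Triage predictor labels
#'
#' The nine predictors of the Smart Triage admission-risk model: five
#' continuous (age, temperature, heart rate, transformed oxygen
#' saturation, MUAC) and four categorical coded 0/1 (difficulty
#' breathing, pallor, oedema, parental concern).
#'
#' @return Character vector of the nine predictor labels.
#' @export
st_predictors <- function() {
  c("age", "temperature", "heart_rate", "spo2_transformed", "muac",
    "difficulty_breathing", "pallor", "oedema", "parental_concern")
}

#' Construct a Smart Triage model specification
#'
#' Bundles the logistic-regression intercept and coefficients, the
#' oxygen-saturation transform, and the dual risk thresholds that map
#' predicted admission probability to a triage category.
#'
#' @param intercept Intercept on the logit scale.
#' @param coefficients Named numeric vector/list over exactly the nine
#'   labels of [st_predictors()]; unknown keys are rejected.
#' @param spo2_transform List with `name` (one of `"identity"`,
#'   `"affine"`, `"sqrt_deficit"`) and `params` (for `"affine"`: `a`,
#'   `b`, giving a + b * spo2). Applied to `spo2_percent` before its
#'   coefficient is used.
#' @param low_threshold,high_threshold Risk thresholds on the
#'   probability scale; 0 < low < high < 1. Probabilities at or above
#'   `high_threshold` are emergency, in [low, high) priority, below
#'   `low_threshold` non-urgent.
#' @param label Free-text model label used in outputs.
#' @return Object of class `st_model_spec`.
#' @export
#' @examples
#' model_spec(-4, setNames(rep(0, 9), st_predictors()), low_threshold = 0.08,
#'            high_threshold = 0.40)
model_spec <- function(intercept, coefficients,
                       spo2_transform = list(name = "identity", params = list()),
                       low_threshold, high_threshold, label = "smart-triage") {
  coefficients <- unlist(coefficients)
  extra <- setdiff(names(coefficients), st_predictors())
  miss <- setdiff(st_predictors(), names(coefficients))
  if (length(extra) > 0) {
    stop("unknown predictor key(s) in coefficients: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (length(miss) > 0) {
    stop("coefficients missing predictor key(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  stopifnot(is.numeric(intercept), length(intercept) == 1, is.finite(intercept))
  if (!(is.numeric(low_threshold) && is.numeric(high_threshold) &&
        low_threshold > 0 && low_threshold < high_threshold &&
        high_threshold < 1)) {
    stop("thresholds must satisfy 0 < low_threshold < high_threshold < 1",
         call. = FALSE)
  }
  spo2_transform$name <- match.arg(spo2_transform$name,
                                   c("identity", "affine", "sqrt_deficit"))
  spo2_transform$params <- spo2_transform$params %||% list()
  structure(
    list(intercept = intercept,
         coefficients = coefficients[st_predictors()],
         spo2_transform = spo2_transform,
         low_threshold = low_threshold,
         high_threshold = high_threshold,
         label = label),
    class = "st_model_spec")
}

#' @export
print.st_model_spec <- function(x, ...) {
  cat("<st_model_spec> ", x$label, "\n", sep = "")
  cat("  intercept: ", format(x$intercept), "\n", sep = "")
  cat("  thresholds: low ", format(x$low_threshold), ", high ",
      format(x$high_threshold), "\n", sep = "")
  cat("  spo2 transform: ", x$spo2_transform$name, "\n", sep = "")
  coef_str <- paste(names(x$coefficients), format(unname(x$coefficients)),
                    sep = " = ")
  cat("  coefficients:\n")
  for (s in coef_str) cat("    ", s, "\n", sep = "")
  invisible(x)
}

apply_spo2_transform <- function(spo2, transform) {
  switch(transform$name,
         identity = spo2,
         affine = (transform$params$a %||% 0) + (transform$params$b %||% 1) * spo2,
         sqrt_deficit = sqrt(pmax(100 - spo2, 0)))
}

#' Read a model specification from YAML or JSON
#'
#' The file must hold fields `intercept`, `coefficients` (exactly the
#' nine named keys), `low_threshold`, `high_threshold`, and optionally
#' `spo2_transform` (`name`, `params`) and `label`. Unknown top-level or
#' predictor keys are rejected.
#'
#' @param path File path (.yaml/.yml or .json).
#' @return An `st_model_spec`.
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path)) stop("model spec file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- c("intercept", "coefficients", "spo2_transform",
               "low_threshold", "high_threshold", "label")
  extra <- setdiff(names(raw), allowed)
  if (length(extra) > 0) {
    stop("unknown field(s) in model spec file: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  for (f in c("intercept", "coefficients", "low_threshold", "high_threshold")) {
    if (is.null(raw[[f]])) stop("model spec file missing field: ", f, call. = FALSE)
  }
  model_spec(
    intercept = as.numeric(raw$intercept),
    coefficients = unlist(raw$coefficients),
    spo2_transform = raw$spo2_transform %||% list(name = "identity", params = list()),
    low_threshold = as.numeric(raw$low_threshold),
    high_threshold = as.numeric(raw$high_threshold),
    label = raw$label %||% "smart-triage"
  )
}

#' Write a model specification to YAML
#'
#' @param spec An `st_model_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  yaml::write_yaml(list(
    label = spec$label,
    intercept = spec$intercept,
    coefficients = as.list(spec$coefficients),
    spo2_transform = spec$spo2_transform,
    low_threshold = spec$low_threshold,
    high_threshold = spec$high_threshold
  ), path)
  invisible(path)
}

#' Packaged example model specifications
#'
#' Returns one of the model specifications shipped with the package.
#' These carry PLACEHOLDER, NON-CLINICAL coefficients chosen only to be
#' directionally sensible (risk rises with temperature and heart rate,
#' falls with SpO2 and MUAC) for use with the synthetic cohort
#' generator; the published Smart Triage coefficients are not included.
#' Users holding the published model can load it with
#' [read_model_spec()]. The `"original"` spec carries the 8\%/40\% risk
#' thresholds; `"recalibrated"` carries the 2.6\%/13\% thresholds and is
#' meant to be combined with an intercept refit via
#' [recalibrate_model_spec()].
#'
#' @param which `"original"` or `"recalibrated"`.
#' @return An `st_model_spec`.
#' @export
#' @examples
#' example_model_spec("original")
example_model_spec <- function(which = c("original", "recalibrated")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("model_", which, "_synthetic.yaml"),
                      package = "smarttriage")
  read_model_spec(path)
}
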