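#' Smart Triage linear predictor
#'
#' Computes intercept + sum of coefficient times predictor for each
#' patient. Continuous predictors are taken in the cohort's canonical
#' units (age in months, temperature degC, heart rate bpm, MUAC mm);
#' oxygen saturation is passed through the spec's transform first. The
#' four categorical predictors (difficulty breathing, pallor, oedema,
#' parental concern) are coded 0/1 and, unlike in the rule engines, may
#' not be unknown: a missing value is an error naming the fields.
#'
#' @param cohort Validated cohort tibble.
#' @param spec An [model_spec()] object.
#' @return Numeric vector of logit-scale scores.
#' @export
linear_predictor <- function(cohort, spec) {
  stopifnot(inherits(spec, "st_model_spec"))
  cats <- c(difficulty_breathing = "difficulty_breathing", pallor = "pallor",
            oedema = "oedema", parental_concern = "parental_concern")
  miss <- names(cats)[vapply(cats, function(col) anyNA(cohort[[col]]), logical(1))]
  if (length(miss) > 0) {
    stop("missing predictor value(s) for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  b <- spec$coefficients
  spec$intercept +
    b[["age"]] * cohort$age_months +
    b[["temperature"]] * cohort$temperature_c +
    b[["heart_rate"]] * cohort$heart_rate_bpm +
    b[["spo2_transformed"]] *
      apply_spo2_transform(cohort$spo2_percent, spec$spo2_transform) +
    b[["muac"]] * cohort$muac_mm +
    b[["difficulty_breathing"]] * as.numeric(cohort$difficulty_breathing) +
    b[["pallor"]] * as.numeric(cohort$pallor) +
    b[["oedema"]] * as.numeric(cohort$oedema) +
    b[["parental_concern"]] * as.numeric(cohort$parental_concern)
}

#' Predicted admission probability
#'
#' Logistic transform of [linear_predictor()]; strictly increasing in
#' the linear predictor.
#'
#' @inheritParams linear_predictor
#' @return Numeric vector of probabilities in (0, 1).
#' @export
admission_probability <- function(cohort, spec) {
  stats::plogis(linear_predictor(cohort, spec))
}

#' Map admission probabilities to triage categories
#'
#' Dual-threshold rule: probability at or above the high threshold is
#' emergency; at or above the low threshold but below the high is
#' priority; below the low threshold is non-urgent. Boundaries are
#' inclusive at the lower edge of each risk band ("at least this risk").
#'
#' @param prob Numeric vector of probabilities in [0, 1].
#' @param spec An [model_spec()] carrying the thresholds.
#' @return Ordered triage-category factor.
#' @export
#' @examples
#' m <- example_model_spec("original") # thresholds 0.08 / 0.40
#' classify_by_risk(c(0.05, 0.10, 0.40), m)
classify_by_risk <- function(prob, spec) {
  stopifnot(inherits(spec, "st_model_spec"),
            all(prob >= 0 & prob <= 1))
  triage_category(ifelse(prob >= spec$high_threshold, "emergency",
                         ifelse(prob >= spec$low_threshold, "priority",
                                "non-urgent")))
}

#' Merge a model category with independent triggers
#'
#' Returns the maximum severity of the model category, emergency (if any
#' emergency trigger fired) and priority (if any priority trigger
#' fired). Triggers can only raise a category, never demote it.
#'
#' @param model_cat Triage categories (character or ordered factor).
#' @param emergency_triggers,priority_triggers List-columns of fired
#'   trigger labels, as from [evaluate_triggers()].
#' @return Ordered triage-category factor.
#' @export
combine_with_triggers <- function(model_cat, emergency_triggers, priority_triggers) {
  n_em <- lengths(emergency_triggers)
  n_pr <- lengths(priority_triggers)
  trig_cat <- ifelse(n_em > 0, "emergency",
                     ifelse(n_pr > 0, "priority", "non-urgent"))
  max_severity(model_cat, trig_cat)
}

#' Recalibration-in-the-large: intercept offset refit
#'
#' Re-estimates only the model intercept on a new population, holding
#' every coefficient fixed: finds the offset delta maximizing the
#' Bernoulli log-likelihood of plogis(lp + delta). At the optimum the
#' mean predicted probability equals the observed prevalence (the score
#' equation). Solved by a bisection-safeguarded Newton iteration on the
#' score, tolerance 1e-10, at most 100 iterations.
#'
#' @param lp Numeric vector of frozen linear predictors (logit scale).
#' @param outcomes Logical (or 0/1) outcome vector, same length as `lp`;
#'   must contain at least one success and one failure.
#' @param tol Convergence tolerance on the mean score.
#' @param max_iter Maximum Newton iterations.
#' @return The intercept offset delta (numeric scalar), with the number
#'   of iterations in attribute `"iterations"`.
#' @export
#' @examples
#' recalibrate_in_the_large(rep(0, 8), c(rep(TRUE, 2), rep(FALSE, 6)))
#' log(0.25 / 0.75) # closed form for constant lp
recalibrate_in_the_large <- function(lp, outcomes, tol = 1e-10, max_iter = 100) {
  y <- as.numeric(outcomes)
  if (length(lp) != length(y) || length(y) < 2) {
    stop("lp and outcomes must have equal length >= 2", call. = FALSE)
  }
  if (all(y == 1) || all(y == 0)) {
    stop("degenerate outcomes: need at least one event and one non-event",
         call. = FALSE)
  }
  ybar <- mean(y)
  score <- function(d) mean(stats::plogis(lp + d)) - ybar
  # score is strictly increasing in delta; bracket then Newton with bisection fallback
  lo <- -40; hi <- 40
  if (score(lo) > 0 || score(hi) < 0) {
    stop("recalibration failed to bracket a root; score(", lo, ") = ",
         score(lo), ", score(", hi, ") = ", score(hi), call. = FALSE)
  }
  delta <- log(ybar / (1 - ybar)) - mean(lp)  # cheap starting value
  delta <- min(max(delta, lo), hi)
  for (iter in seq_len(max_iter)) {
    p <- stats::plogis(lp + delta)
    g <- mean(p) - ybar
    if (abs(g) <= tol) {
      return(structure(delta, iterations = iter - 1L))
    }
    if (g > 0) hi <- delta else lo <- delta
    dg <- mean(p * (1 - p))
    step <- if (dg > 0) g / dg else NA_real_
    cand <- delta - step
    delta <- if (is.finite(cand) && cand > lo && cand < hi) cand else (lo + hi) / 2
  }
  g <- mean(stats::plogis(lp + delta)) - ybar
  if (abs(g) <= tol) return(structure(delta, iterations = as.integer(max_iter)))
  stop(sprintf(
    "recalibration did not converge in %d iterations (delta = %g, score = %g)",
    max_iter, delta, g), call. = FALSE)
}

#' Refit a model spec's intercept on a cohort
#'
#' Applies [recalibrate_in_the_large()] to a cohort's linear predictors
#' and admission outcomes (restricted to outcome-known patients) and
#' returns a new spec with the shifted intercept, unchanged
#' coefficients, and (optionally) new risk thresholds.
#'
#' @param spec The original `st_model_spec`.
#' @param cohort Validated cohort tibble with outcomes.
#' @param low_threshold,high_threshold Thresholds for the recalibrated
#'   spec; default keeps the original's.
#' @param label Label for the new spec.
#' @return A new `st_model_spec` with attribute `"delta"` holding the
#'   fitted offset.
#' @export
recalibrate_model_spec <- function(spec, cohort,
                                   low_threshold = spec$low_threshold,
                                   high_threshold = spec$high_threshold,
                                   label = paste0(spec$label, " (recalibrated)")) {
  keep <- cohort$outcome_known
  delta <- recalibrate_in_the_large(linear_predictor(cohort[keep, ], spec),
                                    cohort$admitted[keep])
  out <- model_spec(
    intercept = spec$intercept + as.numeric(delta),
    coefficients = spec$coefficients,
    spo2_transform = spec$spo2_transform,
    low_threshold = low_threshold,
    high_threshold = high_threshold,
    label = label)
  attr(out, "delta") <- as.numeric(delta)
  out
}

#' Triage a cohort under every system
#'
#' Runs the ETAT rule engine, the Smart Triage model (original and
#' recalibrated specs), the independent triggers, and the trigger merge,
#' returning one assignment row per patient with a full audit trail.
#' Deterministic given its inputs.
#'
#' @param cohort Validated cohort tibble.
#' @param model Original `st_model_spec`.
#' @param model_recal Recalibrated `st_model_spec` (defaults to `model`,
#'   i.e. no recalibration).
#' @param shock_rule Passed to [evaluate_triggers()].
#' @param include_obstructed_breathing Passed to [classify_etat()].
#' @return Tibble with columns `patient_id`, `etat`,
#'   `etat_emergency_signs`, `etat_priority_signs`, `st_probability`,
#'   `st_probability_recalibrated`, `st_model_only`, `st_with_triggers`,
#'   `st_recalibrated_with_triggers`, `emergency_triggers`,
#'   `priority_triggers`.
#' @export
#' @examples
#' m <- example_model_spec("original")
#' triage_cohort(new_cohort(2, spo2_percent = c(88, 99)), m)
triage_cohort <- function(cohort, model, model_recal = model,
                          shock_rule = c("cool_and_any", "refill_or_pulse"),
                          include_obstructed_breathing = FALSE) {
  shock_rule <- match.arg(shock_rule)
  if (anyDuplicated(cohort$patient_id)) {
    stop("duplicate patient_id values in cohort", call. = FALSE)
  }
  etat_res <- classify_etat(cohort, include_obstructed_breathing)
  trig <- evaluate_triggers(cohort, shock_rule)
  p_orig <- admission_probability(cohort, model)
  p_recal <- admission_probability(cohort, model_recal)
  model_only <- classify_by_risk(p_orig, model)
  recal_only <- classify_by_risk(p_recal, model_recal)
  tibble::tibble(
    patient_id = cohort$patient_id,
    etat = etat_res$etat,
    etat_emergency_signs = etat_res$etat_emergency_signs,
    etat_priority_signs = etat_res$etat_priority_signs,
    st_probability = p_orig,
    st_probability_recalibrated = p_recal,
    st_model_only = model_only,
    st_with_triggers = combine_with_triggers(model_only,
                                             trig$emergency_triggers,
                                             trig$priority_triggers),
    st_recalibrated_with_triggers = combine_with_triggers(
      recal_only, trig$emergency_triggers, trig$priority_triggers),
    emergency_triggers = trig$emergency_triggers,
    priority_triggers = trig$priority_triggers
  )
}
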