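#' Triage category levels
#'
#' The three acuity levels shared by ETAT and Smart Triage, in increasing
#' order of urgency: non-urgent < priority < emergency.
#'
#' @return Character vector of the three levels, lowest first.
#' @export
#' @examples
#' triage_levels()
triage_levels <- function() c("non-urgent", "priority", "emergency")

#' Construct an ordered triage-category factor
#'
#' @param x Character vector with values among [triage_levels()].
#' @return Ordered factor with levels non-urgent < priority < emergency.
#' @export
#' @examples
#' triage_category(c("priority", "emergency")) > "non-urgent"
triage_category <- function(x) {
  bad <- setdiff(unique(as.character(x[!is.na(x)])), triage_levels())
  if (length(bad) > 0) {
    stop("unknown triage category label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(as.character(x), levels = triage_levels(), ordered = TRUE)
}

#' Maximum severity of a set of triage categories
#'
#' @param ... Triage categories (characters or ordered factors), recycled
#'   element-wise; the parallel maximum under the category order is returned.
#' @return Ordered triage-category factor.
#' @export
#' @examples
#' max_severity("non-urgent", "priority") # priority
max_severity <- function(...) {
  args <- lapply(list(...), function(x) as.integer(triage_category(x)))
  idx <- do.call(pmax, args)
  triage_category(triage_levels()[idx])
}

#' Clinical sign vocabulary
#'
#' All boolean clinical-sign fields a patient record may carry. Signs are
#' tri-state on input (TRUE / FALSE / NA = not elicited); both rule engines
#' treat NA as FALSE, with a warning, since a sign that was not elicited
#' cannot fire a rule.
#'
#' @return Character vector of sign column names.
#' @export
sign_vocabulary <- function() {
  c("cyanosis", "grunting", "stridor", "capillary_refill_gt3s",
    "weak_central_pulse", "weak_radial_pulse", "cool_skin",
    "convulsions_now", "not_alert_avpu", "diarrhoea", "sunken_eyes",
    "cannot_sit_or_drink", "slow_skin_pinch", "lethargy", "trauma",
    "major_trauma", "burns", "pallor", "severe_pain", "poisoning",
    "chest_indrawing", "urgent_referral", "irritable",
    "visible_severe_wasting", "oedema", "unresponsive", "not_breathing",
    "obstructed_breathing", "accessory_muscle_use", "head_nodding",
    "not_eating_drinking_respiratory", "difficulty_breathing",
    "parental_concern")
}

#' Vital-sign columns and their physiologic validation bounds
#'
#' Bounds are validation limits, not reference ranges: a value outside them
#' is rejected as a data error rather than clipped.
#'
#' @return Tibble with columns `vital`, `lower`, `upper`, `unit`.
#' @export
vital_bounds <- function() {
  tibble::tibble(
    vital = c("temperature_c", "heart_rate_bpm", "respiratory_rate_bpm",
              "spo2_percent", "muac_mm"),
    lower = c(30, 20, 5, 0, 50),
    upper = c(43, 300, 150, 100, 300),
    unit  = c("degC", "bpm", "breaths/min", "%", "mm")
  )
}

# canonical column order for a cohort tibble
cohort_columns <- function() {
  c("patient_id", "age_months", "sex",
    vital_bounds()$vital, sign_vocabulary(),
    "admitted", "died", "outcome_known")
}
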