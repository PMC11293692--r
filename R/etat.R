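#' Age-dependent fast-breathing rule
#'
#' Fast breathing thresholds by age band: under 2 months, RR > 60; 2 to
#' under 12 months, RR > 50; 12 months and above, RR > 40 breaths per
#' minute. Comparisons are strict.
#'
#' @param age_months Nonnegative age in (possibly fractional) months.
#' @param rr Respiratory rate, breaths per minute.
#' @return Logical vector.
#' @export
#' @examples
#' fast_breathing(c(1, 10, 24), c(61, 50, 41)) # TRUE FALSE TRUE
fast_breathing <- function(age_months, rr) {
  stopifnot(all(age_months >= 0), all(rr > 0))
  threshold <- ifelse(age_months < 2, 60, ifelse(age_months < 12, 50, 40))
  rr > threshold
}

# NA = sign not elicited; cannot fire a rule
sgn <- function(cohort, name) {
  x <- cohort[[name]]
  !is.na(x) & x
}

# per-patient logical matrix of ETAT emergency criteria
etat_emergency_matrix <- function(cohort, include_obstructed_breathing = FALSE) {
  m <- cbind(
    cyanosis = sgn(cohort, "cyanosis"),
    `severe respiratory distress` =
      cohort$spo2_percent < 90 | sgn(cohort, "cyanosis") |
      sgn(cohort, "grunting") | sgn(cohort, "stridor"),
    circulation =
      sgn(cohort, "capillary_refill_gt3s") &
      (sgn(cohort, "weak_central_pulse") | sgn(cohort, "weak_radial_pulse")) &
      sgn(cohort, "cool_skin"),
    convulsions = sgn(cohort, "convulsions_now"),
    `not alert` = sgn(cohort, "not_alert_avpu"),
    `severe dehydration` =
      sgn(cohort, "diarrhoea") &
      (sgn(cohort, "sunken_eyes") + sgn(cohort, "cannot_sit_or_drink") +
         sgn(cohort, "slow_skin_pinch")) >= 2
  )
  if (include_obstructed_breathing) {
    m <- cbind(m, `obstructed or absent breathing` =
                 sgn(cohort, "obstructed_breathing") | sgn(cohort, "not_breathing"))
  }
  m
}

# per-patient logical matrix of ETAT priority criteria
etat_priority_matrix <- function(cohort) {
  cbind(
    `tiny infant` = cohort$age_months < 2,
    fever = cohort$temperature_c >= 37.5,
    trauma = sgn(cohort, "trauma"),
    pallor = sgn(cohort, "pallor"),
    `severe pain` = sgn(cohort, "severe_pain"),
    poisoning = sgn(cohort, "poisoning"),
    `respiratory distress` =
      sgn(cohort, "chest_indrawing") |
      fast_breathing(cohort$age_months, cohort$respiratory_rate_bpm),
    `urgent referral` = sgn(cohort, "urgent_referral"),
    irritable = sgn(cohort, "irritable"),
    `visible severe wasting` = sgn(cohort, "visible_severe_wasting"),
    oedema = sgn(cohort, "oedema"),
    burns = sgn(cohort, "burns")
  )
}

matrix_to_labels <- function(m) {
  labs <- colnames(m)
  lapply(seq_len(nrow(m)), function(i) labs[m[i, ]])
}

#' ETAT emergency signs firing for each patient
#'
#' Evaluates the ETAT emergency criteria: central cyanosis; severe
#' respiratory distress (SpO2 < 90\% or cyanosis, grunting or stridor);
#' the circulation triad (capillary refill > 3 s AND a weak central or
#' radial pulse AND cool skin); convulsions; not alert on AVPU; and
#' severe dehydration (diarrhoea plus at least two of sunken eyes,
#' cannot sit or drink, slow skin pinch).
#'
#' Obstructed/absent breathing is excluded by default because the
#' evaluation dataset this engine mirrors did not collect it; set
#' `include_obstructed_breathing = TRUE` to add it for other uses.
#'
#' @param cohort Validated cohort tibble.
#' @param include_obstructed_breathing Include the airway criterion.
#' @return List of character vectors, one per patient, of firing
#'   emergency criteria.
#' @export
etat_emergency_signs <- function(cohort, include_obstructed_breathing = FALSE) {
  matrix_to_labels(etat_emergency_matrix(cohort, include_obstructed_breathing))
}

#' ETAT priority signs firing for each patient
#'
#' Evaluates the ETAT priority criteria: tiny infant (age < 2 months),
#' fever (temperature >= 37.5 degC, inclusive), trauma, pallor, severe
#' pain, poisoning, respiratory distress (chest indrawing or age-banded
#' fast breathing), urgent referral, irritability, visible severe
#' wasting, oedema, and burns.
#'
#' @inheritParams etat_emergency_signs
#' @return List of character vectors, one per patient.
#' @export
etat_priority_signs <- function(cohort) {
  matrix_to_labels(etat_priority_matrix(cohort))
}

#' Classify a cohort with the ETAT rule engine
#'
#' A patient with any emergency sign is an emergency; otherwise any
#' priority sign makes them priority; a child without any of the signs
#' is non-urgent.
#'
#' @inheritParams etat_emergency_signs
#' @return Tibble with `patient_id`, ordered-factor `etat` category, and
#'   list-columns `etat_emergency_signs`, `etat_priority_signs` (the
#'   audit trail of firing criteria).
#' @export
#' @examples
#' classify_etat(new_cohort(3, spo2_percent = c(88, 98, 98),
#'                          temperature_c = c(38.5, 38.5, 37.0)))
classify_etat <- function(cohort, include_obstructed_breathing = FALSE) {
  em <- etat_emergency_matrix(cohort, include_obstructed_breathing)
  pm <- etat_priority_matrix(cohort)
  any_em <- rowSums(em) > 0
  any_pr <- rowSums(pm) > 0
  category <- triage_category(
    ifelse(any_em, "emergency", ifelse(any_pr, "priority", "non-urgent")))
  tibble::tibble(
    patient_id = cohort$patient_id,
    etat = category,
    etat_emergency_signs = matrix_to_labels(em),
    etat_priority_signs = matrix_to_labels(pm)
  )
}
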