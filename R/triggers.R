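#' Smart Triage independent emergency triggers
#'
#' Single signs or vital-sign thresholds that force the emergency
#' category regardless of the model probability: unresponsive;
#' convulsions; shock (cool skin with capillary refill > 3 s or a weak
#' pulse); major trauma; severe pain; not breathing; obstructed
#' breathing; central cyanosis; dehydration (at least 2 of sunken eyes,
#' slow skin pinch, lethargy — note, unlike the ETAT severe-dehydration
#' rule, diarrhoea is not required); heart rate < 45 bpm; SpO2 < 90\%.
#' All numeric comparisons are strict.
#'
#' @param cohort Validated cohort tibble.
#' @param shock_rule How to parenthesize the shock composite:
#'   `"cool_and_any"` (default) reads "cool hands with (capillary refill
#'   > 3 s or weak pulse)" as cool AND (refill OR weak pulse);
#'   `"refill_or_pulse"` uses the alternative reading
#'   (cool AND refill) OR weak pulse.
#' @return List of character vectors, one per patient, of firing
#'   emergency triggers.
#' @export
#' @examples
#' emergency_triggers(new_cohort(1, heart_rate_bpm = 40))
emergency_triggers <- function(cohort, shock_rule = c("cool_and_any", "refill_or_pulse")) {
  shock_rule <- match.arg(shock_rule)
  matrix_to_labels(emergency_trigger_matrix(cohort, shock_rule))
}

emergency_trigger_matrix <- function(cohort, shock_rule = "cool_and_any") {
  weak_pulse <- sgn(cohort, "weak_central_pulse") | sgn(cohort, "weak_radial_pulse")
  shock <- if (shock_rule == "cool_and_any") {
    sgn(cohort, "cool_skin") & (sgn(cohort, "capillary_refill_gt3s") | weak_pulse)
  } else {
    (sgn(cohort, "cool_skin") & sgn(cohort, "capillary_refill_gt3s")) | weak_pulse
  }
  cbind(
    unresponsive = sgn(cohort, "unresponsive"),
    convulsions = sgn(cohort, "convulsions_now"),
    shock = shock,
    `major trauma` = sgn(cohort, "major_trauma"),
    `severe pain` = sgn(cohort, "severe_pain"),
    `not breathing` = sgn(cohort, "not_breathing"),
    `obstructed breathing` = sgn(cohort, "obstructed_breathing"),
    cyanosis = sgn(cohort, "cyanosis"),
    dehydration = (sgn(cohort, "sunken_eyes") + sgn(cohort, "slow_skin_pinch") +
                     sgn(cohort, "lethargy")) >= 2,
    `low heart rate` = cohort$heart_rate_bpm < 45,
    `low oxygen saturation` = cohort$spo2_percent < 90
  )
}

#' Smart Triage independent priority triggers
#'
#' Triggers that force at least the priority category: trauma; burns;
#' poisoning; urgent referral; the difficulty-breathing composite (not
#' eating/drinking due to respiratory problems, chest indrawing,
#' accessory muscle use, or head nodding); irritability; respiratory
#' rate > 60; temperature > 40 degC or < 35 degC; MUAC < 115 mm. All
#' numeric comparisons are strict.
#'
#' @param cohort Validated cohort tibble.
#' @return List of character vectors, one per patient.
#' @export
#' @examples
#' priority_triggers(new_cohort(1, muac_mm = 110))
priority_triggers <- function(cohort) {
  matrix_to_labels(priority_trigger_matrix(cohort))
}

priority_trigger_matrix <- function(cohort) {
  cbind(
    trauma = sgn(cohort, "trauma"),
    burns = sgn(cohort, "burns"),
    poisoning = sgn(cohort, "poisoning"),
    `urgent referral` = sgn(cohort, "urgent_referral"),
    `difficulty breathing` =
      sgn(cohort, "not_eating_drinking_respiratory") |
      sgn(cohort, "chest_indrawing") |
      sgn(cohort, "accessory_muscle_use") | sgn(cohort, "head_nodding"),
    irritable = sgn(cohort, "irritable"),
    `fast respiratory rate` = cohort$respiratory_rate_bpm > 60,
    `temperature extreme` = cohort$temperature_c > 40 | cohort$temperature_c < 35,
    `low MUAC` = cohort$muac_mm < 115
  )
}

#' Evaluate both trigger sets on a cohort
#'
#' @inheritParams emergency_triggers
#' @return Tibble with `patient_id` and list-columns
#'   `emergency_triggers`, `priority_triggers`.
#' @export
evaluate_triggers <- function(cohort, shock_rule = c("cool_and_any", "refill_or_pulse")) {
  shock_rule <- match.arg(shock_rule)
  tibble::tibble(
    patient_id = cohort$patient_id,
    emergency_triggers = emergency_triggers(cohort, shock_rule),
    priority_triggers = priority_triggers(cohort)
  )
}
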