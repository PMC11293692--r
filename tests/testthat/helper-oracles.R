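# Independent brute-force rule implementations, written scalar-by-scalar
# straight from the clinical rule tables. These never share code with the
# package's vectorized engines; they exist to cross-check them.

oracle_record <- function(cohort, i) {
  as.list(cohort[i, ])
}

# TRUE only if the sign was elicited and positive
ob <- function(r, s) isTRUE(r[[s]])

oracle_etat_category <- function(r) {
  emergency <- FALSE
  if (ob(r, "cyanosis")) emergency <- TRUE
  if (r$spo2_percent < 90 || ob(r, "cyanosis") || ob(r, "grunting") ||
      ob(r, "stridor")) emergency <- TRUE
  if (ob(r, "capillary_refill_gt3s") &&
      (ob(r, "weak_central_pulse") || ob(r, "weak_radial_pulse")) &&
      ob(r, "cool_skin")) emergency <- TRUE
  if (ob(r, "convulsions_now")) emergency <- TRUE
  if (ob(r, "not_alert_avpu")) emergency <- TRUE
  dehydration_subsigns <- ob(r, "sunken_eyes") + ob(r, "cannot_sit_or_drink") +
    ob(r, "slow_skin_pinch")
  if (ob(r, "diarrhoea") && dehydration_subsigns >= 2) emergency <- TRUE
  if (emergency) return("emergency")

  priority <- FALSE
  if (r$age_months < 2) priority <- TRUE
  if (r$temperature_c >= 37.5) priority <- TRUE
  for (s in c("trauma", "pallor", "severe_pain", "poisoning",
              "urgent_referral", "irritable", "visible_severe_wasting",
              "oedema", "burns")) {
    if (ob(r, s)) priority <- TRUE
  }
  rr_cut <- if (r$age_months < 2) 60 else if (r$age_months < 12) 50 else 40
  if (ob(r, "chest_indrawing") || r$respiratory_rate_bpm > rr_cut) {
    priority <- TRUE
  }
  if (priority) "priority" else "non-urgent"
}

oracle_emergency_triggers <- function(r) {
  fired <- character()
  if (ob(r, "unresponsive")) fired <- c(fired, "unresponsive")
  if (ob(r, "convulsions_now")) fired <- c(fired, "convulsions")
  weak <- ob(r, "weak_central_pulse") || ob(r, "weak_radial_pulse")
  if (ob(r, "cool_skin") && (ob(r, "capillary_refill_gt3s") || weak)) {
    fired <- c(fired, "shock")
  }
  if (ob(r, "major_trauma")) fired <- c(fired, "major trauma")
  if (ob(r, "severe_pain")) fired <- c(fired, "severe pain")
  if (ob(r, "not_breathing")) fired <- c(fired, "not breathing")
  if (ob(r, "obstructed_breathing")) fired <- c(fired, "obstructed breathing")
  if (ob(r, "cyanosis")) fired <- c(fired, "cyanosis")
  if (ob(r, "sunken_eyes") + ob(r, "slow_skin_pinch") + ob(r, "lethargy") >= 2) {
    fired <- c(fired, "dehydration")
  }
  if (r$heart_rate_bpm < 45) fired <- c(fired, "low heart rate")
  if (r$spo2_percent < 90) fired <- c(fired, "low oxygen saturation")
  fired
}

oracle_priority_triggers <- function(r) {
  fired <- character()
  if (ob(r, "trauma")) fired <- c(fired, "trauma")
  if (ob(r, "burns")) fired <- c(fired, "burns")
  if (ob(r, "poisoning")) fired <- c(fired, "poisoning")
  if (ob(r, "urgent_referral")) fired <- c(fired, "urgent referral")
  if (ob(r, "not_eating_drinking_respiratory") || ob(r, "chest_indrawing") ||
      ob(r, "accessory_muscle_use") || ob(r, "head_nodding")) {
    fired <- c(fired, "difficulty breathing")
  }
  if (ob(r, "irritable")) fired <- c(fired, "irritable")
  if (r$respiratory_rate_bpm > 60) fired <- c(fired, "fast respiratory rate")
  if (r$temperature_c > 40 || r$temperature_c < 35) {
    fired <- c(fired, "temperature extreme")
  }
  if (r$muac_mm < 115) fired <- c(fired, "low MUAC")
  fired
}

# exhaustive 0/1 grid over a set of sign names, as a tibble of overrides
sign_grid <- function(signs) {
  g <- do.call(expand.grid, stats::setNames(
    rep(list(c(FALSE, TRUE)), length(signs)), signs))
  tibble::as_tibble(g)
}

# build a cohort from a tibble of column overrides (one row per patient)
cohort_from_grid <- function(grid, ...) {
  fixed <- list(...)
  args <- c(list(n = nrow(grid)), as.list(grid), fixed)
  do.call(new_cohort, args)
}
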