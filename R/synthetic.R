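#' Default sign loadings for the synthetic cohort generator
#'
#' Each clinical sign is drawn as Bernoulli(plogis(qlogis(base_rate) +
#' slope * severity)) where severity is the child's latent severity
#' draw. Base rates are the sign's prevalence in an average child
#' (severity 0); slopes are nonnegative so that sicker children show
#' more signs. Injury-type signs (trauma, burns, poisoning) get small
#' slopes: they strike mostly at random.
#'
#' @return Tibble with columns `sign`, `base_rate`, `slope`.
#' @export
default_sign_loadings <- function() {
  tibble::tribble(
    ~sign, ~base_rate, ~slope,
    "cyanosis", 0.004, 1.5,
    "grunting", 0.008, 1.5,
    "stridor", 0.006, 1.2,
    "capillary_refill_gt3s", 0.010, 1.5,
    "weak_central_pulse", 0.006, 1.5,
    "weak_radial_pulse", 0.008, 1.5,
    "cool_skin", 0.020, 1.2,
    "convulsions_now", 0.004, 1.5,
    "not_alert_avpu", 0.006, 1.8,
    "diarrhoea", 0.060, 0.5,
    "sunken_eyes", 0.020, 1.0,
    "cannot_sit_or_drink", 0.015, 1.2,
    "slow_skin_pinch", 0.012, 1.2,
    "lethargy", 0.020, 1.5,
    "trauma", 0.040, 0.1,
    "major_trauma", 0.004, 0.8,
    "burns", 0.008, 0.2,
    "pallor", 0.020, 0.8,
    "severe_pain", 0.010, 0.8,
    "poisoning", 0.003, 0.3,
    "chest_indrawing", 0.030, 1.3,
    "urgent_referral", 0.010, 0.8,
    "irritable", 0.050, 0.8,
    "visible_severe_wasting", 0.008, 1.0,
    "oedema", 0.006, 1.0,
    "unresponsive", 0.0015, 2.0,
    "not_breathing", 0.0005, 2.0,
    "obstructed_breathing", 0.001, 1.5,
    "accessory_muscle_use", 0.015, 1.3,
    "head_nodding", 0.008, 1.3,
    "not_eating_drinking_respiratory", 0.020, 1.2,
    "difficulty_breathing", 0.070, 1.2,
    "parental_concern", 0.250, 0.7
  )
}

#' Default vital-sign generative model
#'
#' Vitals are Gaussian around an age-appropriate mean, shifted adversely
#' by the latent severity, then truncated to the validation bounds.
#' `mean` is the mean for a 1-5 year old; internal age adjustments make
#' heart and respiratory rates higher (and MUAC lower) in infants.
#' `shift` is the change per unit severity; for SpO2 and MUAC the shift
#' is applied only for positive severity (healthy children are not
#' supra-normal).
#'
#' @return Tibble with columns `vital`, `mean`, `sd`, `shift`,
#'   `adverse_only`.
#' @export
default_vitals_model <- function() {
  tibble::tribble(
    ~vital, ~mean, ~sd, ~shift, ~adverse_only,
    "temperature_c", 37.1, 0.6, 0.5, FALSE,
    "heart_rate_bpm", 118, 14, 9, FALSE,
    "respiratory_rate_bpm", 28, 5, 4, FALSE,
    "spo2_percent", 97.5, 1.2, -1.8, TRUE,
    "muac_mm", 148, 14, -6, TRUE
  )
}

#' Configuration for the synthetic paediatric-ED cohort generator
#'
#' Defaults emulate the marginal structure of a large two-hospital
#' Kenyan paediatric emergency cohort: the age mixture (3.2\% under 1
#' month, 29.4\% 1-12 months, 55.4\% 1-5 years, 10.8\% 5-12 years,
#' 1.2\% over 12 years), an overall admission rate of 7\%, a mortality
#' rate of 0.9\%, and a 13/5618 fraction of missing hospital outcomes.
#' A standard-normal latent severity drives signs, vitals and outcomes
#' so that sicker children are more likely to be admitted or die.
#'
#' @param n Number of children.
#' @param seed Integer RNG seed.
#' @param admission_rate Target expected admission rate.
#' @param mortality_rate Target expected mortality rate; must be below
#'   `admission_rate`.
#' @param age_mixture Named weights over the five age bands (months)
#'   `[0,1)`, `[1,12)`, `[12,60)`, `[60,144)`, `[144,180)`; must sum to 1.
#' @param sign_loadings Tibble as [default_sign_loadings()].
#' @param vitals_model Tibble as [default_vitals_model()].
#' @param admission_slope,mortality_slope Logistic slopes of the
#'   outcomes on latent severity; intercepts are calibrated so expected
#'   rates hit their targets exactly.
#' @param missing_outcome_rate Fraction of (surviving) children whose
#'   hospital outcome is unknown.
#' @param death_setting_probs Probabilities that a death is in-hospital
#'   (forces admission), on the day of enrolment in the ED, or during
#'   follow-up after discharge; defaults follow the 31/6/12 split of 49
#'   deaths in the reference cohort.
#' @param male_fraction Fraction male (the remainder female).
#' @return Object of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(
    n, seed = 1L,
    admission_rate = 0.07, mortality_rate = 0.009,
    age_mixture = c("0-1m" = 0.032, "1-12m" = 0.294, "12-60m" = 0.554,
                    "60-144m" = 0.108, "144-180m" = 0.012),
    sign_loadings = default_sign_loadings(),
    vitals_model = default_vitals_model(),
    admission_slope = 1.6, mortality_slope = 2.2,
    missing_outcome_rate = 13 / 5618,
    death_setting_probs = c(in_hospital = 31, ed = 6, follow_up = 12) / 49,
    male_fraction = 0.541) {
  stopifnot(n >= 0, n == round(n))
  if (abs(sum(age_mixture) - 1) > 1e-9) {
    stop("age_mixture weights must sum to 1", call. = FALSE)
  }
  if (!(mortality_rate > 0 && mortality_rate < admission_rate &&
        admission_rate < 1)) {
    stop("need 0 < mortality_rate < admission_rate < 1", call. = FALSE)
  }
  stopifnot(length(age_mixture) == 5, all(age_mixture >= 0),
            all(sign_loadings$slope >= 0),
            all(sign_loadings$base_rate > 0 & sign_loadings$base_rate < 1),
            setequal(sign_loadings$sign, sign_vocabulary()),
            setequal(vitals_model$vital, vital_bounds()$vital),
            abs(sum(death_setting_probs) - 1) < 1e-9,
            admission_slope >= 0, mortality_slope >= 0)
  structure(list(
    n = as.integer(n), seed = as.integer(seed),
    admission_rate = admission_rate, mortality_rate = mortality_rate,
    age_mixture = age_mixture, sign_loadings = sign_loadings,
    vitals_model = vitals_model,
    admission_slope = admission_slope, mortality_slope = mortality_slope,
    missing_outcome_rate = missing_outcome_rate,
    death_setting_probs = death_setting_probs,
    male_fraction = male_fraction
  ), class = "synthetic_cohort_config")
}

# solve c for mean(plogis(lp + c)) = target; monotone, so uniroot suffices
calibrate_intercept <- function(lp, target) {
  if (length(lp) == 0) return(stats::qlogis(target))
  stats::uniroot(function(c) mean(stats::plogis(lp + c)) - target,
                 lower = -50, upper = 50, tol = 1e-12)$root
}

age_band_edges <- function() c(0, 1, 12, 60, 144, 180)

#' Generate a synthetic paediatric-ED cohort
#'
#' Deterministic given the config's seed. For each child: draw an age
#' band then a uniform age within it; draw a standard-normal latent
#' severity; draw each clinical sign and each vital from the config's
#' severity-linked laws (vitals truncated to validation bounds); draw
#' death and admission from severity-driven logistic laws whose
#' intercepts are calibrated on the realized severities so the expected
#' rates equal the configured targets. In-hospital deaths force
#' admission (the calibration accounts for this); ED and follow-up
#' deaths may remain unadmitted. Deceased children always have a known
#' outcome; a configurable fraction of the rest have
#' `outcome_known = FALSE`.
#'
#' @param config A [synthetic_cohort_config()].
#' @return Validated cohort tibble with two extra columns: `.severity`
#'   (the latent severity) and `.death_setting` (`"none"`,
#'   `"in_hospital"`, `"ed"`, `"follow_up"`).
#' @export
#' @examples
#' generate_cohort(synthetic_cohort_config(n = 5, seed = 42))
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  n <- config$n
  if (n == 0) {
    out <- new_cohort(0)
    out$.severity <- numeric()
    out$.death_setting <- character()
    return(out)
  }
  set.seed(config$seed)
  edges <- age_band_edges()
  band <- sample.int(5, n, replace = TRUE, prob = config$age_mixture)
  age <- stats::runif(n, edges[band], edges[band + 1])
  sev <- stats::rnorm(n)

  out <- tibble::tibble(
    patient_id = sprintf("S%06d", seq_len(n)),
    age_months = age,
    sex = ifelse(stats::runif(n) < config$male_fraction, "male", "female")
  )

  # age adjustments (relative to the 1-5y reference mean) for HR/RR/MUAC
  hr_adj <- c(25, 15, 0, -18, -28)[band]
  rr_adj <- c(14, 7, 0, -6, -9)[band]
  muac_adj <- c(-38, -22, 0, 22, 38)[band]
  adj <- list(temperature_c = 0, heart_rate_bpm = hr_adj,
              respiratory_rate_bpm = rr_adj, spo2_percent = 0,
              muac_mm = muac_adj)
  bounds <- vital_bounds()
  for (i in seq_len(nrow(config$vitals_model))) {
    vm <- config$vitals_model[i, ]
    s_eff <- if (vm$adverse_only) pmax(sev, 0) else sev
    x <- stats::rnorm(n, vm$mean + adj[[vm$vital]] + vm$shift * s_eff, vm$sd)
    b <- bounds[bounds$vital == vm$vital, ]
    out[[vm$vital]] <- pmin(pmax(x, b$lower), b$upper)
  }

  for (i in seq_len(nrow(config$sign_loadings))) {
    sl <- config$sign_loadings[i, ]
    p <- stats::plogis(stats::qlogis(sl$base_rate) + sl$slope * sev)
    out[[sl$sign]] <- stats::runif(n) < p
  }

  # mortality first, calibrated to its target on the realized severities
  lp_d <- config$mortality_slope * sev
  died <- stats::runif(n) < stats::plogis(lp_d + calibrate_intercept(lp_d, config$mortality_rate))
  setting <- rep("none", n)
  setting[died] <- sample(names(config$death_setting_probs), sum(died),
                          replace = TRUE, prob = config$death_setting_probs)

  # admission: in-hospital deaths are admitted by construction; calibrate
  # the remainder so the overall expected rate still hits the target
  forced <- setting == "in_hospital"
  admitted <- forced
  rest <- !forced
  target_rest <- (config$admission_rate * n - sum(forced)) / max(sum(rest), 1)
  if (target_rest <= 0 || target_rest >= 1) {
    stop("admission target unattainable after forcing in-hospital deaths; ",
         "check admission_rate vs mortality_rate", call. = FALSE)
  }
  lp_a <- config$admission_slope * sev[rest]
  admitted[rest] <- stats::runif(sum(rest)) <
    stats::plogis(lp_a + calibrate_intercept(lp_a, target_rest))

  out$admitted <- admitted
  out$died <- died
  out$outcome_known <- died | (stats::runif(n) >= config$missing_outcome_rate)
  out$.severity <- sev
  out$.death_setting <- setting
  validate_cohort(out[, c(cohort_columns(), ".severity", ".death_setting")],
                  quiet = TRUE)
}

#' Check that outcomes rise with latent severity
#'
#' Stratifies a generated cohort into severity tertiles and reports the
#' admission and mortality rate in each (among outcome-known children),
#' with flags for weak monotone increase across tertiles — the
#' generative property the rest of the pipeline leans on (acuity tracks
#' outcomes).
#'
#' @param cohort Cohort from [generate_cohort()] (must carry
#'   `.severity`).
#' @return List of class `severity_gradient`: `table` (tibble with one
#'   row per tertile), `monotone_admission`, `monotone_mortality`.
#' @export
severity_gradient_check <- function(cohort) {
  if (!".severity" %in% names(cohort)) {
    stop("cohort has no stored latent severity (.severity column)",
         call. = FALSE)
  }
  known <- cohort[cohort$outcome_known, ]
  qs <- stats::quantile(known$.severity, c(0, 1 / 3, 2 / 3, 1))
  tert <- cut(known$.severity, breaks = unique(qs), include.lowest = TRUE,
              labels = FALSE)
  tab <- known |>
    dplyr::mutate(tertile = tert) |>
    dplyr::group_by(.data$tertile) |>
    dplyr::summarise(n = dplyr::n(),
                     admission_rate = mean(.data$admitted),
                     mortality_rate = mean(.data$died), .groups = "drop")
  structure(list(
    table = tab,
    monotone_admission = !is.unsorted(tab$admission_rate),
    monotone_mortality = !is.unsorted(tab$mortality_rate)
  ), class = "severity_gradient")
}

#' @export
print.severity_gradient <- function(x, ...) {
  cat("<severity_gradient>\n")
  print(x$table)
  cat("monotone admission:", x$monotone_admission,
      "| monotone mortality:", x$monotone_mortality, "\n")
  invisible(x)
}
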