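test_that("model spec validates thresholds, keys and files", {
  coefs <- stats::setNames(rep(0, 9), st_predictors())
  expect_error(model_spec(0, coefs, low_threshold = 0.4, high_threshold = 0.08),
               "thresholds")
  expect_error(model_spec(0, c(coefs, bogus = 1), low_threshold = 0.1,
                          high_threshold = 0.4), "unknown predictor")
  expect_error(model_spec(0, coefs[-1], low_threshold = 0.1,
                          high_threshold = 0.4), "missing predictor")

  spec <- placeholder_spec()
  expect_s3_class(spec, "st_model_spec")
  expect_equal(spec$low_threshold, 0.08)
  expect_equal(spec$high_threshold, 0.40)
  expect_equal(placeholder_recal_spec()$low_threshold, 0.026)
  expect_equal(placeholder_recal_spec()$high_threshold, 0.13)

  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(spec, path)
  back <- read_model_spec(path)
  expect_equal(back$coefficients, spec$coefficients)
  expect_equal(back$intercept, spec$intercept)

  # strict schema: unknown top-level fields are rejected
  raw <- yaml::read_yaml(path)
  raw$extra_field <- 1
  yaml::write_yaml(raw, path)
  expect_error(read_model_spec(path), "unknown field")
})

test_that("linear predictor is the coefficient-weighted sum", {
  co <- new_cohort(1, pallor = TRUE, spo2_percent = 90)
  expect_equal(linear_predictor(co, zero_spec(intercept = -2)), -2)
  expect_equal(linear_predictor(co, zero_spec(pallor = 1.5)), 1.5)
  expect_equal(linear_predictor(co, zero_spec(spo2_transformed = -0.1)), -9)
  # additivity across terms
  expect_equal(
    linear_predictor(co, zero_spec(intercept = 1, pallor = 2,
                                   spo2_transformed = -0.1)),
    1 + 2 - 9)
})

test_that("spo2 transforms are applied before the coefficient", {
  co <- new_cohort(1, spo2_percent = 96)
  aff <- zero_spec(spo2_transformed = 1)
  aff$spo2_transform <- list(name = "affine", params = list(a = -100, b = 1))
  expect_equal(linear_predictor(co, aff), -4)
  sq <- zero_spec(spo2_transformed = 1)
  sq$spo2_transform <- list(name = "sqrt_deficit", params = list())
  expect_equal(linear_predictor(co, sq), 2)
})

test_that("a missing categorical predictor is an explicit error", {
  co <- suppressWarnings(new_cohort(1, pallor = NA))
  expect_error(linear_predictor(co, zero_spec()), "missing predictor.*pallor")
})

test_that("admission probability is the logistic of the linear predictor", {
  co <- new_cohort(1)
  expect_equal(admission_probability(co, zero_spec(intercept = 0)), 0.5)
  expect_equal(admission_probability(co, zero_spec(intercept = log(0.08 / 0.92))),
               0.08)
  expect_lt(admission_probability(co, zero_spec(intercept = -30)), 1e-12)
})

test_that("risk classification uses [low, high) and [high, 1] bands", {
  orig <- placeholder_spec()   # 0.08 / 0.40
  recal <- placeholder_recal_spec() # 0.026 / 0.13
  expect_equal(as.character(classify_by_risk(0.05, orig)), "non-urgent")
  expect_equal(as.character(classify_by_risk(0.10, recal)), "priority")
  expect_equal(as.character(classify_by_risk(0.40, orig)), "emergency")
  expect_equal(as.character(classify_by_risk(0.08, orig)), "priority")
  expect_equal(as.character(classify_by_risk(0.079999, orig)), "non-urgent")
  # monotone in probability
  p <- sort(runif(50))
  cats <- classify_by_risk(p, orig)
  expect_false(is.unsorted(cats))
})

test_that("triggers merge by max severity and never demote", {
  expect_equal(as.character(combine_with_triggers(
    triage_category("non-urgent"), list("low heart rate"), list(character()))),
    "emergency")
  expect_equal(as.character(combine_with_triggers(
    triage_category("emergency"), list(character()), list(character()))),
    "emergency")
  expect_equal(as.character(combine_with_triggers(
    triage_category("non-urgent"), list(character()), list("trauma"))),
    "priority")
})

test_that("triage_cohort composes all systems with an audit trail", {
  expect_equal(nrow(triage_cohort(new_cohort(0), placeholder_spec())), 0)

  co <- new_cohort(1, heart_rate_bpm = 40)
  spec <- zero_spec(intercept = qlogis(0.01))
  asg <- triage_cohort(co, spec)
  expect_equal(as.character(asg$st_model_only), "non-urgent")
  expect_equal(as.character(asg$st_with_triggers), "emergency")
  expect_equal(asg$emergency_triggers[[1]], "low heart rate")

  co2 <- generate_cohort(synthetic_cohort_config(n = 30, seed = 5))
  expect_identical(triage_cohort(co2, placeholder_spec()),
                   triage_cohort(co2, placeholder_spec()))
  expect_error(triage_cohort(dplyr::bind_rows(co2, co2), placeholder_spec()),
               "duplicate patient_id")
})

test_that("trigger merge and intercept-shift invariants hold cohort-wide", {
  co <- generate_cohort(synthetic_cohort_config(n = 2000, seed = 17))
  recal <- placeholder_recal_spec()
  recal$intercept <- recal$intercept + 0.7 # any pure intercept shift
  asg <- triage_cohort(co, placeholder_spec(), recal)
  expect_true(all(asg$st_with_triggers >= asg$st_model_only))
  expect_true(all(asg$st_with_triggers[lengths(asg$emergency_triggers) > 0] ==
                    "emergency"))
  # intercept-only recalibration preserves the risk ranking
  expect_identical(order(asg$st_probability),
                   order(asg$st_probability_recalibrated))
})

test_that("raising one contribution never lowers the model category", {
  co <- generate_cohort(synthetic_cohort_config(n = 200, seed = 23))
  spec <- placeholder_spec()
  cats <- classify_by_risk(admission_probability(co, spec), spec)
  bumped <- co
  bumped$temperature_c <- pmin(co$temperature_c + 1.5, 43)
  cats2 <- classify_by_risk(admission_probability(bumped, spec), spec)
  expect_true(all(cats2 >= cats))
})
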