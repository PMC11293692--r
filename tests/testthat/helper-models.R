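# a zeroed model spec whose single nonzero pieces tests set explicitly
zero_spec <- function(intercept = 0, low = 0.08, high = 0.40, ...) {
  coefs <- stats::setNames(rep(0, 9), st_predictors())
  overrides <- list(...)
  coefs[names(overrides)] <- unlist(overrides)
  model_spec(intercept = intercept, coefficients = coefs,
             low_threshold = low, high_threshold = high,
             label = "test")
}

placeholder_spec <- function() example_model_spec("original")
placeholder_recal_spec <- function() example_model_spec("recalibrated")
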