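test_that("triage categories are ordered and max-severity works", {
  expect_equal(triage_levels(), c("non-urgent", "priority", "emergency"))
  cats <- triage_category(c("non-urgent", "priority", "emergency"))
  expect_true(cats[1] < cats[2] && cats[2] < cats[3])
  expect_error(triage_category("urgent"), "unknown triage category")
  expect_equal(as.character(max_severity("non-urgent", "priority")), "priority")
  expect_equal(
    as.character(max_severity(c("emergency", "non-urgent"),
                              c("non-urgent", "non-urgent"))),
    c("emergency", "non-urgent"))
})

test_that("validation rejects out-of-bounds vitals and names the row", {
  expect_error(new_cohort(2, spo2_percent = c(98, 101)),
               "spo2_percent.*row\\(s\\) 2")
  expect_error(new_cohort(1, temperature_c = 29), "temperature_c")
  expect_error(new_cohort(1, heart_rate_bpm = 310), "heart_rate_bpm")
  # accepted records are stable under re-validation
  co <- new_cohort(3, spo2_percent = c(90, 95, 100))
  expect_identical(validate_cohort(co), co)
})

test_that("outcome consistency: died implies outcome_known", {
  expect_error(new_cohort(1, died = TRUE, outcome_known = FALSE),
               "died.*outcome_known")
  expect_silent(new_cohort(1, died = TRUE, admitted = TRUE,
                           outcome_known = TRUE))
})

test_that("unknown signs are allowed but flagged", {
  expect_warning(new_cohort(2, cyanosis = c(NA, FALSE)), "unknown \\(NA\\) sign")
  co <- suppressWarnings(new_cohort(1, cyanosis = NA))
  # an unelicited sign cannot fire a rule
  expect_equal(as.character(classify_etat(co)$etat), "non-urgent")
})

test_that("cohort CSV round-trips losslessly", {
  co <- generate_cohort(synthetic_cohort_config(n = 40, seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), 40)
  expect_identical(back$patient_id, co$patient_id)
  for (v in vital_bounds()$vital) {
    expect_equal(back[[v]], co[[v]], tolerance = 1e-9)
  }
  for (s in sign_vocabulary()) expect_identical(back[[s]], co[[s]])
  expect_identical(back$admitted, co$admitted)
  expect_identical(back$died, co$died)
  # re-write is byte-identical (bitwise stability under re-validation)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(validate_cohort(back), path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("read_cohort parses flexible booleans and reports bad cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  co <- new_cohort(2, cyanosis = c(TRUE, FALSE), admitted = c(TRUE, FALSE))
  write_cohort(co, path)
  lines <- readLines(path)
  # rewrite some booleans in assorted spellings and blank one sign cell
  lines[2] <- sub("TRUE", "yes", lines[2])   # cyanosis
  lines[3] <- sub("FALSE", "0", lines[3])
  back <- read_cohort(path)
  expect_identical(back$cyanosis, c(TRUE, FALSE))

  header <- strsplit(lines[1], ",")[[1]]
  row <- strsplit(lines[2], ",")[[1]]
  row[which(header == "grunting")] <- "maybe"
  writeLines(c(lines[1], paste(row, collapse = ",")), path)
  expect_error(read_cohort(path), "unparseable boolean.*grunting.*row")

  row[which(header == "grunting")] <- ""
  row[which(header == "spo2_percent")] <- "101"
  writeLines(c(lines[1], paste(row, collapse = ",")), path)
  expect_error(read_cohort(path), "spo2_percent")
})

test_that("read_cohort handles empty files, missing columns and schemas", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(new_cohort(0), path)
  expect_equal(nrow(read_cohort(path)), 0)

  df <- readr::read_csv(path, show_col_types = FALSE)
  readr::write_csv(df[setdiff(names(df), "muac_mm")], path)
  expect_error(read_cohort(path), "missing required column.*muac_mm")

  # a schema can map canonical names onto arbitrary file headers
  path2 <- withr::local_tempfile(fileext = ".csv")
  co <- new_cohort(2, muac_mm = c(120, 180))
  renamed <- dplyr::rename(co, muac = muac_mm, temp = temperature_c)
  readr::write_csv(renamed, path2)
  back <- read_cohort(path2, schema = list(muac_mm = "muac",
                                           temperature_c = "temp"))
  expect_equal(back$muac_mm, c(120, 180))
})

test_that("assignments round-trip preserves categories and audit lists", {
  co <- generate_cohort(synthetic_cohort_config(n = 25, seed = 3))
  asg <- triage_cohort(co, placeholder_spec(), placeholder_recal_spec())
  path <- withr::local_tempfile(fileext = ".csv")
  write_assignments(asg, path)
  back <- read_assignments(path)
  for (sys in c("etat", "st_model_only", "st_with_triggers",
                "st_recalibrated_with_triggers")) {
    expect_identical(as.character(back[[sys]]), as.character(asg[[sys]]))
  }
  expect_identical(back$emergency_triggers, asg$emergency_triggers)
  expect_identical(back$etat_priority_signs, asg$etat_priority_signs)

  write_assignments(asg[0, ], path)
  expect_equal(nrow(readr::read_csv(path, show_col_types = FALSE)), 0)
})
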