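test_that("Wilson interval matches the closed form and its boundaries", {
  w <- wilson_interval(191, 395)
  expect_equal(w$lo, 0.4346589, tolerance = 1e-6)
  expect_equal(w$hi, 0.5327467, tolerance = 1e-6)
  expect_equal(wilson_interval(0, 10)$lo, 0)
  expect_equal(wilson_interval(10, 10)$hi, 1)
  # interval contains the point estimate and sits inside [0, 1]
  grid <- expand.grid(x = c(0, 1, 5, 12, 50), n = c(12, 50, 200))
  grid <- grid[grid$x <= grid$n, ]
  w <- wilson_interval(grid$x, grid$n)
  expect_true(all(w$lo <= w$estimate & w$estimate <= w$hi))
  expect_true(all(w$lo >= 0 & w$hi <= 1))
})

test_that("Wilson interval agrees with prop.test and shrinks with n", {
  for (i in seq_len(20)) {
    n <- sample(5:500, 1)
    x <- sample(0:n, 1)
    w <- wilson_interval(x, n)
    pt <- suppressWarnings(prop.test(x, n, correct = FALSE))$conf.int
    expect_equal(c(w$lo, w$hi), as.numeric(pt), tolerance = 1e-9)
  }
  widths <- sapply(c(1, 2, 4, 8, 16), function(k) {
    w <- wilson_interval(30 * k, 100 * k)
    w$hi - w$lo
  })
  expect_true(all(diff(widths) < 0))
})

test_that("dichotomization maps emergency to high acuity", {
  expect_equal(as.character(dichotomize(c("emergency", "priority", "non-urgent"))),
               c("high", "low", "low"))
})

test_that("confusion counts partition the outcome-known patients", {
  df <- tibble::tibble(cat = rep("emergency", 5), y = rep(TRUE, 5),
                       known = rep(TRUE, 5))
  expect_equal(confusion_2x2(df, cat, y, known),
               tibble::tibble(tp = 5L, fp = 0L, fn = 0L, tn = 0L),
               ignore_attr = TRUE)
  set.seed(12)
  df <- tibble::tibble(
    cat = sample(triage_levels(), 300, replace = TRUE),
    y = runif(300) < 0.2,
    known = runif(300) < 0.95)
  cc <- confusion_2x2(df, cat, y, known)
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, sum(df$known))
  # unknown-outcome rows appear in no cell
  expect_equal(cc$tp + cc$fn, sum(df$y & df$known))
})

test_that("diagnostic summary reproduces the worked 2x2 example", {
  ds <- diagnostic_summary(191, 322, 204, 4888)
  g <- glance(ds)
  expect_equal(round(g$sensitivity, 3), 0.484)
  expect_equal(round(g$specificity, 3), 0.938)
  expect_equal(round(g$ppv, 3), 0.372)
  expect_equal(round(g$npv, 3), 0.960)
  td <- tidy(ds)
  expect_equal(pct1(td$conf.low[td$statistic == "sensitivity"]), 43.5)
  expect_equal(pct1(td$conf.high[td$statistic == "sensitivity"]), 53.3)

  perfect <- glance(diagnostic_summary(7, 0, 0, 13))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  # zero denominator: only the affected statistic is undefined
  ds0 <- diagnostic_summary(0, 0, 3, 10)
  t0 <- tidy(ds0)
  expect_true(is.na(t0$estimate[t0$statistic == "ppv"]))
  expect_equal(t0$estimate[t0$statistic == "npv"], 10 / 13)
})

test_that("transition tables count flows exactly", {
  df <- tibble::tibble(a = rep(triage_levels(), times = c(2, 3, 4)))
  df$b <- df$a
  tt <- transition_table(df, a, b)
  expect_equal(sum(diag(tt$counts)), 9)
  expect_equal(glance(tt)$agreement, 1)

  df2 <- tibble::tibble(a = "emergency", b = "non-urgent")
  tt2 <- transition_table(df2, a, b)
  expect_equal(tt2$counts["emergency", "non-urgent"], 1)
  expect_equal(sum(tt2$counts), 1)
  expect_equal(tidy(tt2)$value, 1)

  set.seed(4)
  df3 <- tibble::tibble(a = sample(triage_levels(), 200, replace = TRUE),
                        b = sample(triage_levels(), 200, replace = TRUE))
  tt3 <- transition_table(df3, a, b)
  expect_equal(sum(tt3$counts), 200)
  # brute-force recount oracle
  for (i in triage_levels()) for (j in triage_levels()) {
    expect_equal(unname(tt3$counts[i, j]), sum(df3$a == i & df3$b == j))
  }
  expect_equal(glance(tt3)$agreement, mean(df3$a == df3$b))
  expect_equal(agreement_proportion(df3, a, b), mean(df3$a == df3$b))
})

test_that("agreement proportion handles edge cases", {
  df <- tibble::tibble(a = c("priority", "priority"),
                       b = c("emergency", "non-urgent"))
  expect_equal(agreement_proportion(df, a, b), 0)
  expect_error(agreement_proportion(df[0, ], a, b), "empty")
})

test_that("category-outcome table reproduces the published per-category rates", {
  # rebuild per-patient rows from the reference ETAT aggregates
  rc <- dplyr::filter(reference_counts(), system == "etat")
  df <- purrr::pmap_dfr(rc, function(category, participants, admitted, died, ...) {
    tibble::tibble(
      cat = rep(as.character(category), participants),
      adm = rep(c(TRUE, FALSE), c(admitted, participants - admitted)),
      dth = rep(c(TRUE, FALSE), c(died, participants - died)))
  })
  df$known <- TRUE
  tab <- category_outcome_table(df, cat, adm, dth, known)
  em <- tab[tab$category == "emergency", ]
  expect_equal(pct1(em$admitted_pct / 100), 37.2)
  expect_equal(pct1(tab$admitted_pct[tab$category == "priority"] / 100), 8.4)
  expect_equal(pct1(tab$admitted_pct[tab$category == "non-urgent"] / 100), 1.2)
  expect_equal(sum(tab$n), 5605)
  expect_equal(sum(tab$admitted_n), 395)
  expect_equal(sum(tab$died_n), 49)

  # unknown outcomes leave every denominator
  df2 <- dplyr::bind_rows(df, tibble::tibble(cat = "emergency", adm = FALSE,
                                             dth = FALSE, known = FALSE))
  expect_equal(sum(category_outcome_table(df2, cat, adm, dth, known)$n), 5605)
})

test_that("aggregated and per-patient diagnostic routes agree exactly", {
  co <- generate_cohort(synthetic_cohort_config(n = 4000, seed = 13))
  asg <- triage_cohort(co, placeholder_spec())
  dat <- dplyr::inner_join(asg, co[, c("patient_id", "admitted", "died",
                                       "outcome_known")], by = "patient_id")
  per_patient <- diagnostic_summary(confusion_2x2(dat, etat, admitted,
                                                  outcome_known))
  tab <- category_outcome_table(dat, etat, admitted, died, outcome_known)
  tp <- tab$admitted_n[tab$category == "emergency"]
  fp <- tab$n[tab$category == "emergency"] - tp
  fn <- sum(tab$admitted_n) - tp
  tn <- sum(tab$n) - sum(tab$admitted_n) - fp
  from_table <- diagnostic_summary(tp, fp, fn, tn)
  expect_identical(glance(per_patient), glance(from_table))
})

test_that("reference confusion tables derive from the aggregate counts", {
  adm <- reference_confusion(outcome = "admission")
  etat <- adm[adm$system == "etat", ]
  expect_equal(unlist(etat[, c("tp", "fp", "fn", "tn")]),
               c(tp = 191, fp = 322, fn = 204, tn = 4888))
  expect_true(all(adm$tp + adm$fp + adm$fn + adm$tn == 5605))
  mort <- reference_confusion(outcome = "mortality")
  expect_true(all(mort$tp + mort$fn == 49))
  # sanity of the fixture table itself
  rc <- reference_counts()
  expect_true(all(tapply(rc$participants, rc$system, sum) == 5605))
  expect_true(all(tapply(rc$admitted, rc$system, sum) == 395))
  expect_true(all(tapply(rc$died, rc$system, sum) == 49))
})

test_that("sankey JSON and autoplot render from a transition table", {
  df <- tibble::tibble(a = sample(triage_levels(), 50, replace = TRUE),
                       b = sample(triage_levels(), 50, replace = TRUE))
  tt <- transition_table(df, a, b)
  path <- withr::local_tempfile(fileext = ".json")
  write_sankey_json(tt, path)
  flows <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(sum(flows$value), 50)
  expect_s3_class(autoplot(tt), "ggplot")
  expect_s3_class(autoplot(diagnostic_summary(5, 2, 3, 40)), "ggplot")
})
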