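#' Published aggregate counts from a two-hospital Kenyan evaluation cohort
#'
#' Per-category participant, admission and mortality counts from a
#' published prospective comparison of ETAT and Smart Triage in 5618
#' children presenting to the emergency departments of two Kenyan public
#' hospitals. 13 children had a missing hospital outcome, leaving 5605
#' evaluable, among whom there were 395 admissions and 49 deaths
#' (day-of-enrolment, in-hospital and follow-up deaths combined). The
#' per-patient dataset is not public; these aggregates are sufficient to
#' reconstruct every dichotomized diagnostic statistic.
#'
#' @return Tibble with columns `system` (one of `"etat"`,
#'   `"st_with_triggers"`, `"st_recalibrated_with_triggers"`),
#'   `category`, `participants`, `admitted`, `died_enrolment`,
#'   `died_in_hospital`, `died_followup`, `died`.
#' @export
#' @examples
#' reference_counts()
reference_counts <- function() {
  tibble::tibble(
    system = rep(c("etat", "st_with_triggers", "st_recalibrated_with_triggers"),
                 each = 3),
    category = triage_category(rep(c("emergency", "priority", "non-urgent"), 3)),
    participants     = c(513, 2003, 3089,  1163, 2345, 2097,  1161, 1827, 2617),
    admitted         = c(191,  168,   36,   296,   83,   16,   296,   74,   25),
    died_enrolment   = c(  4,    2,    0,     5,    1,    0,     5,    1,    0),
    died_in_hospital = c( 13,    8,    0,    18,    3,    0,    18,    3,    0),
    died_followup    = c(  8,   12,    2,    16,    6,    0,    16,    6,    0)
  ) |>
    dplyr::mutate(died = .data$died_enrolment + .data$died_in_hospital +
                    .data$died_followup)
}

#' Headline sizes of the reference evaluation cohort
#'
#' @return One-row tibble: `enrolled`, `missing_outcome`, `evaluable`,
#'   `admissions`, `deaths`.
#' @export
reference_cohort_size <- function() {
  tibble::tibble(enrolled = 5618L, missing_outcome = 13L, evaluable = 5605L,
                 admissions = 395L, deaths = 49L)
}

#' 2x2 confusion counts reconstructed from the reference aggregates
#'
#' Dichotomizes the per-category reference counts into high acuity
#' (emergency) versus low acuity (priority + non-urgent) against an
#' outcome: tp is the outcome count in the emergency category, fp the
#' remaining emergency participants, fn the outcome count outside
#' emergency, tn everyone else among the evaluable patients.
#'
#' @param counts Reference counts, as from [reference_counts()]; pass a
#'   filtered/modified tibble to reconstruct other scenarios.
#' @param outcome `"admission"` or `"mortality"`.
#' @return Tibble with one row per system: `system`, `tp`, `fp`, `fn`, `tn`.
#' @export
#' @examples
#' reference_confusion(outcome = "admission")
reference_confusion <- function(counts = reference_counts(),
                                outcome = c("admission", "mortality")) {
  outcome <- match.arg(outcome)
  col <- if (outcome == "admission") "admitted" else "died"
  counts |>
    dplyr::group_by(.data$system) |>
    dplyr::summarise(
      tp = sum(.data[[col]][.data$category == "emergency"]),
      fp = sum(.data$participants[.data$category == "emergency"]) - .data$tp,
      fn = sum(.data[[col]]) - .data$tp,
      tn = sum(.data$participants) - sum(.data[[col]]) - .data$fp,
      .groups = "drop")
}

#' Diagnostic statistics recomputed from the reference aggregates
#'
#' Rebuilds, for every triage system and both outcomes, the 2x2 table
#' from [reference_counts()] and summarises it with
#' [diagnostic_summary()]. This reproduces the published
#' sensitivity/specificity/PPV/NPV tables from counts alone.
#'
#' @param counts Reference counts tibble.
#' @return Tidy tibble: `system`, `outcome`, `statistic`, `estimate`,
#'   `conf.low`, `conf.high`, `numerator`, `denominator`.
#' @export
#' @examples
#' reference_diagnostics() |> head()
reference_diagnostics <- function(counts = reference_counts()) {
  purrr::map_dfr(c("admission", "mortality"), function(oc) {
    reference_confusion(counts, oc) |>
      dplyr::group_by(.data$system) |>
      dplyr::group_modify(~ tidy(diagnostic_summary(.x$tp, .x$fp, .x$fn, .x$tn))) |>
      dplyr::ungroup() |>
      dplyr::mutate(outcome = oc, .after = "system")
  })
}
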