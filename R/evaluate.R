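#' Wilson score confidence interval for a binomial proportion
#'
#' Continuity-uncorrected Wilson interval. Always lies inside [0, 1] and
#' contains the point estimate x/n; at x = 0 the lower bound is 0 and at
#' x = n the upper bound is 1.
#'
#' @param x Number of successes (vectorized).
#' @param n Number of trials.
#' @param conf Confidence level, default 0.95 (z = 1.959964).
#' @return Tibble with columns `estimate`, `lo`, `hi`.
#' @export
#' @examples
#' wilson_interval(191, 395) # 0.4347 - 0.5327
wilson_interval <- function(x, n, conf = 0.95) {
  stopifnot(all(n > 0), all(x >= 0), all(x <= n), conf > 0, conf < 1)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  tibble::tibble(estimate = p,
                 lo = pmax((centre - half) / denom, 0),
                 hi = pmin((centre + half) / denom, 1))
}

#' Collapse triage categories to a two-level acuity
#'
#' Emergency is high acuity; priority and non-urgent are low acuity.
#'
#' @param cat Triage categories (character or factor).
#' @return Factor with levels `low`, `high`.
#' @export
#' @examples
#' dichotomize(c("emergency", "priority", "non-urgent"))
dichotomize <- function(cat) {
  cat <- triage_category(cat)
  factor(ifelse(cat == "emergency", "high", "low"), levels = c("low", "high"))
}

#' 2x2 confusion counts of high/low acuity against an outcome
#'
#' Restricted to outcome-known patients. High acuity (emergency) with
#' the outcome is a true positive; high acuity without it a false
#' positive; low acuity with the outcome a false negative; low acuity
#' without it a true negative.
#'
#' @param data Data frame of per-patient rows (e.g. from
#'   [triage_cohort()] joined to outcomes).
#' @param category Column of triage categories (tidy-eval).
#' @param outcome Logical outcome column (tidy-eval).
#' @param outcome_known Optional logical column; rows where it is FALSE
#'   are dropped from every cell.
#' @return One-row tibble with columns `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_2x2 <- function(data, category, outcome, outcome_known = NULL) {
  cat <- dichotomize(dplyr::pull(data, {{ category }}))
  y <- dplyr::pull(data, {{ outcome }})
  stopifnot(length(cat) == length(y))
  known <- rlang::enquo(outcome_known)
  keep <- if (rlang::quo_is_null(known)) rep(TRUE, length(y)) else
    dplyr::pull(data, {{ outcome_known }})
  cat <- cat[keep]; y <- y[keep]
  tibble::tibble(
    tp = sum(cat == "high" & y),
    fp = sum(cat == "high" & !y),
    fn = sum(cat == "low" & y),
    tn = sum(cat == "low" & !y)
  )
}

#' Diagnostic test statistics with Wilson confidence intervals
#'
#' Sensitivity, specificity, PPV and NPV from 2x2 counts, each with a
#' Wilson score 95\% CI. A statistic whose denominator is zero is
#' reported as NA (undefined); the others are still computed.
#'
#' @param tp,fp,fn,tn Nonnegative integer counts. Alternatively pass a
#'   one-row data frame with these columns as `tp` and leave the rest
#'   missing.
#' @param conf Confidence level.
#' @return Object of class `diagnostic_summary`; see [tidy()] and
#'   [glance()] methods.
#' @export
#' @examples
#' diagnostic_summary(191, 322, 204, 4888)
diagnostic_summary <- function(tp, fp = NULL, fn = NULL, tn = NULL, conf = 0.95) {
  if (is.data.frame(tp)) {
    counts <- tp
    stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(counts)),
              nrow(counts) == 1)
    tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  }
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  one <- function(x, n) {
    if (n == 0) {
      return(tibble::tibble(estimate = NA_real_, lo = NA_real_, hi = NA_real_,
                            numerator = x, denominator = n))
    }
    dplyr::mutate(wilson_interval(x, n, conf), numerator = x, denominator = n)
  }
  stats <- dplyr::bind_rows(
    sensitivity = one(tp, tp + fn),
    specificity = one(tn, tn + fp),
    ppv = one(tp, tp + fp),
    npv = one(tn, tn + fn),
    .id = "statistic")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, conf = conf,
                 stats = stats),
            class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, digits = 1, ...) {
  cat(sprintf("<diagnostic_summary> tp=%d fp=%d fn=%d tn=%d (n=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  for (i in seq_len(nrow(x$stats))) {
    s <- x$stats[i, ]
    if (is.na(s$estimate)) {
      cat(sprintf("  %-11s undefined (denominator 0)\n", s$statistic))
    } else {
      cat(sprintf("  %-11s %s%% (%s%% - %s%%)  [%d/%d]\n", s$statistic,
                  format_pct(s$estimate, digits), format_pct(s$lo, digits),
                  format_pct(s$hi, digits), s$numerator, s$denominator))
    }
  }
  invisible(x)
}

#' Tidy a diagnostic summary
#'
#' @param x A `diagnostic_summary`.
#' @param ... Unused.
#' @return Tibble with one row per statistic: `statistic`, `estimate`,
#'   `conf.low`, `conf.high`, `numerator`, `denominator`.
#' @method tidy diagnostic_summary
#' @export
tidy.diagnostic_summary <- function(x, ...) {
  dplyr::transmute(x$stats,
                   statistic = .data$statistic, estimate = .data$estimate,
                   conf.low = .data$lo, conf.high = .data$hi,
                   numerator = .data$numerator, denominator = .data$denominator)
}

#' One-row overview of a diagnostic summary
#'
#' @param x A `diagnostic_summary`.
#' @param ... Unused.
#' @return One-row tibble with the counts and the four point estimates.
#' @method glance diagnostic_summary
#' @export
glance.diagnostic_summary <- function(x, ...) {
  est <- stats::setNames(x$stats$estimate, x$stats$statistic)
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn,
                 n = x$tp + x$fp + x$fn + x$tn,
                 sensitivity = est[["sensitivity"]],
                 specificity = est[["specificity"]],
                 ppv = est[["ppv"]], npv = est[["npv"]])
}

#' Category-by-category reclassification (transition) table
#'
#' Cross-tabulates each patient's category under two systems; the
#' off-diagonal cells are the reclassification flows a Sankey diagram
#' draws.
#'
#' @param data Data frame with one row per patient.
#' @param from,to Category columns (tidy-eval).
#' @return Object of class `transition_table` holding the 3x3 count
#'   matrix, the flow list, and the total; see [tidy()], [glance()] and
#'   [ggplot2::autoplot()] methods.
#' @export
#' @examples
#' m <- example_model_spec("original")
#' asg <- triage_cohort(new_cohort(3, spo2_percent = c(88, 98, 98)), m)
#' transition_table(asg, etat, st_with_triggers)
transition_table <- function(data, from, to) {
  a <- triage_category(dplyr::pull(data, {{ from }}))
  b <- triage_category(dplyr::pull(data, {{ to }}))
  if (length(a) != length(b)) stop("category vectors differ in length", call. = FALSE)
  counts <- table(from = a, to = b)
  flows <- tibble::as_tibble(counts)
  names(flows) <- c("source", "target", "value")
  flows <- dplyr::filter(flows, .data$value > 0)
  structure(list(
    counts = unclass(counts),
    flows = flows,
    n = length(a),
    from_label = rlang::as_name(rlang::enquo(from)),
    to_label = rlang::as_name(rlang::enquo(to))
  ), class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("<transition_table> %s -> %s (n = %d, agreement %.1f%%)\n",
              x$from_label, x$to_label, x$n,
              100 * sum(diag(x$counts)) / max(x$n, 1)))
  print(x$counts)
  invisible(x)
}

#' Tidy a transition table into its Sankey flow list
#'
#' @param x A `transition_table`.
#' @param ... Unused.
#' @return Tibble with `source`, `target`, `value` (only nonzero flows).
#' @method tidy transition_table
#' @export
tidy.transition_table <- function(x, ...) x$flows

#' One-row overview of a transition table
#'
#' @param x A `transition_table`.
#' @param ... Unused.
#' @return One-row tibble with `n`, `agreement` (diagonal proportion).
#' @method glance transition_table
#' @export
glance.transition_table <- function(x, ...) {
  tibble::tibble(n = x$n, agreement = sum(diag(x$counts)) / x$n)
}

#' Write a transition table's flows as Sankey JSON
#'
#' Emits `[{"source": ..., "target": ..., "value": ...}, ...]`,
#' consumable by standard Sankey plotting tools.
#'
#' @param x A `transition_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sankey_json <- function(x, path) {
  stopifnot(inherits(x, "transition_table"))
  jsonlite::write_json(x$flows, path, dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

#' Proportion of patients given the same category by two systems
#'
#' @param data Data frame with one row per patient.
#' @param a,b Category columns (tidy-eval).
#' @return Numeric scalar in [0, 1].
#' @export
agreement_proportion <- function(data, a, b) {
  ca <- triage_category(dplyr::pull(data, {{ a }}))
  cb <- triage_category(dplyr::pull(data, {{ b }}))
  if (length(ca) != length(cb)) stop("category vectors differ in length", call. = FALSE)
  if (length(ca) == 0) stop("empty input", call. = FALSE)
  mean(ca == cb)
}

#' Per-category participant and outcome counts
#'
#' For each triage category: number of outcome-known participants (and
#' its share of all outcome-known patients), admissions (with the
#' within-category percentage), and deaths (with percentage). Patients
#' with unknown outcome are excluded from every denominator.
#'
#' @param data Data frame with one row per patient.
#' @param category Category column (tidy-eval).
#' @param admitted,died,outcome_known Logical columns (tidy-eval).
#' @return Tibble with one row per category (all three categories
#'   always present) and columns `category`, `n`, `pct`, `admitted_n`,
#'   `admitted_pct`, `died_n`, `died_pct`.
#' @export
category_outcome_table <- function(data, category, admitted, died, outcome_known) {
  cat <- triage_category(dplyr::pull(data, {{ category }}))
  adm <- dplyr::pull(data, {{ admitted }})
  dth <- dplyr::pull(data, {{ died }})
  known <- dplyr::pull(data, {{ outcome_known }})
  stopifnot(length(adm) == length(cat), length(dth) == length(cat),
            length(known) == length(cat))
  cat <- cat[known]; adm <- adm[known]; dth <- dth[known]
  total <- length(cat)
  tibble::tibble(category = triage_category(rev(triage_levels()))) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      n = sum(cat == .data$category),
      pct = if (total > 0) 100 * .data$n / total else NA_real_,
      admitted_n = sum(adm[cat == .data$category]),
      admitted_pct = if (.data$n > 0) 100 * .data$admitted_n / .data$n else NA_real_,
      died_n = sum(dth[cat == .data$category]),
      died_pct = if (.data$n > 0) 100 * .data$died_n / .data$n else NA_real_
    ) |>
    dplyr::ungroup()
}

# round-half-away-from-zero percentage formatting, matching clinical tables
format_pct <- function(p, digits = 1) {
  x <- 100 * p
  scale <- 10^digits
  formatC(sign(x) * floor(abs(x) * scale + 0.5) / scale,
          format = "f", digits = digits)
}

#' Round a proportion to a percentage, half away from zero
#'
#' Clinical tables conventionally round 0.05 up; base R's `round()`
#' rounds half to even. `pct1(0.4835)` is 48.4, `pct1(0.255)` is 25.5.
#'
#' @param p Proportion in [0, 1] (vectorized).
#' @param digits Decimal places of the percentage.
#' @return Numeric percentage.
#' @export
pct1 <- function(p, digits = 1) {
  scale <- 10^digits
  x <- 100 * p
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
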