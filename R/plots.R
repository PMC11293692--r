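#' Sankey-style plot of a transition table
#'
#' Draws the two category columns as stacked node bars and each nonzero
#' flow as a ribbon whose height is the patient count. A static
#' ggplot2 rendering of the flow list; the flow list itself is available
#' via [tidy()] or [write_sankey_json()] for fancier Sankey tooling.
#'
#' @param object A `transition_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot transition_table
#' @export
autoplot.transition_table <- function(object, ...) {
  lv <- rev(triage_levels()) # emergency on top
  counts <- object$counts[lv, lv]
  left_top <- cumsum(c(0, rowSums(counts)))[1:3]
  right_top <- cumsum(c(0, colSums(counts)))[1:3]

  nodes <- tibble::tibble(
    side = rep(c("from", "to"), each = 3),
    category = factor(rep(lv, 2), levels = lv),
    xmin = rep(c(0, 0.92), each = 3), xmax = rep(c(0.08, 1), each = 3),
    ymax = -c(left_top, right_top),
    ymin = -c(left_top + rowSums(counts), right_top + colSums(counts))
  )

  ribbons <- list()
  loff <- left_top
  roff <- right_top
  for (i in 1:3) for (j in 1:3) {
    v <- counts[i, j]
    if (v == 0) next
    ribbons[[length(ribbons) + 1]] <- tibble::tibble(
      id = sprintf("%s->%s", lv[i], lv[j]),
      category = factor(lv[i], levels = lv),
      x = c(0.08, 0.92, 0.92, 0.08),
      y = -c(loff[i], roff[j], roff[j] + v, loff[i] + v))
    loff[i] <- loff[i] + v
    roff[j] <- roff[j] + v
  }
  ribbons <- dplyr::bind_rows(ribbons)

  ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = ribbons,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$id,
                   fill = .data$category), alpha = 0.45) +
    ggplot2::geom_rect(
      data = nodes,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax,
                   fill = .data$category)) +
    ggplot2::scale_fill_manual(values = c(
      "emergency" = "#c0392b", "priority" = "#e67e22",
      "non-urgent" = "#27ae60"), name = NULL) +
    ggplot2::scale_x_continuous(
      breaks = c(0.04, 0.96), labels = c(object$from_label, object$to_label)) +
    ggplot2::labs(y = NULL, x = NULL,
                  title = sprintf("Reclassification, n = %d", object$n)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Plot diagnostic statistics with their confidence intervals
#'
#' @param object A `diagnostic_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diagnostic_summary
#' @export
autoplot.diagnostic_summary <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::scale_y_continuous(limits = c(0, 1),
                                labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of category counts per triage system
#'
#' @param assignments Tibble from [triage_cohort()].
#' @param systems Assignment columns to show.
#' @return A ggplot object.
#' @export
plot_category_distribution <- function(
    assignments,
    systems = c("etat", "st_model_only", "st_with_triggers",
                "st_recalibrated_with_triggers")) {
  long <- assignments |>
    dplyr::select(dplyr::all_of(c("patient_id", systems))) |>
    tidyr::pivot_longer(-"patient_id", names_to = "system",
                        values_to = "category",
                        values_transform = as.character) |>
    dplyr::mutate(system = factor(.data$system, levels = systems),
                  category = triage_category(.data$category))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$system, fill = .data$category)) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::scale_fill_manual(values = c(
      "emergency" = "#c0392b", "priority" = "#e67e22",
      "non-urgent" = "#27ae60"), name = NULL) +
    ggplot2::labs(x = NULL, y = "children") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}
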