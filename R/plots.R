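# ggplot2 displays for the three result types.

#' Plot a monthly regional abundance-index table
#'
#' Line plot of the index by month, one line per region -- the annual
#' movement signal at a glance.
#'
#' @param object An [ai_by_region()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ai_region <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$month, y = .data$ai,
                               colour = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = 1:12, labels = month.abb) +
    ggplot2::labs(x = NULL, y = "Abundance index (%)", colour = "Region") +
    ggplot2::theme_minimal()
}

#' Plot raw monthly specimen counts
#'
#' @param counts A [raw_monthly_counts()] tibble.
#' @return A ggplot object.
#' @export
plot_raw_counts <- function(counts) {
  ggplot2::ggplot(counts, ggplot2::aes(x = factor(.data$month,
                                                  labels = month.abb),
                                       y = .data$count)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "Specimen records") +
    ggplot2::theme_minimal()
}

#' Plot a movement-test battery
#'
#' Observed-versus-expected focal proportions per question with the test
#' p-value annotated.
#'
#' @param object A [run_movement_battery()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.movement_battery <- function(object, ...) {
  td <- tidy(object) |>
    filter(.data$valid) |>
    tidyr::pivot_longer(c("focal_a", "focal_b"), names_to = "stratum",
                        values_to = "focal") |>
    mutate(
      other = if_else(.data$stratum == "focal_a", .data$other_a, .data$other_b),
      stratum = if_else(.data$stratum == "focal_a", "predicted high",
                        "predicted low"),
      prop = .data$focal / (.data$focal + .data$other)
    )
  ggplot2::ggplot(td, ggplot2::aes(x = .data$stratum, y = .data$prop)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::facet_wrap(~.data$test, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Focal share of specimens") +
    ggplot2::theme_minimal()
}

#' Plot monthly greenness comparisons
#'
#' Monthly mean EVI at specimen sites versus the null sample, with 95%
#' confidence intervals, faceted by comparison type (random locations /
#' weighted reference subsample).
#'
#' @param object A [run_evi_battery()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evi_battery <- function(object, ...) {
  td <- as_tibble(object) |>
    filter(.data$computable) |>
    tidyr::pivot_longer(
      cols = c("specimen_mean", "null_mean"),
      names_to = "set", values_to = "mean_evi"
    ) |>
    mutate(
      lo = if_else(.data$set == "specimen_mean", .data$specimen_lo, .data$null_lo),
      hi = if_else(.data$set == "specimen_mean", .data$specimen_hi, .data$null_hi),
      set = if_else(.data$set == "specimen_mean", "specimen sites", "null sample")
    )
  ggplot2::ggplot(td, ggplot2::aes(x = .data$month, y = .data$mean_evi,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                             size = 0.2) +
    ggplot2::facet_wrap(~.data$comparison) +
    ggplot2::scale_x_continuous(breaks = 1:12, labels = month.abb) +
    ggplot2::labs(x = NULL, y = "Mean EVI", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
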