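#' Plot the cohort sliding-window rejection curve
#'
#' @param records Trial records.
#' @param window Window length in trials.
#' @return A ggplot: mean rejection percentage by trial, block boundaries
#'   marked.
#' @export
plot_sliding_rejection <- function(records, window = 5L) {
  curve <- sliding_rejection(records, window = window)
  boundaries <- records |>
    dplyr::summarise(start = min(.data$trial), .by = "block") |>
    dplyr::filter(.data$start > 1)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$trial,
                                      y = .data$rejection_rate)) +
    ggplot2::geom_vline(data = boundaries,
                        ggplot2::aes(xintercept = .data$start - 0.5),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Trial", y = "Rejection rate (%)",
                  title = paste0("Sliding-window rejection (window = ",
                                 window, " trials)")) +
    ggplot2::theme_minimal()
}

#' Plot mean rejection rates by block
#'
#' @param records Trial records.
#' @return A ggplot of block means with SEM error bars.
#' @export
plot_block_rates <- function(records) {
  rates <- rejection_rates(records, by = "block")
  summ <- rates |>
    dplyr::summarise(
      mean_rate = mean(.data$rejection_rate),
      sem = sd(.data$rejection_rate) / sqrt(dplyr::n()),
      .by = "block"
    )
  summ$block <- factor(summ$block, levels = unique(records$block))
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$block, y = .data$mean_rate)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_rate - .data$sem,
                                        ymax = .data$mean_rate + .data$sem),
                           width = 0.15) +
    ggplot2::labs(x = NULL, y = "Mean rejection rate (%)") +
    ggplot2::theme_minimal()
}

#' Plot rejection rate by offer size
#'
#' @param records Trial records.
#' @return A ggplot of mean rejection percentage against offer size.
#' @export
plot_rejection_by_offer <- function(records) {
  summ <- records |>
    dplyr::mutate(rejected = !parse_choices(.data$choice)) |>
    dplyr::summarise(rate = 100 * mean(.data$rejected),
                     n = dplyr::n(), .by = "offer")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$offer, y = .data$rate)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "Offer (tokens)", y = "Rejection rate (%)",
                  size = "Trials") +
    ggplot2::theme_minimal()
}

#' @describeIn compare_models Bar chart of summed BIC and AIC per model.
#' @param object A `ug_comparison`.
#' @param ... Unused.
#' @method autoplot ug_comparison
#' @export
autoplot.ug_comparison <- function(object, ...) {
  long <- object$table |>
    tidyr::pivot_longer(c("sum_bic", "sum_aic"),
                        names_to = "criterion", values_to = "score") |>
    dplyr::mutate(criterion = toupper(sub("sum_", "", .data$criterion)))
  ggplot2::ggplot(long, ggplot2::aes(x = stats::reorder(.data$model_id,
                                                        .data$score),
                                     y = .data$score,
                                     fill = .data$criterion)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Summed score (lower is better)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn model_recovery Confusion-matrix tile plot of winner
#'   fractions.
#' @param object A `ug_recovery`.
#' @param ... Unused.
#' @method autoplot ug_recovery
#' @export
autoplot.ug_recovery <- function(object, ...) {
  ggplot2::ggplot(object$confusion,
                  ggplot2::aes(x = .data$winner, y = .data$generating_model,
                               fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$fraction)), colour = "white") +
    ggplot2::scale_fill_gradient(low = "grey80", high = "steelblue4",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "Summed-BIC winner", y = "Generating model",
                  fill = "Fraction") +
    ggplot2::theme_minimal()
}
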