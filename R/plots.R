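#' Plot predictions in score space
#'
#' Scatter of the infiltration score against the response score, colored by
#' predicted class and shaped by nonresponder mechanism.
#'
#' @param object A predictions tibble from [classify_training_cohort()] or
#'   [classify_validation_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tmepre_predictions
#' @export
autoplot.tmepre_predictions <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$tme1_score, y = .data$tme2_score,
      colour = .data$predicted, shape = .data$mechanism
    )
  ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = "TME1 infiltration score", y = "TME2 response score",
      colour = "predicted", shape = "mechanism"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-gene selection frequencies
#'
#' Ranked selection frequencies from stability selection with the frequency
#' threshold drawn as a horizontal line; selected genes highlighted.
#'
#' @param object A `selection_report` from [stability_select()].
#' @param top Number of top-frequency genes to show (default 100).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot selection_report
#' @export
autoplot.selection_report <- function(object, top = 100, ...) {
  df <- tidy(object) |>
    dplyr::slice_head(n = top) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$frequency, colour = .data$selected)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$params$min_frequency, linetype = "dashed") +
    ggplot2::labs(
      x = "gene rank", y = "selection frequency",
      colour = sprintf("frequency >= %.2f", object$params$min_frequency)
    ) +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves for a survival read-out
#'
#' @param object A `tmepre_survival` from [survival_readout()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tmepre_survival
#' @export
autoplot.tmepre_survival <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble(time = 0, n_risk = max(.x$n_risk), n_event = 0, survival = 1), .x
    )) |>
    dplyr::ungroup()
  gl <- glance(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "time (days)", y = "survival probability",
      title = sprintf(
        "HR = %.2f, log-rank p = %.3g",
        gl$hazard_ratio, gl$p_two_sided
      )
    ) +
    ggplot2::theme_minimal()
}
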