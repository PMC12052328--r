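#' Plot a discriminant-validity comparison
#'
#' Jittered total scores by group with group means, the visual counterpart
#' of the discriminant comparison table.
#'
#' @param object A `nova_discriminant` (plot built from its stored table) -
#'   pass the scores through [plot_score_distribution()] for raw data.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nova_discriminant <- function(object, ...) {
  tab <- object$table
  df <- tibble::tibble(
    group = factor(rep(object$groups, times = nrow(tab)), levels = object$groups),
    component = rep(tab$component, each = 2),
    mean = as.vector(rbind(tab$mean_ref, tab$mean_cmp)),
    sd = as.vector(rbind(tab$sd_ref, tab$sd_cmp))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$mean, fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::labs(
      x = NULL, y = "Score (mean ± SD)",
      title = "Knowledge score by group"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a convergent-validity fit
#'
#' Scatter of usual UPF intake against the total knowledge score, with the
#' adjusted regression line for the total-score model (evaluated at the
#' covariate means/reference levels).
#'
#' @param object A `nova_convergent`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nova_convergent <- function(object, ...) {
  df <- object$data
  tot <- object$table[object$table$component == "total", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$total, y = .data$usual_estimate)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(
      intercept = object$usual_mean - tot$estimate * mean(df$total),
      slope = tot$estimate, color = "firebrick", linewidth = 1
    ) +
    ggplot2::labs(
      x = "Knowledge score (0-8)",
      y = "Usual UPF intake (% of energy)",
      title = sprintf(
        "Adjusted slope %.2f pp per score point (95%% CI %.2f to %.2f)",
        tot$estimate, tot$conf_low, tot$conf_high
      )
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of total knowledge scores
#'
#' @param scores A score table from [score_table()], optionally with a
#'   `group` column for faceting.
#' @param group Optional grouping column name.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, group = NULL) {
  scores <- check_data_frame(scores, "scores")
  check_cols(scores, "total", "scores")
  p <- ggplot2::ggplot(
    scores[!is.na(scores$total), ],
    ggplot2::aes(x = .data$total)
  ) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::scale_x_continuous(breaks = 0:8) +
    ggplot2::labs(x = "Total knowledge score", y = "Respondents") +
    ggplot2::theme_minimal()
  if (!is.null(group)) {
    check_cols(scores, group, "scores")
    p <- p + ggplot2::facet_wrap(group)
  }
  p
}
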