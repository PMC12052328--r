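#' Discriminant-validity analysis
#'
#' Compares the knowledge score between two groups expected to differ on the
#' construct (e.g. nutrition vs education students): group mean and SD for
#' each category score and for the total, with a two-sided [mann_whitney()]
#' p-value per row. Respondents with a missing total (incomplete responses)
#' are excluded.
#'
#' @param scores A score table from [score_table()] with an added group
#'   column (e.g. joined from covariates); exactly two groups.
#' @param group Name of the grouping column.
#' @param reference Optional level to use as the reference (higher-knowledge)
#'   group; defaults to the first level encountered.
#' @param exact Passed to [mann_whitney()].
#' @return An object of class `nova_discriminant`. [tidy()] returns the
#'   per-component table; [glance()] the total-score row with group sizes.
#' @examples
#' study <- generate_two_group_study(
#'   scenario_nutrition_students(n = 30),
#'   scenario_education_students(n = 30)
#' )
#' scores <- score_table(study) |>
#'   dplyr::inner_join(study$covariates, by = "respondent_id")
#' discriminant_validity(scores)
#' @export
discriminant_validity <- function(scores, group = "group", reference = NULL,
                                  exact = NULL) {
  scores <- check_data_frame(scores, "scores")
  check_cols(scores, c("respondent_id", "total", group), "scores")
  cats <- attr(scores, "categories") %||%
    setdiff(
      names(scores),
      c("respondent_id", "total", "n_complete_categories", group, "sex", "age", "education", "k")
    )
  g <- as.character(scores[[group]])
  levels_g <- unique(g)
  if (length(levels_g) != 2) nv_usage("`scores` must contain exactly 2 groups.")
  if (!is.null(reference)) {
    if (!reference %in% levels_g) nv_usage("`reference` is not a group level.")
    levels_g <- c(reference, setdiff(levels_g, reference))
  }
  keep <- !is.na(scores$total)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("Excluding %d respondent(s) with incomplete responses.", n_dropped))
  }
  scores <- scores[keep, ]
  g <- g[keep]

  rows <- purrr::map_dfr(c(cats, "total"), function(comp) {
    a <- scores[[comp]][g == levels_g[1]]
    b <- scores[[comp]][g == levels_g[2]]
    mw <- mann_whitney(a, b, exact = exact)
    tibble::tibble(
      component = comp,
      mean_ref = mean(a), sd_ref = sd(a),
      mean_cmp = mean(b), sd_cmp = sd(b),
      statistic = mw$statistic, p_value = mw$p_value
    )
  })
  structure(
    list(
      table = rows,
      groups = levels_g,
      n = c(sum(g == levels_g[1]), sum(g == levels_g[2])),
      n_excluded = n_dropped
    ),
    class = "nova_discriminant"
  )
}

#' @export
tidy.nova_discriminant <- function(x, ...) x$table

#' @export
glance.nova_discriminant <- function(x, ...) {
  tot <- x$table[x$table$component == "total", ]
  tibble::tibble(
    group_ref = x$groups[1], group_cmp = x$groups[2],
    n_ref = x$n[1], n_cmp = x$n[2],
    mean_ref = tot$mean_ref, sd_ref = tot$sd_ref,
    mean_cmp = tot$mean_cmp, sd_cmp = tot$sd_cmp,
    p_value = tot$p_value
  )
}

#' @export
print.nova_discriminant <- function(x, ...) {
  cat(sprintf(
    "<nova_discriminant> %s (n = %d) vs %s (n = %d)\n",
    x$groups[1], x$n[1], x$groups[2], x$n[2]
  ))
  tab <- x$table
  cat(sprintf(
    "  %-10s %10s %12s %10s\n", "component",
    paste0(substr(x$groups[1], 1, 9), " M(SD)"),
    paste0(substr(x$groups[2], 1, 9), " M(SD)"), "p"
  ))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf(
      "  %-10s %4.1f (%.1f) %6.1f (%.1f) %10.2g\n",
      tab$component[i], tab$mean_ref[i], tab$sd_ref[i],
      tab$mean_cmp[i], tab$sd_cmp[i], tab$p_value[i]
    ))
  }
  invisible(x)
}

#' Convergent-validity analysis
#'
#' Tests whether the knowledge score is associated with usual UPF intake:
#' for each category score and for the total, fits [ols_adjusted()] with
#' usual intake as outcome and sex, age and education as adjustment terms,
#' and reports the score coefficient (percentage points of energy per score
#' point) with its confidence interval.
#'
#' @param scores A score table from [score_table()].
#' @param usual Usual-intake estimates from [estimate_usual()] (columns
#'   `respondent_id`, `usual_estimate`).
#' @param covariates A data frame with `respondent_id`, `sex`, `age`,
#'   `education`.
#' @param covariate_terms Adjustment columns passed to [ols_adjusted()].
#' @param conf_level Confidence level for intervals.
#' @return An object of class `nova_convergent`. [tidy()] returns one row
#'   per component (`mean`, `sd`, `estimate`, `std_error`, `conf_low`,
#'   `conf_high`, `p_value`); [glance()] a one-row cohort summary.
#' @export
convergent_validity <- function(scores, usual, covariates,
                                covariate_terms = c("sex", "age", "education"),
                                conf_level = 0.95) {
  scores <- check_data_frame(scores, "scores")
  usual <- check_data_frame(usual, "usual")
  covariates <- check_data_frame(covariates, "covariates")
  check_cols(scores, c("respondent_id", "total"), "scores")
  check_cols(usual, c("respondent_id", "usual_estimate"), "usual")
  check_cols(covariates, c("respondent_id", covariate_terms), "covariates")
  cats <- attr(scores, "categories") %||%
    setdiff(names(scores), c("respondent_id", "total", "n_complete_categories"))

  data <- scores |>
    dplyr::inner_join(usual[, c("respondent_id", "usual_estimate")], by = "respondent_id") |>
    dplyr::inner_join(
      covariates[, c("respondent_id", covariate_terms)],
      by = "respondent_id"
    ) |>
    dplyr::filter(!is.na(.data$total))

  fits <- purrr::map(
    setNames(c(cats, "total"), c(cats, "total")),
    function(comp) {
      ols_adjusted(data,
        response = "usual_estimate", score = comp,
        covariates = covariate_terms, conf_level = conf_level
      )
    }
  )
  rows <- purrr::imap_dfr(fits, function(fit, comp) {
    co <- tidy(fit)
    sc <- co[co$term == comp, ]
    tibble::tibble(
      component = comp,
      mean = mean(data[[comp]]), sd = sd(data[[comp]]),
      estimate = sc$estimate, std_error = sc$std_error,
      conf_low = sc$conf_low, conf_high = sc$conf_high,
      p_value = sc$p_value
    )
  })
  structure(
    list(
      table = rows, fits = fits, n = nrow(data),
      usual_mean = mean(data$usual_estimate),
      usual_sd = sd(data$usual_estimate),
      data = data, conf_level = conf_level
    ),
    class = "nova_convergent"
  )
}

#' @export
tidy.nova_convergent <- function(x, ...) x$table

#' @export
glance.nova_convergent <- function(x, ...) {
  tot <- x$table[x$table$component == "total", ]
  tibble::tibble(
    n = x$n,
    usual_mean = x$usual_mean, usual_sd = x$usual_sd,
    score_mean = tot$mean, score_sd = tot$sd,
    beta_total = tot$estimate,
    conf_low = tot$conf_low, conf_high = tot$conf_high,
    p_value = tot$p_value
  )
}

#' @export
print.nova_convergent <- function(x, ...) {
  cat(sprintf(
    "<nova_convergent> n = %d | usual UPF intake %.1f%% (SD %.1f)\n",
    x$n, x$usual_mean, x$usual_sd
  ))
  cat(sprintf(
    "  %-10s %9s %8s %18s %8s\n",
    "component", "M (SD)", "beta", sprintf("%d%% CI", round(100 * x$conf_level)), "p"
  ))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf(
      "  %-10s %4.1f (%.1f) %8.2f [%6.2f, %6.2f] %8.2g\n",
      tab$component[i], tab$mean[i], tab$sd[i], tab$estimate[i],
      tab$conf_low[i], tab$conf_high[i], tab$p_value[i]
    ))
  }
  invisible(x)
}
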