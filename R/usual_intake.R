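#' Variance components of repeated recalls
#'
#' One-way random-effects method-of-moments decomposition of repeated
#' 24-hour-recall observations into between-person and within-person
#' variance. Within-person variance is the pooled within-person mean square;
#' between-person variance is `(MSB - var_within) / n0` with `n0` the
#' classical effective replicate count for unbalanced designs,
#' `n0 = (N - sum(n_i^2) / N) / (k - 1)`. Negative between-person estimates
#' are truncated to zero with a warning.
#'
#' This is the shrinkage core of usual-intake estimation: it deliberately
#' omits the covariate modeling, transformation and consumption-probability
#' parts of full usual-intake methods such as the Multiple Source Method.
#'
#' @param recalls A data frame with columns `respondent_id` and
#'   `upf_percent` (% of energy from ultra-processed food per recall day,
#'   in \[0, 100\]).
#' @return An object of class `nova_varcomp` with elements `grand_mean`,
#'   `var_between`, `var_within`, `n0`, `n_respondents`,
#'   `mean_recalls_per_respondent`, `truncated`, `respondent_ids`.
#' @seealso [estimate_usual()]
#' @export
variance_components <- function(recalls) {
  recalls <- check_data_frame(recalls, "recalls")
  check_cols(recalls, c("respondent_id", "upf_percent"), "recalls")
  if (any(is.na(recalls$upf_percent))) {
    nv_abort("`upf_percent` contains missing values.")
  }
  if (any(recalls$upf_percent < 0 | recalls$upf_percent > 100)) {
    nv_abort("`upf_percent` must lie in [0, 100].")
  }
  per <- recalls |>
    dplyr::group_by(respondent_id = as.character(.data$respondent_id)) |>
    dplyr::summarise(
      n_i = dplyr::n(),
      mean_i = mean(.data$upf_percent),
      ss_i = sum((.data$upf_percent - mean(.data$upf_percent))^2),
      .groups = "drop"
    )
  k <- nrow(per)
  if (k < 2) nv_abort("Need at least 2 respondents to estimate variance components.")
  if (!any(per$n_i >= 2)) {
    nv_abort(
      "No respondent has 2 or more recalls: within-person variance is unidentifiable.",
      class = "novascore_identifiability_error"
    )
  }
  N <- sum(per$n_i)
  grand_mean <- sum(per$n_i * per$mean_i) / N
  var_within <- sum(per$ss_i) / (N - k)
  msb <- sum(per$n_i * (per$mean_i - grand_mean)^2) / (k - 1)
  n0 <- (N - sum(per$n_i^2) / N) / (k - 1)
  var_between <- (msb - var_within) / n0
  truncated <- FALSE
  if (var_between < 0) {
    warn(sprintf(
      "Negative between-person variance estimate (%.4f) truncated to 0.",
      var_between
    ))
    var_between <- 0
    truncated <- TRUE
  }
  structure(
    list(
      grand_mean = grand_mean,
      var_between = var_between,
      var_within = var_within,
      n0 = n0,
      n_respondents = k,
      mean_recalls_per_respondent = N / k,
      truncated = truncated,
      respondent_ids = per$respondent_id
    ),
    class = "nova_varcomp"
  )
}

#' @export
print.nova_varcomp <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<nova_varcomp> %d respondents, %.2f recalls/person\n",
      "  grand mean %.2f%% | between-person var %.2f | within-person var %.2f\n"
    ),
    x$n_respondents, x$mean_recalls_per_respondent,
    x$grand_mean, x$var_between, x$var_within
  ))
  invisible(x)
}

#' @export
glance.nova_varcomp <- function(x, ...) {
  tibble::tibble(
    grand_mean = x$grand_mean,
    var_between = x$var_between,
    var_within = x$var_within,
    n0 = x$n0,
    n_respondents = x$n_respondents,
    mean_recalls_per_respondent = x$mean_recalls_per_respondent,
    truncated = x$truncated
  )
}

#' Estimate usual intake by shrinkage
#'
#' Deattenuates each respondent's observed recall mean by shrinking it
#' toward the grand mean in proportion to how much of its variance is
#' within-person noise:
#' `lambda_i = var_between / (var_between + var_within / n_i)` and
#' `usual_i = grand_mean + lambda_i * (person_mean_i - grand_mean)`.
#' More recalls mean less shrinkage; with no within-person variance the
#' person mean is returned unchanged, and with no between-person variance
#' every estimate collapses to the grand mean.
#'
#' @param recalls A data frame with columns `respondent_id`, `upf_percent`.
#' @param components A [variance_components()] object computed from the same
#'   recalls; computed automatically when omitted.
#' @return A tibble with one row per respondent: `respondent_id`,
#'   `n_recalls`, `person_mean`, `shrinkage_lambda`, `usual_estimate`.
#' @examples
#' recalls <- data.frame(
#'   respondent_id = rep(c("a", "b", "c"), each = 2),
#'   upf_percent = c(10, 14, 20, 24, 31, 27)
#' )
#' estimate_usual(recalls)
#' @export
estimate_usual <- function(recalls, components = NULL) {
  recalls <- check_data_frame(recalls, "recalls")
  check_cols(recalls, c("respondent_id", "upf_percent"), "recalls")
  if (is.null(components)) components <- variance_components(recalls)
  stopifnot(inherits(components, "nova_varcomp"))
  per <- recalls |>
    dplyr::group_by(respondent_id = as.character(.data$respondent_id)) |>
    dplyr::summarise(
      n_recalls = dplyr::n(),
      person_mean = mean(.data$upf_percent),
      .groups = "drop"
    )
  unknown <- setdiff(per$respondent_id, components$respondent_ids)
  if (length(unknown) > 0) {
    nv_abort(sprintf(
      "Respondent(s) absent from the variance-components input: %s.",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  vb <- components$var_between
  vw <- components$var_within
  lambda <- if (vw == 0) {
    rep(1, nrow(per))
  } else {
    vb / (vb + vw / per$n_recalls)
  }
  per |>
    dplyr::mutate(
      shrinkage_lambda = lambda,
      usual_estimate = components$grand_mean +
        lambda * (.data$person_mean - components$grand_mean)
    )
}
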