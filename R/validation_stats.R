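#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples, the test used to
#' compare knowledge scores between groups. The statistic is the U of the
#' first sample computed from midranks. The p-value is exact (full
#' enumeration of group assignments, valid with ties) when both samples have
#' at most 10 observations and there are no ties, or whenever `exact = TRUE`
#' and enumeration is feasible; otherwise a normal approximation with
#' tie-corrected variance is used (no continuity correction).
#'
#' The exact two-sided p-value is the permutation probability of a U at
#' least as far from its null mean `n1 * n2 / 2` as the observed one.
#'
#' @param x,y Numeric samples (e.g. total scores of the two groups).
#' @param exact `NULL` (auto), `TRUE` (force enumeration when feasible) or
#'   `FALSE` (force normal approximation).
#' @return A one-row tibble: `method`, `statistic` (U of `x`), `p_value`,
#'   `n1`, `n2`, `exact`, `tie_corrected`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) {
    n_na <- sum(is.na(x)) + sum(is.na(y))
    warn(sprintf("Dropping %d missing value(s).", n_na))
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
  }
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) {
    nv_abort("Both samples must be non-empty.", class = "novascore_empty_error")
  }
  pooled <- c(x, y)
  r <- rank(pooled) # midranks
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  n_comb <- choose(n1 + n2, n1)
  use_exact <- if (is.null(exact)) {
    n1 <= 10 && n2 <= 10 && !ties
  } else {
    isTRUE(exact) && n_comb <= 2e5
  }
  if (use_exact) {
    mu <- n1 * n2 / 2
    idx <- combn(n1 + n2, n1)
    rank_sums <- colSums(matrix(r[idx], nrow = n1))
    u_all <- rank_sums - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u1 - mu) - 1e-9)
    return(tibble::tibble(
      method = "Mann-Whitney U (exact permutation)",
      statistic = u1, p_value = p, n1 = n1, n2 = n2,
      exact = TRUE, tie_corrected = FALSE
    ))
  }
  nn <- n1 + n2
  tie_counts <- table(pooled)
  sigma2 <- n1 * n2 / 12 *
    ((nn + 1) - sum(tie_counts^3 - tie_counts) / (nn * (nn - 1)))
  if (sigma2 <= 0) {
    p <- 1
  } else {
    z <- (u1 - n1 * n2 / 2) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  tibble::tibble(
    method = "Mann-Whitney U (normal approximation)",
    statistic = u1, p_value = p, n1 = n1, n2 = n2,
    exact = FALSE, tie_corrected = ties
  )
}

#' Chi-square test for a 2x2 table
#'
#' Pearson chi-square with Yates continuity correction by default, as used
#' for the group-comparability contrasts (sex, education level) between the
#' two student groups.
#'
#' @param counts A 2x2 matrix (or coercible) of nonnegative integer counts;
#'   rows are levels of one variable, columns the groups.
#' @param continuity Apply the Yates continuity correction (default `TRUE`).
#' @return A one-row tibble: `method`, `statistic`, `df`, `p_value`,
#'   `continuity`.
#' @examples
#' chi_square_2x2(matrix(c(11, 65, 27, 72), nrow = 2))
#' @export
chi_square_2x2 <- function(counts, continuity = TRUE) {
  m <- as.matrix(counts)
  if (!all(dim(m) == c(2, 2))) nv_usage("`counts` must be a 2x2 table.")
  if (any(is.na(m)) || any(m < 0) || !all(is_wholenumber(m))) {
    nv_abort("`counts` must be nonnegative integers.")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    nv_abort("All row and column margins must be positive.")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = continuity))
  tibble::tibble(
    method = if (continuity) {
      "Pearson chi-square, Yates continuity correction"
    } else {
      "Pearson chi-square"
    },
    statistic = unname(ct$statistic),
    df = 1L,
    p_value = unname(ct$p.value),
    continuity = continuity
  )
}

#' Welch two-sample t test from summary statistics
#'
#' Computes the Welch (unequal-variance) t statistic, Satterthwaite degrees
#' of freedom and two-sided p-value from group means, SDs and sizes - the
#' form needed to reproduce an age comparison from printed summaries.
#'
#' @param mean1,sd1,n1 Summary of the first group.
#' @param mean2,sd2,n2 Summary of the second group.
#' @return A one-row tibble: `method`, `statistic`, `df`, `p_value`,
#'   `mean_diff`, `std_error`.
#' @examples
#' welch_t_from_summary(24.5, 4.8, 76, 24.4, 8.2, 99)
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0) nv_abort("SDs must be positive.")
  if (!is_wholenumber(n1) || !is_wholenumber(n2) || n1 < 2 || n2 < 2) {
    nv_abort("Group sizes must be integers >= 2.")
  }
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se <- sqrt(v1 + v2)
  t_stat <- (mean1 - mean2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble::tibble(
    method = "Welch two-sample t (from summaries)",
    statistic = t_stat,
    df = df,
    p_value = 2 * pt(-abs(t_stat), df),
    mean_diff = mean1 - mean2,
    std_error = se
  )
}

#' Covariate-adjusted least-squares regression
#'
#' Fits the convergent-validity model: usual UPF intake (% of energy)
#' regressed on a knowledge-score term plus sociodemographic covariates
#' (sex, age, education by default), with classical standard errors.
#' Character or factor covariates are expanded to indicator terms against
#' their first level.
#'
#' @param data A data frame containing all model variables, one row per
#'   respondent (complete cases are used, with a message when rows drop).
#' @param response Name of the outcome column (default `"usual_estimate"`).
#' @param score Name of the score column whose coefficient is of interest
#'   (default `"total"`; percentage points of energy per score point).
#' @param covariates Character vector of adjustment columns.
#' @param conf_level Confidence level for [tidy()] intervals.
#' @return An object of class `nova_ols`; see [tidy.nova_ols()] and
#'   [glance.nova_ols()].
#' @export
ols_adjusted <- function(data, response = "usual_estimate", score = "total",
                         covariates = c("sex", "age", "education"),
                         conf_level = 0.95) {
  data <- check_data_frame(data, "data")
  vars <- c(response, score, covariates)
  check_cols(data, vars, "data")
  df <- data[, vars]
  cc <- complete.cases(df)
  if (!all(cc)) {
    inform(sprintf("Dropping %d incomplete row(s).", sum(!cc)))
    df <- df[cc, ]
  }
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.character), factor))
  fml <- stats::reformulate(c(score, covariates), response = response)
  mm <- model.matrix(fml, data = df)
  if (nrow(df) < ncol(mm) + 10) {
    nv_abort(sprintf(
      "Need at least %d observations for %d parameters; got %d.",
      ncol(mm) + 10, ncol(mm), nrow(df)
    ))
  }
  fit <- lm(fml, data = df)
  if (anyNA(coef(fit))) {
    nv_abort(sprintf(
      "Rank-deficient design; collinear term(s): %s.",
      paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")
    ))
  }
  structure(
    list(
      fit = fit, response = response, score_term = score,
      covariates = covariates, n = nrow(df), conf_level = conf_level
    ),
    class = "nova_ols"
  )
}

#' @describeIn ols_adjusted Coefficient table as a tibble (`term`,
#'   `estimate`, `std_error`, `statistic`, `p_value`, `conf_low`,
#'   `conf_high`).
#' @param x A `nova_ols` object.
#' @param ... Unused.
#' @export
tidy.nova_ols <- function(x, ...) {
  s <- coef(summary(x$fit))
  ci <- stats::confint(x$fit, level = x$conf_level)
  tibble::tibble(
    term = rownames(s),
    estimate = unname(s[, "Estimate"]),
    std_error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p_value = unname(s[, "Pr(>|t|)"]),
    conf_low = unname(ci[, 1]),
    conf_high = unname(ci[, 2])
  )
}

#' @describeIn ols_adjusted One-row model summary (`n`, `r_squared`,
#'   `adj_r_squared`, `sigma`, and the score term's estimate and p-value).
#' @export
glance.nova_ols <- function(x, ...) {
  s <- summary(x$fit)
  co <- tidy(x)
  sc <- co[co$term == x$score_term, ]
  tibble::tibble(
    n = x$n,
    r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared,
    sigma = s$sigma,
    score_estimate = sc$estimate,
    score_p_value = sc$p_value
  )
}

#' @export
print.nova_ols <- function(x, ...) {
  cat(sprintf(
    "<nova_ols> %s ~ %s + %s (n = %d)\n",
    x$response, x$score_term, paste(x$covariates, collapse = " + "), x$n
  ))
  print(tidy(x))
  invisible(x)
}

#' Sample size for a two-group Mann-Whitney comparison
#'
#' Normal-approximation two-sample size for detecting a mean difference
#' `delta` with group SDs `sd1`, `sd2`, inflated by the worst-case
#' asymptotic relative efficiency of the Mann-Whitney test versus the t
#' test (0.864):
#' `n = ceiling(((z_{1 - alpha/2} + z_{power})^2 * (sd1^2 + sd2^2) / delta^2) / ARE)`
#' per group. With the planning inputs used for the discriminant study
#' (delta 0.5, SDs 0.8 and 1.2, alpha 0.05, power 0.80) this gives 76 per
#' group.
#'
#' @param delta Smallest mean difference to detect (score points), > 0.
#' @param sd1,sd2 Group standard deviations.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param nonparametric_are Relative-efficiency divisor; 1 gives the plain
#'   t-test size.
#' @return Integer sample size per group.
#' @examples
#' sample_size_two_groups(0.5, 0.8, 1.2)
#' @export
sample_size_two_groups <- function(delta, sd1, sd2, alpha = 0.05, power = 0.80,
                                   nonparametric_are = 0.864) {
  if (delta <= 0) nv_abort("`delta` must be positive.")
  if (sd1 <= 0 || sd2 <= 0) nv_abort("SDs must be positive.")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    nv_abort("`alpha` and `power` must lie in (0, 1).")
  }
  if (nonparametric_are <= 0) nv_abort("`nonparametric_are` must be positive.")
  n <- ceiling(
    ((qnorm(1 - alpha / 2) + qnorm(power))^2 * (sd1^2 + sd2^2) / delta^2) /
      nonparametric_are
  )
  if (!is.finite(n)) nv_abort("Sample size is not finite for these inputs.")
  max(1L, as.integer(n))
}

#' Group-comparability tests
#'
#' Reproduces the comparability battery of a two-group validation study:
#' chi-square tests (Yates-corrected for 2x2) for categorical covariates and
#' a Welch t test for age.
#'
#' @param covariates A data frame with columns `group` plus the covariates.
#' @param group Name of the grouping column (exactly 2 levels).
#' @param categorical,continuous Covariate column names to test.
#' @return A tibble: `variable`, `method`, `statistic`, `p_value`.
#' @export
group_comparability <- function(covariates, group = "group",
                                categorical = c("sex", "education"),
                                continuous = "age") {
  covariates <- check_data_frame(covariates, "covariates")
  check_cols(covariates, c(group, categorical, continuous), "covariates")
  g <- as.factor(covariates[[group]])
  if (nlevels(g) != 2) nv_usage("`group` must have exactly 2 levels.")
  rows <- list()
  for (v in categorical) {
    tab <- table(covariates[[v]], g)
    res <- if (all(dim(tab) == c(2, 2))) {
      chi_square_2x2(tab)
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab))
      tibble::tibble(
        method = "Pearson chi-square",
        statistic = unname(ct$statistic), df = unname(ct$parameter),
        p_value = unname(ct$p.value), continuity = FALSE
      )
    }
    rows[[v]] <- tibble::tibble(
      variable = v, method = res$method,
      statistic = res$statistic, p_value = res$p_value
    )
  }
  for (v in continuous) {
    x <- covariates[[v]][g == levels(g)[1]]
    y <- covariates[[v]][g == levels(g)[2]]
    tt <- stats::t.test(x, y)
    rows[[v]] <- tibble::tibble(
      variable = v, method = "Welch two-sample t",
      statistic = unname(tt$statistic), p_value = tt$p.value
    )
  }
  dplyr::bind_rows(rows)
}
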