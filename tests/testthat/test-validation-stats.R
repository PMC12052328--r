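test_that("Mann-Whitney exact path reproduces textbook and enumeration results", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1) # 2 of the C(6,3) = 20 assignments as extreme
  expect_true(res$exact)

  # identical samples: no separation
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3), exact = FALSE)
  expect_gte(same$p_value, 0.99)
  # all values equal: degenerate variance, p = 1
  expect_equal(mann_whitney(rep(2, 5), rep(2, 7))$p_value, 1)

  expect_error(mann_whitney(numeric(0), 1:3), class = "novascore_empty_error")
})

test_that("exact no-tie path agrees with stats::wilcox.test and full enumeration", {
  set.seed(47)
  for (i in 1:25) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    vals <- sample(1:100, n1 + n2) # distinct -> no ties
    x <- vals[1:n1]
    y <- vals[-(1:n1)]
    res <- mann_whitney(x, y)
    expect_true(res$exact)
    expect_equal(res$p_value, oracle_mw_enumeration(x, y))
    wt <- wilcox.test(x, y, exact = TRUE)
    expect_equal(res$statistic, unname(wt$statistic))
    expect_equal(res$p_value, wt$p.value)
  }
})

test_that("forced permutation path handles ties and matches enumeration", {
  set.seed(48)
  for (i in 1:10) {
    x <- sample(0:8, 5, replace = TRUE)
    y <- sample(0:8, 6, replace = TRUE)
    res <- mann_whitney(x, y, exact = TRUE)
    expect_true(res$exact)
    expect_equal(res$p_value, oracle_mw_enumeration(x, y))
  }
})

test_that("normal approximation uses the tie-corrected variance of wilcox.test", {
  set.seed(49)
  for (i in 1:10) {
    x <- sample(0:8, 40, replace = TRUE)
    y <- sample(0:8, 55, replace = TRUE)
    res <- mann_whitney(x, y)
    expect_false(res$exact)
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(res$p_value, wt$p.value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney holds its nominal 5% size under the null", {
  set.seed(50)
  rejections <- 0
  n_sim <- 1000
  for (i in 1:n_sim) {
    x <- rnorm(25)
    y <- rnorm(25)
    if (mann_whitney(x, y)$p_value < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / n_sim
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("Yates-corrected chi-square reproduces the printed comparability p-values", {
  sex <- chi_square_2x2(matrix(c(11, 65, 27, 72), nrow = 2, byrow = TRUE))
  expect_equal(sex$p_value, 0.064, tolerance = 0.002 / 0.064)
  edu <- chi_square_2x2(matrix(c(15, 61, 31, 68), nrow = 2, byrow = TRUE))
  expect_equal(edu$p_value, 0.121, tolerance = 0.002 / 0.121)
})

test_that("chi-square degenerate and invalid tables behave as specified", {
  prop <- chi_square_2x2(matrix(c(10, 30, 20, 60), nrow = 2))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p_value, 1)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), nrow = 2)), "margins")
  expect_error(chi_square_2x2(matrix(c(1.5, 2, 3, 4), nrow = 2)), "integers")
  expect_error(chi_square_2x2(matrix(1:6, nrow = 2)), class = "novascore_usage_error")
})

test_that("uncorrected chi-square equals the classical closed-form statistic", {
  set.seed(51)
  for (i in 1:20) {
    m <- matrix(sample(5:80, 4), nrow = 2)
    res <- chi_square_2x2(m, continuity = FALSE)
    n <- sum(m)
    want <- n * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
      (prod(rowSums(m)) * prod(colSums(m)))
    expect_equal(res$statistic, want, tolerance = 1e-12)
  }
})

test_that("Welch t from summaries reproduces the printed age comparison and a raw-data oracle", {
  age <- welch_t_from_summary(24.5, 4.8, 76, 24.4, 8.2, 99)
  expect_equal(age$p_value, 0.920, tolerance = 0.002 / 0.920)

  ident <- welch_t_from_summary(10, 2, 30, 10, 3, 40)
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  # raw data constructed to match the summaries exactly
  set.seed(52)
  mk <- function(n, m, s) {
    z <- rnorm(n)
    m + s * (z - mean(z)) / sd(z)
  }
  x <- mk(30, 12.3, 2.1)
  y <- mk(45, 11.1, 3.4)
  res <- welch_t_from_summary(12.3, 2.1, 30, 11.1, 3.4, 45)
  wt <- t.test(x, y)
  expect_equal(res$statistic, unname(wt$statistic), tolerance = 1e-6)
  expect_equal(res$df, unname(wt$parameter), tolerance = 1e-6)

  expect_error(welch_t_from_summary(1, 0, 10, 2, 1, 10), "positive")
  expect_error(welch_t_from_summary(1, 1, 1, 2, 1, 10), ">= 2")
})

test_that("adjusted OLS recovers a noise-free linear law exactly", {
  set.seed(53)
  n <- 60
  df <- tibble::tibble(
    total = sample(0:8, n, replace = TRUE),
    sex = sample(c("female", "male"), n, replace = TRUE),
    age = round(rnorm(n, 40, 12), 1),
    education = sample(c("hs", "higher"), n, replace = TRUE),
    usual_estimate = 30 - 1.0 * total
  )
  fit <- ols_adjusted(df)
  # summary.lm warns about the (intentionally) exact interpolation
  co <- suppressWarnings(tidy(fit))
  expect_equal(co$estimate[co$term == "total"], -1.0, tolerance = 1e-10)
})

test_that("adjusted OLS matches the normal-equations oracle and is invariant to recentering", {
  set.seed(54)
  n <- 150
  df <- tibble::tibble(
    total = sample(0:8, n, replace = TRUE),
    sex = sample(c("female", "male"), n, replace = TRUE),
    age = rnorm(n, 40, 12),
    education = sample(c("ihs", "hs", "higher"), n, replace = TRUE),
    usual_estimate = pmin(100, pmax(0, 27 - 1.03 * total + rnorm(n, 0, 8)))
  )
  fit <- ols_adjusted(df)
  X <- model.matrix(
    usual_estimate ~ total + factor(sex) + age + factor(education),
    data = df
  )
  want <- oracle_ols_coefs(X, df$usual_estimate)
  expect_equal(unname(coef(fit$fit)), unname(want), tolerance = 1e-8)

  centered <- dplyr::mutate(df, age = age - mean(age))
  fit_c <- ols_adjusted(centered)
  expect_equal(
    tidy(fit)$estimate[tidy(fit)$term == "total"],
    tidy(fit_c)$estimate[tidy(fit_c)$term == "total"],
    tolerance = 1e-10
  )
})

test_that("rank-deficient or undersized designs are refused", {
  set.seed(55)
  n <- 40
  df <- tibble::tibble(
    total = sample(0:8, n, replace = TRUE),
    sex = sample(c("f", "m"), n, replace = TRUE),
    age = rnorm(n, 40, 10),
    usual_estimate = rnorm(n, 20, 5)
  )
  df$age2 <- df$age # exact copy -> collinear
  expect_error(
    ols_adjusted(df, covariates = c("sex", "age", "age2")),
    "collinear|Rank-deficient"
  )
  expect_error(ols_adjusted(df[1:12, ], covariates = c("sex", "age")), "at least")
})

test_that("sample-size formula reproduces the planning example and its limits", {
  expect_identical(sample_size_two_groups(0.5, 0.8, 1.2), 76L)
  # textbook equal-sd case without the nonparametric inflation: ceil(15.70)
  expect_identical(
    sample_size_two_groups(1, 1, 1, nonparametric_are = 1), 16L
  )
  expect_identical(sample_size_two_groups(1e9, 0.8, 1.2), 1L)
  expect_error(sample_size_two_groups(0, 1, 1), "positive")
  expect_error(sample_size_two_groups(0.5, 1, 1, alpha = 1.2), "alpha")
})

test_that("group comparability battery runs on a two-group covariate table", {
  study <- generate_two_group_study(
    scenario_nutrition_students(n = 60, seed = 56),
    scenario_education_students(n = 60, seed = 57)
  )
  comp <- group_comparability(study$covariates)
  expect_equal(comp$variable, c("sex", "education", "age"))
  expect_true(all(comp$p_value >= 0 & comp$p_value <= 1))
  expect_match(comp$method[3], "Welch")
})
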