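toy_recalls <- function() {
  # 4 respondents x 2 recalls, values chosen for easy hand verification
  data.frame(
    respondent_id = rep(c("a", "b", "c", "d"), each = 2),
    occasion = rep(1:2, 4),
    upf_percent = c(10, 14, 20, 24, 30, 26, 40, 36)
  )
}

test_that("variance components match the hand-computed ANOVA oracle on the toy table", {
  rec <- toy_recalls()
  vc <- variance_components(rec)
  want <- oracle_varcomp(rec$respondent_id, rec$upf_percent)
  expect_equal(vc$grand_mean, want$grand_mean)
  expect_equal(vc$var_within, want$var_within)
  expect_equal(vc$var_between, want$var_between)
  expect_equal(vc$n0, want$n0)
  # the toy table by hand: person means 12/22/28/38, all within-SS = 8
  expect_equal(vc$grand_mean, 25)
  expect_equal(vc$var_within, 8) # SSW = 4 persons x 8, df = 8 - 4
  expect_equal(vc$n0, 2)
})

test_that("variance components match the oracle on random unbalanced designs", {
  set.seed(31)
  for (i in 1:10) {
    n_i <- sample(1:4, 12, replace = TRUE)
    if (!any(n_i >= 2)) n_i[1] <- 2
    ids <- rep(sprintf("p%02d", seq_along(n_i)), n_i)
    vals <- pmin(100, pmax(0, rnorm(length(ids), 25, 8)))
    rec <- data.frame(respondent_id = ids, upf_percent = vals)
    vc <- suppressWarnings(variance_components(rec))
    want <- oracle_varcomp(ids, vals)
    expect_equal(vc$var_within, want$var_within)
    expect_equal(vc$var_between, want$var_between)
  }
})

test_that("degenerate variance structures collapse as expected", {
  # identical recalls within each person -> no within-person variance
  rec <- data.frame(
    respondent_id = rep(c("a", "b"), each = 2),
    upf_percent = c(10, 10, 30, 30)
  )
  vc <- variance_components(rec)
  expect_equal(vc$var_within, 0)
  expect_gt(vc$var_between, 0)
  # one shared constant -> both components zero
  const <- data.frame(
    respondent_id = rep(c("a", "b"), each = 2),
    upf_percent = rep(20, 4)
  )
  vc0 <- variance_components(const)
  expect_equal(vc0$var_within, 0)
  expect_equal(vc0$var_between, 0)
})

test_that("negative between-person estimates are truncated to zero with a warning", {
  # person means identical, all variation within
  rec <- data.frame(
    respondent_id = rep(c("a", "b"), each = 2),
    upf_percent = c(10, 30, 15, 25)
  )
  expect_warning(vc <- variance_components(rec), "truncated")
  expect_equal(vc$var_between, 0)
  expect_true(vc$truncated)
})

test_that("identifiability and input validation errors are raised", {
  expect_error(
    variance_components(data.frame(respondent_id = "a", upf_percent = 10)),
    "at least 2 respondents"
  )
  expect_error(
    variance_components(data.frame(respondent_id = c("a", "b"), upf_percent = c(10, 20))),
    class = "novascore_identifiability_error"
  )
  expect_error(
    variance_components(data.frame(respondent_id = c("a", "a", "b"), upf_percent = c(10, 20, 110))),
    "\\[0, 100\\]"
  )
  # respondent absent from the components input
  vc <- variance_components(toy_recalls())
  stranger <- data.frame(respondent_id = c("zz", "zz"), upf_percent = c(10, 20))
  expect_error(estimate_usual(stranger, vc), "zz")
})

test_that("shrinkage limits: no within-noise keeps person means, no between-variance collapses to the grand mean", {
  rec <- data.frame(
    respondent_id = rep(c("a", "b"), each = 2),
    upf_percent = c(10, 10, 30, 30)
  )
  u <- estimate_usual(rec)
  expect_equal(u$shrinkage_lambda, c(1, 1))
  expect_equal(u$usual_estimate, u$person_mean)

  rec2 <- data.frame(
    respondent_id = rep(c("a", "b"), each = 2),
    upf_percent = c(10, 30, 15, 25)
  )
  suppressWarnings(u2 <- estimate_usual(rec2))
  expect_equal(u2$shrinkage_lambda, c(0, 0))
  expect_equal(u2$usual_estimate, rep(20, 2))
})

test_that("lambda lies in [0, 1], increases with recall count, and estimates stay between grand and person mean", {
  set.seed(37)
  scn <- scenario_nutrinet_cohort(n = 300, seed = 37)
  scores <- score_table(generate_ratings(scn))
  recalls <- generate_recalls(scores, scn)
  vc <- variance_components(recalls)
  u <- estimate_usual(recalls, vc)
  expect_true(all(u$shrinkage_lambda >= 0 & u$shrinkage_lambda <= 1))
  by_n <- tapply(u$shrinkage_lambda, u$n_recalls, unique)
  expect_true(all(diff(unlist(by_n)) > 0))
  lo <- pmin(u$person_mean, vc$grand_mean)
  hi <- pmax(u$person_mean, vc$grand_mean)
  expect_true(all(u$usual_estimate >= lo - 1e-12 & u$usual_estimate <= hi + 1e-12))
})

test_that("grand mean is preserved exactly under a balanced design", {
  set.seed(38)
  u <- rnorm(30, 22, 6)
  rec <- data.frame(
    respondent_id = rep(sprintf("p%02d", 1:30), each = 3),
    upf_percent = pmin(100, pmax(0, rep(u, each = 3) + rnorm(90, 0, 4)))
  )
  u <- estimate_usual(rec)
  expect_equal(mean(u$usual_estimate), mean(rec$upf_percent))
})

test_that("variance-component estimates converge to truth as the cohort grows", {
  vb_true <- 81
  vw_true <- 9
  est <- function(n, seed) {
    withr::with_seed(seed, {
      u <- rnorm(n, 25, sqrt(vb_true))
      rec <- data.frame(
        respondent_id = rep(sprintf("p%05d", 1:n), each = 3),
        upf_percent = pmin(100, pmax(0, rep(u, each = 3) + rnorm(3 * n, 0, sqrt(vw_true))))
      )
      vc <- variance_components(rec)
      c(vb = vc$var_between, vw = vc$var_within)
    })
  }
  small <- est(200, 1)
  big <- est(2000, 1)
  expect_lt(abs(small["vb"] - vb_true) / vb_true, 0.25)
  expect_lt(abs(small["vw"] - vw_true) / vw_true, 0.25)
  expect_lt(abs(big["vb"] - vb_true) / vb_true, 0.10)
  expect_lt(abs(big["vw"] - vw_true) / vw_true, 0.10)
})

test_that("shrinkage beats raw person means against the simulated truth", {
  scn <- scenario_nutrinet_cohort(n = 400, seed = 41)
  scores <- score_table(generate_ratings(scn))
  recalls <- generate_recalls(scores, scn)
  truth <- attr(recalls, "truth")
  u <- estimate_usual(recalls) |>
    dplyr::inner_join(truth, by = "respondent_id")
  mse_shrunk <- mean((u$usual_estimate - u$usual_true)^2)
  mse_raw <- mean((u$person_mean - u$usual_true)^2)
  expect_lt(mse_shrunk, mse_raw)
})
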