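#' Recall-generation model for usual UPF intake
#'
#' Defines how synthetic 24-hour recalls are produced from knowledge scores.
#' A respondent's true usual intake (% of energy from ultra-processed food)
#' is `intercept + slope * total_score + b_i` with person effect
#' `b_i ~ N(0, sd_between^2)`; each observed recall adds day-to-day noise
#' `N(0, sd_within^2)`. Both quantities are truncated to \[0, 100\].
#'
#' Defaults calibrate the cohort scenario to a mean usual intake near 21.6%
#' (SD near 9.1) with a slope of -1.03 percentage points per score point.
#' `recall_count_probs` defaults to the observed completion pattern of the
#' cohort (10.5% / 17.8% / 71.6% completing 1 / 2 / 3 recalls); the
#' probabilities are normalized to sum to one.
#'
#' @param intercept,slope Linear relation of true usual intake (%) to the
#'   total knowledge score (percentage points per score point).
#' @param sd_between Between-person SD (%) of usual intake around the line.
#' @param sd_within Within-person day-to-day SD (%) of a single recall.
#' @param recall_count_probs Probabilities of completing 1, 2 or 3 recalls.
#' @return An object of class `nova_recall_model`.
#' @export
recall_model <- function(intercept = 27.36, slope = -1.03,
                         sd_between = 9.0, sd_within = 3.0,
                         recall_count_probs = c(0.105, 0.178, 0.716)) {
  if (sd_between < 0 || sd_within < 0) nv_usage("Recall SDs must be >= 0.")
  if (length(recall_count_probs) != 3 || any(recall_count_probs < 0)) {
    nv_usage("`recall_count_probs` must be 3 nonnegative probabilities (1/2/3 recalls).")
  }
  s <- sum(recall_count_probs)
  if (abs(s - 1) > 0.02) {
    nv_usage("`recall_count_probs` must sum to 1 (within 0.02).")
  }
  structure(
    list(
      intercept = intercept, slope = slope,
      sd_between = sd_between, sd_within = sd_within,
      recall_count_probs = recall_count_probs / s
    ),
    class = "nova_recall_model"
  )
}

#' Define a synthetic cohort scenario
#'
#' A scenario bundles everything needed to simulate one labeled group of
#' respondents: its size, the distribution of the latent knowledge parameter
#' `k`, the rating noise, covariate distributions, the recall model and a
#' seed. The latent rating model places each item's expected rating at
#' `m_bar + k * (m_g - m_bar)`, where `m_g` is the latent healthiness mean of
#' the item's Nova group (defaults G1 = 9, G3 = 6, G4 = 3) and `m_bar` their
#' mean, adds `N(0, noise_sd^2)` noise, rounds, and clamps to the rating
#' scale. `k = 1` with no noise reproduces the Nova ordering exactly; `k = 0`
#' erases all group separation (chance-level knowledge).
#'
#' @param n Number of respondents.
#' @param label Group label attached to every respondent.
#' @param k_mean,k_sd Mean and SD of the Beta-distributed knowledge
#'   parameter `k` in (0, 1).
#' @param noise_sd SD of the Gaussian rating noise, on the rating scale.
#' @param group_means Named vector of latent healthiness means for G1/G3/G4.
#' @param sex_female_prop Proportion of female respondents.
#' @param age_mean,age_sd Age distribution (years), truncated at 18.
#' @param education_probs Named probabilities over education levels.
#' @param recall A [recall_model()].
#' @param seed Integer seed; all generation from this scenario is a
#'   deterministic function of it.
#' @return An object of class `nova_scenario`.
#' @seealso [scenario_nutrition_students()], [scenario_education_students()],
#'   [scenario_nutrinet_cohort()] for the calibrated defaults.
#' @export
cohort_scenario <- function(n,
                            label = "cohort",
                            k_mean = 0.60, k_sd = 0.10,
                            noise_sd = 1.5,
                            group_means = c(G1 = 9, G3 = 6, G4 = 3),
                            sex_female_prop = 0.545,
                            age_mean = 40.2, age_sd = 13.6,
                            education_probs = c(
                              incomplete_high_school = 0.035,
                              high_school = 0.661,
                              higher_education = 0.304
                            ),
                            recall = recall_model(),
                            seed = 1L) {
  if (!is_wholenumber(n) || n < 0) nv_usage("`n` must be a nonnegative integer.")
  if (noise_sd < 0) nv_usage("`noise_sd` must be >= 0.")
  if (!setequal(names(group_means), c("G1", "G3", "G4"))) {
    nv_usage("`group_means` must be named G1, G3, G4.")
  }
  if (sex_female_prop < 0 || sex_female_prop > 1) {
    nv_usage("`sex_female_prop` must be in [0, 1].")
  }
  if (is.null(names(education_probs)) || any(education_probs < 0) ||
    abs(sum(education_probs) - 1) > 0.02) {
    nv_usage("`education_probs` must be named nonnegative probabilities summing to 1.")
  }
  beta_shapes(k_mean, k_sd) # validates compatibility
  stopifnot(inherits(recall, "nova_recall_model"))
  structure(
    list(
      n = as.integer(n), label = as.character(label),
      k_mean = k_mean, k_sd = k_sd, noise_sd = noise_sd,
      group_means = group_means[c("G1", "G3", "G4")],
      sex_female_prop = sex_female_prop,
      age_mean = age_mean, age_sd = age_sd,
      education_probs = education_probs / sum(education_probs),
      recall = recall,
      seed = as.integer(seed)
    ),
    class = "nova_scenario"
  )
}

#' @export
print.nova_scenario <- function(x, ...) {
  cat(sprintf(
    "<nova_scenario> '%s': n = %d, k ~ Beta(mean %.2f, sd %.2f), noise_sd %.2f, seed %d\n",
    x$label, x$n, x$k_mean, x$k_sd, x$noise_sd, x$seed
  ))
  invisible(x)
}

#' Calibrated default scenarios
#'
#' Three ready-made scenarios emulating the validation study populations:
#' final-year nutrition students (higher knowledge), education students
#' (lower knowledge), and a large web-cohort subsample with repeated dietary
#' recalls. Knowledge distributions were calibrated by simulation so that
#' mean total scores land near 6.7, 5.3 and 5.6 respectively; covariate
#' distributions follow the published sample descriptions.
#'
#' @param n Number of respondents (defaults: 76, 99, 1245).
#' @param seed Integer seed.
#' @return A `nova_scenario`.
#' @export
scenario_nutrition_students <- function(n = 76, seed = 101L) {
  cohort_scenario(
    n = n, label = "nutrition",
    k_mean = 0.89, k_sd = 0.12,
    sex_female_prop = 65 / 76,
    age_mean = 24.5, age_sd = 4.8,
    education_probs = c(high_school = 15 / 76, higher_education = 61 / 76),
    seed = seed
  )
}

#' @rdname scenario_nutrition_students
#' @export
scenario_education_students <- function(n = 99, seed = 102L) {
  cohort_scenario(
    n = n, label = "education",
    k_mean = 0.55, k_sd = 0.10,
    sex_female_prop = 72 / 99,
    age_mean = 24.4, age_sd = 8.2,
    education_probs = c(high_school = 31 / 99, higher_education = 68 / 99),
    seed = seed
  )
}

#' @rdname scenario_nutrition_students
#' @export
scenario_nutrinet_cohort <- function(n = 1245, seed = 103L) {
  cohort_scenario(n = n, label = "cohort", seed = seed)
}

# draw covariates + latent knowledge for one scenario (inside caller's seed scope)
draw_respondents <- function(scenario) {
  n <- scenario$n
  shp <- beta_shapes(scenario$k_mean, scenario$k_sd)
  id <- sprintf("%s_%0*d", scenario$label, max(3, nchar(n)), seq_len(n))
  tibble::tibble(
    respondent_id = id,
    group = scenario$label,
    sex = ifelse(stats::runif(n) < scenario$sex_female_prop, "female", "male"),
    age = round(pmax(18, rnorm(n, scenario$age_mean, scenario$age_sd)), 1),
    education = sample(names(scenario$education_probs), n,
      replace = TRUE, prob = scenario$education_probs
    ),
    k = rbeta(n, shp$shape1, shp$shape2)
  )
}

#' Generate synthetic ratings for one scenario
#'
#' Draws respondents (covariates plus latent knowledge `k`) and their item
#' ratings under the latent rating model described in [cohort_scenario()].
#' Output is deterministic given the scenario's seed.
#'
#' @param scenario A [cohort_scenario()].
#' @param instrument A [nova_instrument()].
#' @return An object of class `nova_responses`: a list of tibbles
#'   `ratings` (respondent_id, item_id, rating), `covariates`
#'   (respondent_id, group, sex, age, education) and `truth`
#'   (respondent_id, k). The ratings and covariates tables are valid inputs
#'   for [score_table()] and the validity analyses.
#' @examples
#' resp <- generate_ratings(scenario_nutrition_students(n = 10), default_instrument())
#' score_table(resp)
#' @export
generate_ratings <- function(scenario, instrument = default_instrument()) {
  stopifnot(inherits(scenario, "nova_scenario"), inherits(instrument, "nova_instrument"))
  if (scenario$n == 0) {
    nv_abort("Scenario has n = 0 respondents: nothing to generate.",
      class = "novascore_empty_error"
    )
  }
  withr::with_seed(scenario$seed, {
    resp <- draw_respondents(scenario)
    m <- scenario$group_means
    m_bar <- mean(m)
    items <- instrument$items
    grid <- tidyr::expand_grid(
      resp[, c("respondent_id", "k")],
      items[, c("item_id", "nova_group")]
    )
    mu <- m_bar + grid$k * (m[grid$nova_group] - m_bar)
    raw <- mu + rnorm(nrow(grid), 0, scenario$noise_sd)
    rating <- as.integer(clamp(round(raw), instrument$scale$min, instrument$scale$max))
    ratings <- tibble::tibble(
      respondent_id = grid$respondent_id,
      item_id = grid$item_id,
      rating = rating
    )
    structure(
      list(
        ratings = ratings,
        covariates = resp[, c("respondent_id", "group", "sex", "age", "education")],
        truth = resp[, c("respondent_id", "k")]
      ),
      class = "nova_responses"
    )
  })
}

#' @export
print.nova_responses <- function(x, ...) {
  cat(sprintf(
    "<nova_responses> %d respondents x %d rated items (groups: %s)\n",
    nrow(x$covariates), length(unique(x$ratings$item_id)),
    paste(unique(x$covariates$group), collapse = ", ")
  ))
  invisible(x)
}

#' Generate a labeled two-group study
#'
#' Pools two scenarios (reference and comparison group) into one labeled
#' `nova_responses` object, e.g. for a discriminant-validity analysis. With
#' the calibrated defaults this emulates the nutrition-vs-education student
#' comparison.
#'
#' @param scenario_ref,scenario_cmp Scenarios for the two groups; their
#'   labels must differ so respondent ids cannot collide.
#' @param instrument A [nova_instrument()].
#' @return A `nova_responses` object with both groups.
#' @examples
#' study <- generate_two_group_study(
#'   scenario_nutrition_students(n = 20),
#'   scenario_education_students(n = 20)
#' )
#' table(study$covariates$group)
#' @export
generate_two_group_study <- function(scenario_ref = scenario_nutrition_students(),
                                     scenario_cmp = scenario_education_students(),
                                     instrument = default_instrument()) {
  a <- generate_ratings(scenario_ref, instrument)
  b <- generate_ratings(scenario_cmp, instrument)
  shared <- intersect(a$covariates$respondent_id, b$covariates$respondent_id)
  if (length(shared) > 0) {
    nv_abort(sprintf(
      "Duplicated respondent_id(s) across groups (labels must differ): %s.",
      paste(head(shared, 3), collapse = ", ")
    ))
  }
  structure(
    list(
      ratings = dplyr::bind_rows(a$ratings, b$ratings),
      covariates = dplyr::bind_rows(a$covariates, b$covariates),
      truth = dplyr::bind_rows(a$truth, b$truth)
    ),
    class = "nova_responses"
  )
}

#' Generate repeated 24-hour recalls from knowledge scores
#'
#' Simulates each respondent's true usual UPF intake from their total score
#' under the scenario's [recall_model()], draws how many recalls (1-3) they
#' complete, and emits noisy daily observations. Uses the scenario seed
#' offset by a constant so recall noise is decoupled from the rating stream
#' while remaining deterministic.
#'
#' @param scores A score table (e.g. from [score_table()]) with columns
#'   `respondent_id` and `total`; totals must be non-missing - filter
#'   incomplete respondents first.
#' @param scenario A [cohort_scenario()].
#' @return A tibble (`respondent_id`, `occasion`, `upf_percent`) with the
#'   per-respondent ground truth in attribute `"truth"` (a tibble with
#'   `respondent_id`, `n_recalls`, `usual_true`).
#' @examples
#' scn <- scenario_nutrinet_cohort(n = 30)
#' scores <- score_table(generate_ratings(scn))
#' recalls <- generate_recalls(scores, scn)
#' head(recalls)
#' @export
generate_recalls <- function(scores, scenario) {
  scores <- check_data_frame(scores, "scores")
  check_cols(scores, c("respondent_id", "total"), "scores")
  stopifnot(inherits(scenario, "nova_scenario"))
  if (nrow(scores) == 0) {
    nv_abort("`scores` is empty: nothing to generate.", class = "novascore_empty_error")
  }
  if (anyNA(scores$total)) {
    nv_abort(paste(
      "Some totals are missing: recalls require complete scores.",
      "Filter respondents with incomplete categories first."
    ))
  }
  rm_ <- scenario$recall
  withr::with_seed(scenario$seed + 7919L, {
    n <- nrow(scores)
    n_recalls <- sample(1:3, n, replace = TRUE, prob = rm_$recall_count_probs)
    usual_true <- clamp(
      rm_$intercept + rm_$slope * scores$total + rnorm(n, 0, rm_$sd_between),
      0, 100
    )
    idx <- rep(seq_len(n), n_recalls)
    recalls <- tibble::tibble(
      respondent_id = scores$respondent_id[idx],
      occasion = unlist(lapply(n_recalls, seq_len)),
      upf_percent = clamp(
        usual_true[idx] + rnorm(length(idx), 0, rm_$sd_within),
        0, 100
      )
    )
    attr(recalls, "truth") <- tibble::tibble(
      respondent_id = scores$respondent_id,
      n_recalls = n_recalls,
      usual_true = usual_true
    )
    recalls
  })
}

#' Read or write a scenario definition (JSON)
#'
#' @param path Path to a JSON file.
#' @return `read_scenario()` returns a `nova_scenario`; `write_scenario()`
#'   returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) {
      nv_abort(
        sprintf("Could not parse scenario JSON '%s': %s", path, conditionMessage(e)),
        class = "novascore_parse_error"
      )
    }
  )
  rm_args <- doc$recall
  doc$recall <- NULL
  args <- doc
  args$group_means <- unlist(doc$group_means)
  args$education_probs <- unlist(doc$education_probs)
  args$recall <- do.call(recall_model, as.list(rm_args) |>
    (\(x) {
      x$recall_count_probs <- unlist(x$recall_count_probs)
      x
    })())
  do.call(cohort_scenario, args)
}

#' @rdname read_scenario
#' @param scenario A `nova_scenario` to serialize.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "nova_scenario"))
  doc <- unclass(scenario)
  doc$recall <- unclass(doc$recall)
  doc$group_means <- as.list(doc$group_means)
  doc$education_probs <- as.list(doc$education_probs)
  doc$recall$recall_count_probs <- as.list(doc$recall$recall_count_probs)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
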