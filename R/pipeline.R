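#' Run an end-to-end analysis pipeline
#'
#' Orchestrates the package's stages behind a single configurable entry
#' point, mirroring the command-line interface (see `inst/cli/novascore.R`).
#' Modes:
#'
#' * `score`: read a responses CSV, score it, write `scores.csv`.
#' * `simulate`: generate synthetic data. With `scenario = "two_group"`,
#'   the calibrated two-group study (writes `responses.csv`,
#'   `covariates.csv`, `truth.csv`); with `scenario = "cohort"` or a
#'   scenario JSON path, a recall cohort (additionally writes `scores.csv`,
#'   `recalls.csv`).
#' * `discriminant`: scores + covariates CSVs in, comparability and
#'   Mann-Whitney comparison report out (`discriminant_report.json` / `.txt`).
#' * `convergent`: scores + recalls + covariates CSVs in,
#'   `usual_intake.csv` and a regression report out
#'   (`convergent_report.json` / `.txt`).
#' * `power`: sample-size calculation, written to `power.json`.
#'
#' Every run echoes its configuration to `config_echo.json` and appends a
#' `run_log.txt` with the seed, a configuration hash, and package/R
#' versions. Outputs other than the log contain no timestamps, so reruns
#' with the same configuration and seed are byte-identical.
#'
#' @param config A named list (or path to a JSON file) with fields depending
#'   on mode: `out_dir` (always); `responses`, `responses_format`,
#'   `instrument` (`"default"` or a JSON path), `policy` (list of
#'   [scoring_policy()] arguments) for `score`; `scenario` (`"two_group"`,
#'   `"cohort"`, or a JSON path), `seed`, `n` for `simulate`; `scores`,
#'   `covariates` for `discriminant`; `scores`, `recalls`, `covariates` for
#'   `convergent`; `delta`, `sd1`, `sd2`, `alpha`, `power`, `are` for
#'   `power`.
#' @param mode One of `"score"`, `"simulate"`, `"discriminant"`,
#'   `"convergent"`, `"power"`.
#' @return Invisibly, a named list of the objects produced (also written to
#'   `out_dir`).
#' @export
run_pipeline <- function(config,
                         mode = c("score", "simulate", "discriminant", "convergent", "power")) {
  mode <- match.arg(mode)
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) nv_usage("`config` must be a named list or a JSON path.")
  out_dir <- config$out_dir
  if (is.null(out_dir)) nv_usage("`config$out_dir` is required.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  need <- function(fields) {
    miss <- fields[vapply(fields, function(f) is.null(config[[f]]), logical(1))]
    if (length(miss) > 0) {
      nv_usage(sprintf(
        "Mode '%s' requires config field(s): %s.", mode, paste(miss, collapse = ", ")
      ))
    }
  }
  get_instrument <- function() {
    spec <- config$instrument %||% "default"
    if (identical(spec, "default")) default_instrument() else read_instrument(spec)
  }
  get_policy <- function() do.call(scoring_policy, config$policy %||% list())

  results <- switch(mode,
    score = {
      need("responses")
      inst <- get_instrument()
      responses <- read_responses(config$responses,
        format = config$responses_format %||% "long", instrument = inst
      )
      scores <- score_table(responses,
        instrument = inst, policy = get_policy(),
        verbose = isTRUE(config$verbose)
      )
      write_scores(scores, file.path(out_dir, "scores.csv"))
      list(scores = scores)
    },
    simulate = {
      spec <- config$scenario %||% "cohort"
      seed <- as.integer(config$seed %||% 1L)
      inst <- get_instrument()
      if (identical(spec, "two_group")) {
        study <- generate_two_group_study(
          scenario_nutrition_students(seed = seed),
          scenario_education_students(seed = seed + 1L),
          instrument = inst
        )
        readr::write_csv(study$ratings, file.path(out_dir, "responses.csv"), progress = FALSE)
        readr::write_csv(study$covariates, file.path(out_dir, "covariates.csv"), progress = FALSE)
        readr::write_csv(study$truth, file.path(out_dir, "truth.csv"), progress = FALSE)
        list(study = study)
      } else {
        scn <- if (identical(spec, "cohort")) {
          scenario_nutrinet_cohort(n = as.integer(config$n %||% 1245L), seed = seed)
        } else {
          read_scenario(spec)
        }
        resp <- generate_ratings(scn, inst)
        scores <- score_table(resp, instrument = inst)
        recalls <- generate_recalls(scores[!is.na(scores$total), ], scn)
        truth <- dplyr::left_join(resp$truth, attr(recalls, "truth"), by = "respondent_id")
        readr::write_csv(resp$ratings, file.path(out_dir, "responses.csv"), progress = FALSE)
        readr::write_csv(resp$covariates, file.path(out_dir, "covariates.csv"), progress = FALSE)
        write_scores(scores, file.path(out_dir, "scores.csv"))
        readr::write_csv(recalls, file.path(out_dir, "recalls.csv"), progress = FALSE)
        readr::write_csv(truth, file.path(out_dir, "truth.csv"), progress = FALSE)
        list(responses = resp, scores = scores, recalls = recalls)
      }
    },
    discriminant = {
      need(c("scores", "covariates"))
      scores <- read_csv_dialect(config$scores)
      covs <- read_covariates(config$covariates)
      check_cols(covs, "group", basename(config$covariates))
      joined <- dplyr::inner_join(scores, covs[, c("respondent_id", "group")],
        by = "respondent_id"
      )
      disc <- discriminant_validity(joined, reference = config$reference %||% NULL)
      comp <- group_comparability(covs)
      report <- list(
        comparability = comp,
        groups = disc$groups, n = disc$n,
        comparison = disc$table
      )
      jsonlite::write_json(report, file.path(out_dir, "discriminant_report.json"),
        auto_unbox = TRUE, digits = 10, pretty = TRUE
      )
      writeLines(
        c(
          utils::capture.output(print(disc)),
          "", "Group comparability:", utils::capture.output(print(as.data.frame(comp)))
        ),
        file.path(out_dir, "discriminant_report.txt")
      )
      list(discriminant = disc, comparability = comp)
    },
    convergent = {
      need(c("scores", "recalls", "covariates"))
      scores <- read_csv_dialect(config$scores)
      recalls <- read_recalls(config$recalls)
      covs <- read_covariates(config$covariates)
      usual <- estimate_usual(recalls)
      write_usual_intake(usual, file.path(out_dir, "usual_intake.csv"))
      conv <- convergent_validity(scores, usual, covs)
      jsonlite::write_json(
        list(
          n = conv$n, usual_mean = conv$usual_mean, usual_sd = conv$usual_sd,
          regression = conv$table
        ),
        file.path(out_dir, "convergent_report.json"),
        auto_unbox = TRUE, digits = 10, pretty = TRUE
      )
      writeLines(
        utils::capture.output(print(conv)),
        file.path(out_dir, "convergent_report.txt")
      )
      list(usual = usual, convergent = conv)
    },
    power = {
      need(c("delta", "sd1", "sd2"))
      n <- sample_size_two_groups(
        delta = config$delta, sd1 = config$sd1, sd2 = config$sd2,
        alpha = config$alpha %||% 0.05, power = config$power %||% 0.80,
        nonparametric_are = config$are %||% 0.864
      )
      jsonlite::write_json(
        list(
          n_per_group = n, delta = config$delta, sd1 = config$sd1,
          sd2 = config$sd2, alpha = config$alpha %||% 0.05,
          power = config$power %||% 0.80, are = config$are %||% 0.864
        ),
        file.path(out_dir, "power.json"),
        auto_unbox = TRUE, pretty = TRUE
      )
      inform(sprintf("Required sample size per group: %d", n))
      list(n_per_group = n)
    }
  )

  echo <- config
  echo$mode <- mode
  jsonlite::write_json(echo, file.path(out_dir, "config_echo.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  log_line <- sprintf(
    "[%s] mode=%s seed=%s config_hash=%s novascore=%s R=%s",
    format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), mode,
    config$seed %||% "NA", rlang::hash(echo),
    as.character(utils::packageVersion("novascore")),
    paste(R.version$major, R.version$minor, sep = ".")
  )
  cat(log_line, "\n", file = file.path(out_dir, "run_log.txt"), append = TRUE)
  invisible(results)
}
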