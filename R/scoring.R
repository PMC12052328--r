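#' Scoring policy for the knowledge score
#'
#' The score rewards recovering the Nova healthiness ordering G1 > G3 > G4
#' within a category. Three choices are configurable where the scoring rules
#' leave room:
#'
#' * `tie_policy`: tied ratings never earn points. Under `"pair_incorrect"`
#'   (default) only the tied pair is counted as incorrect, so e.g. ratings
#'   (9, 9, 2) still have two correct pairs and earn 1 point. Under
#'   `"zero_category"` any tie among the three ratings zeroes the category.
#' * `one_pair_policy`: orderings with exactly one correct pairwise
#'   comparison (e.g. G3 > G4 > G1) earn 0 points under `"zero"` (default;
#'   1 point is reserved for exactly-two-correct configurations) or 1 point
#'   under `"one_point"`.
#' * `missing_policy`: with `"total_requires_all"` (default) the total is
#'   reported only when every category is complete, otherwise `NA`. With
#'   `"partial_sum"` the total is the raw sum of points over complete
#'   categories - never prorated or scaled up.
#'
#' @param tie_policy,one_pair_policy,missing_policy See Details.
#' @return An object of class `nova_policy`.
#' @examples
#' scoring_policy()
#' scoring_policy(tie_policy = "zero_category")
#' @export
scoring_policy <- function(tie_policy = c("pair_incorrect", "zero_category"),
                           one_pair_policy = c("zero", "one_point"),
                           missing_policy = c("total_requires_all", "partial_sum")) {
  structure(
    list(
      tie_policy = match.arg(tie_policy),
      one_pair_policy = match.arg(one_pair_policy),
      missing_policy = match.arg(missing_policy)
    ),
    class = "nova_policy"
  )
}

#' @export
print.nova_policy <- function(x, ...) {
  cat(sprintf(
    "<nova_policy> ties: %s | one correct pair: %s | missing: %s\n",
    x$tie_policy, x$one_pair_policy, x$missing_policy
  ))
  invisible(x)
}

# core pairwise evaluator, vectorized, no input validation
score_triads <- function(g1, g3, g4, policy) {
  miss <- is.na(g1) | is.na(g3) | is.na(g4)
  cp <- (g1 > g3) + (g1 > g4) + (g3 > g4)
  pts <- ifelse(cp == 3L, 2L, ifelse(cp == 2L, 1L, 0L))
  if (policy$one_pair_policy == "one_point") {
    pts <- ifelse(!miss & cp == 1L, 1L, pts)
  }
  if (policy$tie_policy == "zero_category") {
    tied <- !miss & (g1 == g3 | g1 == g4 | g3 == g4)
    pts[tied] <- 0L
  }
  tibble::tibble(
    correct_pairs = as.integer(ifelse(miss, NA, cp)),
    points = as.integer(ifelse(miss, NA, pts)),
    complete = !miss
  )
}

validate_ratings <- function(rating, scale_min, scale_max, context = NULL) {
  bad <- which(!is.na(rating) &
    (!is_wholenumber(rating) | rating < scale_min | rating > scale_max))
  if (length(bad) > 0) {
    where <- if (is.null(context)) {
      sprintf("position(s) %s", paste(head(bad, 5), collapse = ", "))
    } else {
      paste(head(context[bad], 5), collapse = "; ")
    }
    nv_abort(sprintf(
      "Invalid rating(s): must be integers in [%d, %d]. Offending: %s.",
      scale_min, scale_max, where
    ))
  }
  invisible(rating)
}

#' Score one category from its three ratings
#'
#' Evaluates the three ordered pairwise comparisons (G1 > G3, G1 > G4,
#' G3 > G4) strictly. All three correct earns 2 points, exactly two correct
#' earns 1 point, otherwise 0 (see [scoring_policy()] for tie and one-pair
#' variants). Any missing rating makes the category incomplete and its points
#' `NA`.
#'
#' @param g1,g3,g4 Ratings given to the G1, G3 and G4 item of a category.
#'   Vectors are scored elementwise.
#' @param policy A [scoring_policy()].
#' @param scale Length-2 rating bounds used for validation (default 1-10).
#' @return A tibble with one row per input triple and columns
#'   `correct_pairs`, `points`, `complete`.
#' @examples
#' score_category(10, 5, 1) # fully correct ordering: 2 points
#' score_category(10, 1, 5) # one pair wrong: 1 point
#' score_category(1, 5, 10) # fully reversed: 0 points
#' score_category(5, 5, 5) # ties earn nothing
#' @export
score_category <- function(g1, g3, g4, policy = scoring_policy(),
                           scale = c(1L, 10L)) {
  stopifnot(inherits(policy, "nova_policy"))
  n <- max(length(g1), length(g3), length(g4))
  g1 <- rep_len(as.numeric(g1), n)
  g3 <- rep_len(as.numeric(g3), n)
  g4 <- rep_len(as.numeric(g4), n)
  for (r in list(g1, g3, g4)) validate_ratings(r, scale[1], scale[2])
  score_triads(g1, g3, g4, policy)
}

#' Score a full table of responses
#'
#' Computes per-category points and the total knowledge score (0 to twice the
#' number of categories; 0-8 for the bundled 12-item instrument) for every
#' respondent in a long-form ratings table.
#'
#' @param responses A data frame with columns `respondent_id`, `item_id`,
#'   `rating` (long form), or a `nova_responses` object from
#'   [generate_ratings()]. Items a respondent did not rate may simply be
#'   absent (or rated `NA`); the affected category is then incomplete.
#' @param instrument A [nova_instrument()]; ratings are validated against its
#'   items and scale.
#' @param policy A [scoring_policy()].
#' @param verbose If `TRUE`, emit a message with the number of respondents
#'   scored and the number with incomplete categories.
#' @return A tibble with one row per respondent, in input order: columns
#'   `respondent_id`, one points column per category, `total`,
#'   `n_complete_categories`. Carries the category names in attribute
#'   `"categories"`.
#' @examples
#' resp <- data.frame(
#'   respondent_id = "r1",
#'   item_id = default_instrument()$items$item_id,
#'   rating = rep(c(9, 6, 3), 4)
#' )
#' score_table(resp)
#' @export
score_table <- function(responses, instrument = default_instrument(),
                        policy = scoring_policy(), verbose = FALSE) {
  if (inherits(responses, "nova_responses")) responses <- responses$ratings
  responses <- check_data_frame(responses, "responses")
  check_cols(responses, c("respondent_id", "item_id", "rating"), "responses")
  if (nrow(responses) == 0) {
    nv_abort("`responses` is empty: nothing to score.", class = "novascore_empty_error")
  }
  stopifnot(inherits(instrument, "nova_instrument"), inherits(policy, "nova_policy"))

  responses <- dplyr::mutate(responses,
    respondent_id = as.character(.data$respondent_id),
    item_id = as.character(.data$item_id)
  )
  unknown <- setdiff(unique(responses$item_id), instrument$items$item_id)
  if (length(unknown) > 0) {
    nv_abort(sprintf(
      "Rating(s) for item_id(s) not in instrument '%s': %s.",
      instrument$name, paste(head(unknown, 5), collapse = ", ")
    ))
  }
  dup <- duplicated(responses[, c("respondent_id", "item_id")])
  if (any(dup)) {
    d <- responses[dup, ]
    nv_abort(sprintf(
      "Duplicate (respondent_id, item_id) pair(s), e.g. (%s, %s).",
      d$respondent_id[1], d$item_id[1]
    ))
  }
  validate_ratings(
    responses$rating, instrument$scale$min, instrument$scale$max,
    context = sprintf(
      "respondent '%s', item '%s' (rating %s)",
      responses$respondent_id, responses$item_id, responses$rating
    )
  )

  resp_order <- unique(responses$respondent_id)
  cats <- instrument_categories(instrument)

  grid <- tidyr::expand_grid(
    respondent_id = resp_order,
    instrument$items[, c("item_id", "category", "nova_group")]
  )
  wide <- grid |>
    dplyr::left_join(responses, by = c("respondent_id", "item_id")) |>
    tidyr::pivot_wider(
      id_cols = c("respondent_id", "category"),
      names_from = "nova_group", values_from = "rating"
    )
  cs <- score_triads(wide$G1, wide$G3, wide$G4, policy)
  wide <- dplyr::bind_cols(wide[, c("respondent_id", "category")], cs)

  totals <- wide |>
    dplyr::group_by(.data$respondent_id) |>
    dplyr::summarise(
      total = if (policy$missing_policy == "total_requires_all") {
        if (all(.data$complete)) sum(.data$points) else NA_integer_
      } else {
        sum(.data$points[.data$complete])
      },
      n_complete_categories = sum(.data$complete),
      .groups = "drop"
    )
  points_wide <- wide |>
    dplyr::select("respondent_id", "category", "points") |>
    tidyr::pivot_wider(names_from = "category", values_from = "points")

  out <- points_wide |>
    dplyr::left_join(totals, by = "respondent_id") |>
    dplyr::arrange(match(.data$respondent_id, resp_order)) |>
    dplyr::select("respondent_id", dplyr::all_of(cats), "total", "n_complete_categories")
  attr(out, "categories") <- cats
  if (verbose) {
    inform(sprintf(
      "Scored %d respondent(s); %d with at least one incomplete category.",
      nrow(out), sum(out$n_complete_categories < length(cats))
    ))
  }
  out
}

#' Score a single respondent
#'
#' Convenience wrapper around [score_table()] for one respondent's ratings.
#'
#' @param ratings A named vector/list mapping `item_id` to rating, or a data
#'   frame with columns `item_id`, `rating`.
#' @param instrument A [nova_instrument()].
#' @param policy A [scoring_policy()].
#' @param respondent_id Identifier used in the returned row.
#' @return A one-row tibble as in [score_table()].
#' @examples
#' inst <- default_instrument()
#' ratings <- setNames(rep(c(9, 6, 3), 4), inst$items$item_id)
#' score_respondent(ratings)
#' @export
score_respondent <- function(ratings, instrument = default_instrument(),
                             policy = scoring_policy(),
                             respondent_id = "respondent") {
  if (is.data.frame(ratings)) {
    check_cols(ratings, c("item_id", "rating"), "ratings")
    df <- tibble::tibble(
      respondent_id = respondent_id,
      item_id = as.character(ratings$item_id),
      rating = as.numeric(ratings$rating)
    )
  } else {
    ratings <- unlist(ratings)
    if (is.null(names(ratings)) || any(names(ratings) == "")) {
      nv_usage("`ratings` must be named by item_id (or be a data frame).")
    }
    df <- tibble::tibble(
      respondent_id = respondent_id,
      item_id = names(ratings),
      rating = as.numeric(ratings)
    )
  }
  score_table(df, instrument = instrument, policy = policy)
}
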