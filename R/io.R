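# CSV I/O. Canonical dialect: comma separator, period decimal mark, UTF-8,
# header row. A "locale" argument converts Brazilian-style semicolon/comma
# files on read; everything written by the package is canonical.

read_csv_dialect <- function(path, locale = c("canonical", "br")) {
  locale <- match.arg(locale)
  if (!file.exists(path)) {
    nv_abort(sprintf("File not found: '%s'.", path), class = "novascore_io_error")
  }
  if (locale == "br") {
    readr::read_delim(path,
      delim = ";", show_col_types = FALSE, progress = FALSE,
      locale = readr::locale(decimal_mark = ",")
    )
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Read a responses CSV
#'
#' Long form (canonical): columns `respondent_id`, `item_id`, `rating`.
#' Wide form: one `respondent_id` column plus one column per item id;
#' converted to long form on read (missing cells become missing ratings).
#' When an instrument is supplied, item ids and rating bounds are validated
#' with row-level error messages.
#'
#' @param path CSV file path.
#' @param format `"long"` (default) or `"wide"`.
#' @param instrument Optional [nova_instrument()] to validate against.
#' @param locale `"canonical"` (comma separator, period decimal) or `"br"`
#'   (semicolon separator, comma decimal).
#' @return A tibble with columns `respondent_id`, `item_id`, `rating`.
#' @export
read_responses <- function(path, format = c("long", "wide"), instrument = NULL,
                           locale = "canonical") {
  format <- match.arg(format)
  df <- read_csv_dialect(path, locale)
  if (format == "long") {
    check_cols(df, c("respondent_id", "item_id", "rating"), basename(path))
    out <- dplyr::mutate(df[, c("respondent_id", "item_id", "rating")],
      respondent_id = as.character(.data$respondent_id),
      item_id = as.character(.data$item_id),
      rating = as.numeric(.data$rating)
    )
  } else {
    check_cols(df, "respondent_id", basename(path))
    out <- df |>
      dplyr::mutate(respondent_id = as.character(.data$respondent_id)) |>
      tidyr::pivot_longer(-"respondent_id",
        names_to = "item_id", values_to = "rating",
        values_transform = as.numeric
      ) |>
      dplyr::filter(!is.na(.data$rating))
  }
  dup <- duplicated(out[, c("respondent_id", "item_id")])
  if (any(dup)) {
    d <- out[dup, ][1, ]
    nv_abort(sprintf(
      "Duplicate (respondent_id, item_id) pair in '%s': (%s, %s).",
      basename(path), d$respondent_id, d$item_id
    ))
  }
  if (!is.null(instrument)) {
    stopifnot(inherits(instrument, "nova_instrument"))
    unknown <- setdiff(unique(out$item_id), instrument$items$item_id)
    if (length(unknown) > 0) {
      nv_abort(sprintf(
        "'%s' contains item_id(s) not in instrument '%s': %s.",
        basename(path), instrument$name, paste(head(unknown, 5), collapse = ", ")
      ))
    }
    bad <- which(!is.na(out$rating) &
      (!is_wholenumber(out$rating) |
        out$rating < instrument$scale$min | out$rating > instrument$scale$max))
    if (length(bad) > 0) {
      i <- bad[1]
      nv_abort(sprintf(
        "Invalid rating in '%s' row %d (respondent '%s', item '%s'): %s is not an integer in [%d, %d].",
        basename(path), i, out$respondent_id[i], out$item_id[i],
        format(out$rating[i]), instrument$scale$min, instrument$scale$max
      ))
    }
  }
  out
}

#' Read a covariates CSV
#'
#' @param path CSV with columns `respondent_id`, `sex`, `age`, `education`
#'   and optionally `group`.
#' @param locale See [read_responses()].
#' @return A tibble.
#' @export
read_covariates <- function(path, locale = "canonical") {
  df <- read_csv_dialect(path, locale)
  check_cols(df, c("respondent_id", "sex", "age", "education"), basename(path))
  if (anyDuplicated(df$respondent_id)) {
    nv_abort(sprintf("Duplicate respondent_id in '%s'.", basename(path)))
  }
  dplyr::mutate(df,
    respondent_id = as.character(.data$respondent_id),
    age = as.numeric(.data$age)
  )
}

#' Read a recalls CSV
#'
#' @param path CSV with columns `respondent_id`, `occasion`, `upf_percent`
#'   (% of energy from ultra-processed food, in \[0, 100\]).
#' @param locale See [read_responses()].
#' @return A tibble.
#' @export
read_recalls <- function(path, locale = "canonical") {
  df <- read_csv_dialect(path, locale)
  check_cols(df, c("respondent_id", "occasion", "upf_percent"), basename(path))
  df <- dplyr::mutate(df,
    respondent_id = as.character(.data$respondent_id),
    occasion = as.integer(.data$occasion),
    upf_percent = as.numeric(.data$upf_percent)
  )
  bad <- which(is.na(df$upf_percent) | df$upf_percent < 0 | df$upf_percent > 100)
  if (length(bad) > 0) {
    nv_abort(sprintf(
      "Invalid upf_percent in '%s' row %d: values must lie in [0, 100].",
      basename(path), bad[1]
    ))
  }
  if (anyDuplicated(df[, c("respondent_id", "occasion")])) {
    nv_abort(sprintf("Duplicate (respondent_id, occasion) in '%s'.", basename(path)))
  }
  df
}

#' Write package tables as canonical CSV
#'
#' Thin wrappers over [readr::write_csv()] with a fixed, deterministic
#' column order.
#'
#' @param x The table to write (scores, usual-intake estimates, or any
#'   tibble).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
write_usual_intake <- function(x, path) {
  check_cols(
    x, c("respondent_id", "n_recalls", "person_mean", "shrinkage_lambda", "usual_estimate"),
    "x"
  )
  readr::write_csv(
    x[, c("respondent_id", "n_recalls", "person_mean", "shrinkage_lambda", "usual_estimate")],
    path,
    progress = FALSE
  )
  invisible(path)
}
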