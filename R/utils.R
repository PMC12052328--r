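# internal helpers; error classes distinguish user-data problems
# ("novascore_validation_error") from API misuse ("novascore_usage_error")

nv_abort <- function(message, class = "novascore_validation_error", ...) {
  rlang::abort(message = message, class = c(class, "novascore_error"), ...)
}

nv_usage <- function(message, ...) {
  nv_abort(message, class = "novascore_usage_error", ...)
}

check_data_frame <- function(x, arg) {
  if (!is.data.frame(x)) {
    nv_usage(sprintf("`%s` must be a data frame, not %s.", arg, class(x)[1]))
  }
  tibble::as_tibble(x)
}

check_cols <- function(df, cols, arg) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    nv_abort(sprintf(
      "`%s` is missing required column(s): %s. Expected header: %s.",
      arg, paste(missing, collapse = ", "), paste(cols, collapse = ", ")
    ))
  }
  invisible(df)
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# Beta shape parameters from mean/sd; sd must be compatible with (0,1) support
beta_shapes <- function(mean, sd, arg = "k") {
  if (mean <= 0 || mean >= 1) {
    nv_usage(sprintf("`%s_mean` must lie strictly in (0, 1).", arg))
  }
  if (sd <= 0) nv_usage(sprintf("`%s_sd` must be positive.", arg))
  nu <- mean * (1 - mean) / sd^2 - 1
  if (nu <= 0) {
    nv_usage(sprintf(
      "`%s_sd` = %.3f is too large for mean %.3f on the (0, 1) scale.",
      arg, sd, mean
    ))
  }
  list(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

is_wholenumber <- function(x, tol = 1e-8) {
  !is.na(x) & is.finite(x) & abs(x - round(x)) < tol
}

`%||%` <- rlang::`%||%`
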