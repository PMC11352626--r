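# Internal validation helpers shared across modules.

stop_cp <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "cureplateau_error"), ...)
}

check_fraction_0_100 <- function(x, what = "percent_positive") {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 100)) {
    stop_cp(
      sprintf("`%s` must be numeric within [0, 100].", what),
      "cureplateau_validation_error"
    )
  }
  invisible(x)
}

check_positive_times <- function(x, what = "time") {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_cp(
      sprintf("`%s` must be strictly positive and finite.", what),
      "cureplateau_validation_error"
    )
  }
  invisible(x)
}

check_nonempty <- function(df, what = "cohort") {
  if (!is.data.frame(df) || nrow(df) == 0L) {
    stop_cp(
      sprintf("`%s` must be a data frame with at least one row.", what),
      "cureplateau_empty_cohort_error"
    )
  }
  invisible(df)
}

check_columns <- function(df, cols, what = "data") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_cp(
      sprintf(
        "`%s` is missing required column(s): %s.",
        what, paste(missing, collapse = ", ")
      ),
      "cureplateau_validation_error"
    )
  }
  invisible(df)
}

round1 <- function(x) round(x, 1)
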