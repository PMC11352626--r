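# Right-censored survival records and Kaplan-Meier estimation. The
# product-limit estimate itself is delegated to survival::survfit; this
# module provides the tabular surface the plateau model fits against.

endpoint_columns <- function(endpoint) {
  endpoint <- toupper(endpoint)
  switch(endpoint,
    OS  = list(time = "os_time_months", event = "os_event"),
    PFS = list(time = "pfs_time_months", event = "pfs_event"),
    stop_cp("`endpoint` must be 'OS' or 'PFS'.",
            "cureplateau_validation_error")
  )
}

validate_records <- function(records) {
  check_nonempty(records, "records")
  check_columns(records,
                c("os_time_months", "os_event", "pfs_time_months",
                  "pfs_event"),
                "records")
  check_positive_times(records$os_time_months, "os_time_months")
  check_positive_times(records$pfs_time_months, "pfs_time_months")
  if (any(records$pfs_time_months > records$os_time_months + 1e-9)) {
    stop_cp("`pfs_time_months` must not exceed `os_time_months`.",
            "cureplateau_validation_error")
  }
  invisible(records)
}

#' Kaplan-Meier curve for a cohort endpoint
#'
#' Product-limit estimate of the survival function for overall survival
#' (time to death) or progression-free survival (time to relapse,
#' progression or death, whichever comes first). One row is returned per
#' distinct event time; censored-only times shrink the risk set but add
#' no step. Events at a tied time precede censorings (the standard
#' convention). Times are in months.
#'
#' @param records Data frame with one row per patient and columns
#'   `os_time_months`, `os_event`, `pfs_time_months`, `pfs_event`
#'   (times positive, events logical/0-1).
#' @param endpoint `"OS"` or `"PFS"`.
#' @return A tibble of class `km_curve` with columns `time`, `survival`,
#'   `n_risk`, `n_event` at the distinct event times. The implied value
#'   at time zero is 1. The cohort size is carried in attribute
#'   `n_subjects`, the endpoint in `endpoint`.
#' @examples
#' rec <- tibble::tibble(
#'   os_time_months = 1:4, os_event = TRUE,
#'   pfs_time_months = 1:4, pfs_event = TRUE
#' )
#' km_curve(rec, "OS")
#' @export
km_curve <- function(records, endpoint = c("OS", "PFS")) {
  endpoint <- toupper(match.arg(toupper(endpoint[1L]), c("OS", "PFS")))
  validate_records(records)
  cols <- endpoint_columns(endpoint)
  time <- records[[cols$time]]
  event <- as.logical(records[[cols$event]])
  if (anyNA(event)) {
    stop_cp("Event indicators must be logical (or 0/1) without NA.",
            "cureplateau_validation_error")
  }
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1,
    conf.type = "none"
  )
  keep <- fit$n.event > 0
  out <- tibble(
    time = fit$time[keep],
    survival = fit$surv[keep],
    n_risk = as.integer(fit$n.risk[keep]),
    n_event = as.integer(fit$n.event[keep])
  )
  attr(out, "n_subjects") <- nrow(records)
  attr(out, "endpoint") <- endpoint
  class(out) <- c("km_curve", class(out))
  out
}

#' Follow-up summary
#'
#' Median and range of the observed follow-up times of all subjects,
#' regardless of event status.
#'
#' @inheritParams km_curve
#' @return A one-row tibble with columns `median`, `min`, `max` (months).
#' @export
follow_up_summary <- function(records) {
  check_nonempty(records, "records")
  check_columns(records, "os_time_months", "records")
  check_positive_times(records$os_time_months, "os_time_months")
  t <- records$os_time_months
  tibble(median = median(t), min = min(t), max = max(t))
}

#' @exportS3Method ggplot2::autoplot
autoplot.km_curve <- function(object, ...) {
  endpoint <- attr(object, "endpoint") %||% "survival"
  steps <- if (nrow(object) == 0L) {
    tibble(time = 0, survival = 1)
  } else {
    tibble(
      time = c(0, rep(object$time, each = 2)),
      survival = c(1, 1, rep(object$survival, each = 2)[-(2 * nrow(object))])
    )
  }
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  title = paste("Kaplan-Meier estimate,", endpoint)) +
    ggplot2::theme_minimal()
}
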