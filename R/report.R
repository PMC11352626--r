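# Orchestration: cohort summary table, the end-to-end analysis pipeline
# (IHC scoring -> marker calls -> KM -> single-marker and combined-group
# stratification tests -> plateau support -> optional enrichment), and
# report serialisation.

#' Summarise a cohort's categorical characteristics
#'
#' Counts and percentages per categorical variable (percentages use the
#' variable's non-missing denominator, 1 decimal place), plus the
#' median and interquartile range of `age` when present.
#'
#' @param records Cohort data frame.
#' @param variables Character vector of columns to tabulate; defaults to
#'   every character, factor or logical column except identifiers and
#'   event flags.
#' @return A tibble of class `cohort_summary` with columns `variable`,
#'   `level`, `n`, `pct`; attributes `n_total`, `age_median`,
#'   `age_iqr`.
#' @export
summarize_cohort <- function(records, variables = NULL) {
  check_nonempty(records, "records")
  if (is.null(variables)) {
    is_cat <- vapply(records, function(x) {
      is.character(x) || is.factor(x) || is.logical(x)
    }, logical(1L))
    variables <- setdiff(names(records)[is_cat],
                         c("sample_id", "os_event", "pfs_event", "cell"))
  }
  check_columns(records, variables, "records")
  rows <- purrr::map_dfr(variables, function(v) {
    x <- records[[v]]
    x <- x[!is.na(x)]
    tab <- table(as.character(x))
    tibble(
      variable = v,
      level = names(tab),
      n = as.integer(tab),
      pct = round1(100 * as.integer(tab) / length(x))
    )
  })
  attr(rows, "n_total") <- nrow(records)
  if ("age" %in% names(records)) {
    age <- records$age[!is.na(records$age)]
    attr(rows, "age_median") <- median(age)
    attr(rows, "age_iqr") <- unname(quantile(age, c(0.25, 0.75)))
  }
  class(rows) <- c("cohort_summary", class(rows))
  rows
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary (n = %d)\n", attr(x, "n_total")))
  if (!is.null(attr(x, "age_median"))) {
    iqr <- attr(x, "age_iqr")
    cat(sprintf("  age: median %.0f, IQR %.0f to %.0f\n",
                attr(x, "age_median"), iqr[1L], iqr[2L]))
  }
  for (v in unique(x$variable)) {
    cat(" ", v, "\n")
    sub <- x[x$variable == v, ]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("    %-20s %3d, %.1f%%\n",
                  sub$level[i], sub$n[i], sub$pct[i]))
    }
  }
  invisible(x)
}

# Merge IHC-derived marker calls into the survival records.
apply_marker_calls <- function(records, calls) {
  wide <- calls |>
    dplyr::transmute(
      sample_id = .data$sample_id,
      col = paste0(tolower(.data$marker), "_positive"),
      positive = .data$positive
    ) |>
    tidyr::pivot_wider(names_from = "col", values_from = "positive")
  records <- records[setdiff(names(records),
                             c("satb1_positive", "p16_positive"))]
  dplyr::left_join(as_tibble(records), wide, by = "sample_id")
}

#' Ask whether a group's survival plateau is supported
#'
#' Fits the decay-to-plateau model and its no-plateau rival (plateau
#' pinned at zero) to one group's Kaplan-Meier curve and reports
#' `delta_aic = AIC(no plateau) - AIC(with plateau)`: positive values
#' support the existence of a plateau.
#'
#' @param curve A [km_curve()] result.
#' @param config A [fit_config()].
#' @return A one-row tibble with `delta_aic`, `evidence_ratio`,
#'   `er_label`, `f`, `p`, and the two fits as list-columns.
#' @export
plateau_support <- function(curve, config = fit_config()) {
  config$plateau_mode <- "free"
  with_p <- fit_plateau(curve, config)
  no_p <- fit_exponential_to_zero(curve, config)
  delta <- no_p$aic - with_p$aic
  er <- evidence_ratio(delta)
  ftest <- extra_ss_f_test(
    max(no_p$rss, with_p$rss), no_p$n_points - no_p$n_free,
    with_p$rss, with_p$n_points - with_p$n_free
  )
  tibble(
    delta_aic = delta,
    evidence_ratio = er$magnitude,
    er_direction = er$direction,
    er_label = er$label,
    f = ftest$f, p = ftest$p,
    fit_plateau = list(with_p),
    fit_no_plateau = list(no_p)
  )
}

#' Run the full prognostic-analysis pipeline
#'
#' Sequences the package's stages: score raw IHC measurements into
#' marker calls (when supplied), summarise the cohort, estimate pooled
#' Kaplan-Meier curves, test single-marker stratification per endpoint,
#' test the combined-marker grouping (with small-group merging), assess
#' plateau support for any group whose fitted plateau sits at a bound,
#' and optionally correlate gene-set enrichment scores with a
#' transcript. Stage failures are caught and logged as warnings rather
#' than aborting the later stages.
#'
#' @param records Cohort data frame (see [km_curve()]); marker columns
#'   may be supplied directly or derived from `measurements`.
#' @param measurements Optional raw IHC measurement data frame for
#'   [call_markers()].
#' @param markers Markers to analyse (default `c("satb1", "p16")`).
#' @param min_group_size Minimum combined-group size before merging.
#' @param config A [fit_config()].
#' @param expression Optional genes x samples matrix.
#' @param gene_sets Optional gene sets ([read_gmt()] tibble or named
#'   list).
#' @param transcript Optional gene identifier whose expression is
#'   regressed (RMA) against each signature score.
#' @param alpha ssGSEA weighting exponent.
#' @param seed Seed recorded in the report (the pipeline itself is
#'   deterministic given its inputs).
#' @return A list of class `cp_report`.
#' @export
run_pipeline <- function(records, measurements = NULL,
                         markers = c("satb1", "p16"),
                         min_group_size = 10L,
                         config = fit_config(),
                         expression = NULL, gene_sets = NULL,
                         transcript = NULL, alpha = 0.75,
                         seed = NULL) {
  warnings <- character()
  note <- function(msg) warnings <<- c(warnings, msg)

  calls <- NULL
  if (!is.null(measurements)) {
    calls <- call_markers(measurements)
    records <- apply_marker_calls(records, calls)
  }
  validate_records(records)

  summary <- summarize_cohort(records)
  follow_up <- follow_up_summary(records)
  km <- list(OS = km_curve(records, "OS"), PFS = km_curve(records, "PFS"))

  # markers actually present with both levels
  usable <- markers[vapply(markers, function(m) {
    col <- paste0(tolower(m), "_positive")
    col %in% names(records) &&
      dplyr::n_distinct(records[[col]]) == 2L
  }, logical(1L))]
  for (m in setdiff(markers, usable)) {
    note(sprintf("marker '%s' has a single level; dropped from stratification",
                 m))
  }

  single <- list()
  for (m in usable) {
    for (ep in c("OS", "PFS")) {
      key <- paste(m, ep, sep = "_")
      single[[key]] <- tryCatch({
        g <- assign_groups(records, m, min_group_size = 1L)
        compare_stratification(records, ep, g, config)
      }, error = function(e) {
        note(sprintf("single-marker comparison %s failed: %s",
                     key, conditionMessage(e)))
        NULL
      })
    }
  }

  combined <- list()
  if (length(usable) >= 2L) {
    for (ep in c("OS", "PFS")) {
      combined[[ep]] <- tryCatch({
        g <- assign_groups(records, usable, min_group_size = min_group_size)
        compare_stratification(records, ep, g, config)
      }, error = function(e) {
        note(sprintf("combined comparison (%s) failed: %s", ep,
                     conditionMessage(e)))
        NULL
      })
    }
  } else if (length(usable) == 1L) {
    note(sprintf("combined analysis degraded to single marker '%s'",
                 usable[[1L]]))
  }

  # plateau support for groups whose plateau sits at a bound
  support <- list()
  for (ep in names(combined)) {
    cmp <- combined[[ep]]
    if (is.null(cmp)) next
    for (g in names(cmp$strat_fits)) {
      f <- cmp$strat_fits[[g]]
      if (isTRUE(f$at_boundary)) {
        grp_ids <- dplyr::filter(
          assign_groups(records, usable, min_group_size = min_group_size)$assignment,
          .data$group == g
        )$sample_id
        curve <- km_curve(
          dplyr::filter(as_tibble(records), .data$sample_id %in% grp_ids),
          ep
        )
        support[[paste(ep, g, sep = "_")]] <- tryCatch(
          plateau_support(curve, config),
          error = function(e) {
            note(sprintf("plateau support (%s, %s) failed: %s", ep, g,
                         conditionMessage(e)))
            NULL
          }
        )
      }
    }
  }

  enrichment <- NULL
  if (!is.null(expression) && !is.null(gene_sets) &&
      !is.null(transcript)) {
    enrichment <- tryCatch({
      scores <- score_matrix(expression, gene_sets, alpha = alpha)
      driver <- expression[transcript, colnames(expression)]
      scores |>
        dplyr::group_by(.data$set_name) |>
        dplyr::group_modify(function(df, key) {
          rma_regression(df$es[match(colnames(expression), df$sample_id)],
                         driver)
        }) |>
        dplyr::ungroup()
    }, error = function(e) {
      note(sprintf("enrichment stage failed: %s", conditionMessage(e)))
      NULL
    })
  }

  structure(
    list(
      seed = seed,
      config = config,
      n = nrow(records),
      marker_calls = calls,
      summary = summary,
      follow_up = follow_up,
      km = km,
      single_marker = single,
      combined = combined,
      plateau_support = support,
      enrichment = enrichment,
      warnings = warnings
    ),
    class = "cp_report"
  )
}

#' @export
print.cp_report <- function(x, ...) {
  cat(sprintf("Prognostic analysis report (n = %d)\n", x$n))
  cat(sprintf("  follow-up: median %.1f mo, range %.1f-%.1f\n",
              x$follow_up$median, x$follow_up$min, x$follow_up$max))
  for (key in names(x$single_marker)) {
    cmp <- x$single_marker[[key]]
    if (is.null(cmp)) next
    er_txt <- if (grepl("^ER", cmp$er_label)) cmp$er_label else
      paste0("ER = ", cmp$er_label)
    cat(sprintf("  %-12s dAIC = %8.2f  %s  p = %.3g\n",
                key, cmp$delta_aic, er_txt, cmp$f_p))
  }
  for (ep in names(x$combined)) {
    cmp <- x$combined[[ep]]
    if (is.null(cmp)) next
    er_txt <- if (grepl("^ER", cmp$er_label)) cmp$er_label else
      paste0("ER = ", cmp$er_label)
    cat(sprintf("  combined %-3s dAIC = %8.2f  %s  p = %.3g  (%d groups)\n",
                ep, cmp$delta_aic, er_txt, cmp$f_p,
                length(cmp$group_sizes)))
  }
  if (length(x$warnings) > 0L) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}

report_to_list <- function(x) {
  cmp_list <- function(cmp) {
    if (is.null(cmp)) return(NULL)
    g <- glance(cmp)
    list(
      delta_aic = g$delta_aic,
      evidence_ratio = g$evidence_ratio,
      er_direction = g$er_direction,
      er_label = g$er_label,
      f = g$f_stat, p = g$f_p,
      n_points = g$n_points,
      groups = tidy(cmp)
    )
  }
  list(
    seed = x$seed,
    n = x$n,
    follow_up = as.list(x$follow_up),
    summary = as.data.frame(x$summary),
    single_marker = lapply(x$single_marker, cmp_list),
    combined = lapply(x$combined, cmp_list),
    plateau_support = lapply(x$plateau_support, function(s) {
      if (is.null(s)) return(NULL)
      as.list(s[c("delta_aic", "evidence_ratio", "er_label", "f", "p")])
    }),
    enrichment = if (!is.null(x$enrichment)) as.data.frame(x$enrichment),
    warnings = x$warnings
  )
}

#' Write a pipeline report to disk
#'
#' Serialises the report as JSON, the summary and per-group estimates as
#' CSV, and (when an SVG device is available) Kaplan-Meier overlay
#' figures as SVG.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @param plots Attempt SVG figures (default TRUE).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir, plots = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    report_to_list(report),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  readr::write_csv(as_tibble(report$summary),
                   file.path(dir, "cohort_summary.csv"))
  for (ep in names(report$combined)) {
    cmp <- report$combined[[ep]]
    if (is.null(cmp)) next
    readr::write_csv(tidy(cmp),
                     file.path(dir, sprintf("combined_%s_groups.csv", ep)))
    if (plots && capabilities("cairo")) {
      grDevices::svg(file.path(dir, sprintf("combined_%s.svg", ep)),
                     width = 7, height = 5)
      print(autoplot(cmp))
      grDevices::dev.off()
    }
  }
  invisible(dir)
}
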