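# Null-versus-stratified model comparison: one decay-to-plateau curve for
# the whole cohort against one curve per marker-defined subpopulation,
# judged by Delta-AIC, the evidence ratio exp(|dAIC|/2), and the
# extra-sum-of-squares F test. Includes marker cross-classification with
# small-group merging and the pairwise shared-dynamics test.

display_marker <- function(m) {
  ifelse(tolower(m) == "satb1", "SATB1",
         ifelse(tolower(m) == "p16", "p16", m))
}

#' Cross-classify a cohort by marker positivity, merging small groups
#'
#' Builds the joint marker grouping (e.g. SATB1+/p16-, SATB1+/p16+, ...).
#' Any group smaller than `min_group_size` is merged with the groups
#' sharing its rightmost positive marker, producing a pooled
#' `"<marker>+"` group; merge provenance is recorded. A small group with
#' no positive marker, or with no partner to merge into, raises an
#' unmergeable-grouping error.
#'
#' @param records Data frame with `sample_id` and a logical
#'   `<marker>_positive` column per marker.
#' @param markers Character vector of marker names, e.g.
#'   `c("satb1", "p16")`; merge priority is right-to-left.
#' @param min_group_size Groups at least this large are kept as is
#'   (default 10); `1` disables merging.
#' @return An object of class `cp_grouping`: `assignment` (tibble
#'   `sample_id`, `group`), `labels`, `sizes`, `merged_from`.
#' @export
assign_groups <- function(records, markers = c("satb1", "p16"),
                          min_group_size = 10L) {
  check_nonempty(records, "records")
  check_columns(records, "sample_id", "records")
  cols <- paste0(tolower(markers), "_positive")
  check_columns(records, cols, "records")
  if (min_group_size < 1L) {
    stop_cp("`min_group_size` must be >= 1.", "cureplateau_validation_error")
  }
  disp <- display_marker(markers)
  pos <- vapply(cols, function(cc) as.logical(records[[cc]]),
                logical(nrow(records)))
  pos <- matrix(pos, nrow = nrow(records))
  if (anyNA(pos)) {
    stop_cp("Marker positivity columns must be logical without NA.",
            "cureplateau_validation_error")
  }
  group <- apply(pos, 1L, function(p) {
    paste0(disp, ifelse(p, "+", "-"), collapse = "/")
  })
  merged_from <- list()

  for (iter in seq_len(length(markers) + 2L)) {
    sizes <- table(group)
    small <- names(sizes)[sizes < min_group_size]
    if (length(small) == 0L) break
    progress <- FALSE
    # merge the smallest group first
    small <- small[order(sizes[small])]
    for (g in small) {
      rows <- which(group == g)
      all_pos <- apply(pos[rows, , drop = FALSE], 2L, all)
      if (!any(all_pos)) next
      j <- max(which(all_pos))
      # partner groups: every member positive for marker j
      grp_all_pos <- vapply(
        split(seq_along(group), group),
        function(r) all(pos[r, j]), logical(1L)
      )
      partners <- names(grp_all_pos)[grp_all_pos]
      if (length(partners) < 2L) next
      new_label <- paste0(disp[j], "+")
      prior <- unlist(merged_from[partners], use.names = FALSE)
      merged_from[partners] <- NULL
      merged_from[[new_label]] <- unique(c(setdiff(partners, new_label),
                                           prior))
      group[group %in% partners] <- new_label
      progress <- TRUE
      break
    }
    if (!progress) {
      stop_cp(
        sprintf("Cannot merge group(s) below min_group_size = %d: %s.",
                min_group_size, paste(small, collapse = ", ")),
        "cureplateau_unmergeable_grouping_error"
      )
    }
  }
  sizes <- table(group)
  if (any(sizes < min_group_size)) {
    stop_cp(
      sprintf("Grouping still has group(s) below min_group_size = %d: %s.",
              min_group_size,
              paste(names(sizes)[sizes < min_group_size], collapse = ", ")),
      "cureplateau_unmergeable_grouping_error"
    )
  }
  structure(
    list(
      assignment = tibble(sample_id = as.character(records$sample_id),
                          group = group),
      labels = names(sizes),
      sizes = as.integer(sizes) |> setNames(names(sizes)),
      merged_from = merged_from,
      min_group_size = as.integer(min_group_size),
      markers = markers
    ),
    class = "cp_grouping"
  )
}

#' @export
print.cp_grouping <- function(x, ...) {
  cat("Marker grouping (min group size", x$min_group_size, "):\n")
  for (g in x$labels) {
    extra <- if (!is.null(x$merged_from[[g]])) {
      paste0(" [merged from ", paste(x$merged_from[[g]], collapse = ", "), "]")
    } else ""
    cat(sprintf("  %-16s n = %d%s\n", g, x$sizes[[g]], extra))
  }
  invisible(x)
}

#' Global fit across groups: shared or separate parameters
#'
#' Fits the decay-to-plateau model over the union of the per-group
#' Kaplan-Meier point sets. With `shared = TRUE`, one parameter set must
#' describe all groups (the null model); with `shared = FALSE` each group
#' gets its own parameters and the residual sums of squares add. Both
#' models are evaluated on the identical point set, so their AICs are
#' comparable. `AIC = N log(RSS/N) + 2K` where `K` counts free curve
#' parameters plus one for the error variance.
#'
#' @param curves Named list of [km_curve()] results, one per group.
#' @param shared Logical: one curve for everyone, or one per group.
#' @param config A [fit_config()].
#' @return A list with `rss`, `n`, `k_free`, `aic`, `aicc`, and (when
#'   `shared = FALSE`) the per-group `fits`, or (when `shared = TRUE`)
#'   the shared `fit` parameters.
#' @export
global_fit <- function(curves, shared = FALSE, config = fit_config()) {
  if (!is.list(curves) || length(curves) < 1L) {
    stop_cp("`curves` must be a non-empty named list of KM curves.",
            "cureplateau_validation_error")
  }
  n_free_1 <- (config$plateau_mode == "free") + 1L +
    (config$s0_mode == "free")
  pts <- lapply(curves, fit_points, config = config)
  for (g in names(curves)) {
    # zero-event curves are admitted as degenerate no-decay fits when the
    # intercept is fixed; otherwise a group must support at least an
    # exact fit of its free parameters
    if (length(pts[[g]]$t) < n_free_1 &&
        !(nrow(curves[[g]]) == 0L && config$s0_mode == "fixed")) {
      stop_cp(
        sprintf("Group '%s' has too few fitted points (%d) for %d parameters.",
                g, length(pts[[g]]$t), n_free_1),
        "cureplateau_insufficient_data_error"
      )
    }
  }
  n <- sum(vapply(pts, function(p) length(p$t), integer(1L)))

  if (shared) {
    t_all <- unlist(lapply(pts, `[[`, "t"), use.names = FALSE)
    s_all <- unlist(lapply(pts, `[[`, "s"), use.names = FALSE)
    core <- ls_fit_core(t_all, s_all, config)
    rss <- core$rss
    k_free <- n_free_1
    fits <- NULL
    par <- core$par
  } else {
    fits <- lapply(curves, fit_plateau, config = config)
    rss <- sum(vapply(fits, `[[`, numeric(1L), "rss"))
    k_free <- n_free_1 * length(curves)
    par <- NULL
  }
  k_aic <- k_free + 1L
  aic <- if (rss > 0) n * log(rss / n) + 2 * k_aic else -Inf
  aicc <- if (n - k_aic - 1 > 0 && is.finite(aic)) {
    aic + 2 * k_aic * (k_aic + 1) / (n - k_aic - 1)
  } else NA_real_
  list(
    rss = rss, n = n, k_free = k_free,
    aic = if (config$aic == "aicc") aicc else aic,
    aic_plain = aic, aicc = aicc,
    fits = fits, par = par
  )
}

#' Evidence ratio from an AIC difference
#'
#' The evidence ratio `exp(|dAIC|/2)` quantifies how many times more
#' likely the better model is; the sign of `delta_aic` gives the
#' direction. Here `delta_aic = AIC(null) - AIC(stratified)`, so positive
#' values favour stratification.
#'
#' @param delta_aic Finite AIC difference.
#' @return A one-row tibble with `magnitude` (>= 1), `direction`
#'   (`"favors_stratified"`, `"favors_null"` or `"equivocal"`), and a
#'   rendered `label` (`"ER > 100"`, reciprocal `"1/x"` when the null is
#'   favoured, else the magnitude to 2 decimals).
#' @examples
#' evidence_ratio(-9.672)  # magnitude 126, favours the null: "1/126"
#' evidence_ratio(0.03)    # magnitude 1.02, essentially equivocal
#' @export
evidence_ratio <- function(delta_aic) {
  if (length(delta_aic) != 1L || !is.finite(delta_aic)) {
    stop_cp("`delta_aic` must be a single finite number.",
            "cureplateau_validation_error")
  }
  magnitude <- exp(abs(delta_aic) / 2)
  direction <- if (delta_aic > 0) {
    "favors_stratified"
  } else if (delta_aic < 0) {
    "favors_null"
  } else {
    "equivocal"
  }
  tibble(
    magnitude = magnitude,
    direction = direction,
    label = format_evidence_ratio(magnitude, direction)
  )
}

#' Render an evidence ratio the way survival reports print it
#'
#' Magnitudes of 100 or more are reported as `"ER > 100"`; when the null
#' is favoured the ratio is shown as the reciprocal `"1/x"` with `x`
#' rounded to the nearest integer; otherwise to two decimals.
#'
#' @param magnitude Evidence-ratio magnitude (>= 1).
#' @param direction `"favors_stratified"`, `"favors_null"` or
#'   `"equivocal"`.
#' @return Character scalar.
#' @export
format_evidence_ratio <- function(magnitude, direction) {
  if (direction == "favors_null") {
    sprintf("1/%.0f", round(magnitude))
  } else {
    if (magnitude >= 100) "ER > 100" else sprintf("%.2f", magnitude)
  }
}

#' Extra-sum-of-squares F test for nested least-squares models
#'
#' `F = ((RSS_null - RSS_strat)/(df_null - df_strat)) /
#' (RSS_strat/df_strat)` with a p-value from the F distribution on
#' `(df_null - df_strat, df_strat)` degrees of freedom. Degrees of
#' freedom count fitted Kaplan-Meier points minus free parameters; since
#' KM points are serially correlated the p-value is approximate.
#'
#' @param rss_null,rss_strat Residual sums of squares of the nested
#'   (null) and the richer (stratified) model; `rss_null >= rss_strat`.
#' @param df_null,df_strat Residual degrees of freedom,
#'   `df_null > df_strat > 0`.
#' @return A one-row tibble with `f`, `p`, `df1`, `df2`.
#' @examples
#' extra_ss_f_test(20, 18, 10, 16)  # F = 8
#' @export
extra_ss_f_test <- function(rss_null, df_null, rss_strat, df_strat) {
  if (df_strat <= 0 || df_null <= df_strat) {
    stop_cp("Require df_null > df_strat > 0.",
            "cureplateau_validation_error")
  }
  if (rss_null < rss_strat - 1e-10 * max(1, rss_strat)) {
    stop_cp("Require rss_null >= rss_strat (models are nested).",
            "cureplateau_validation_error")
  }
  rss_null <- max(rss_null, rss_strat)
  df1 <- df_null - df_strat
  df2 <- df_strat
  if (rss_strat == 0) {
    f <- if (rss_null > 0) Inf else 0
  } else {
    f <- ((rss_null - rss_strat) / df1) / (rss_strat / df2)
  }
  tibble(f = f, p = pf(f, df1, df2, lower.tail = FALSE),
         df1 = df1, df2 = df2)
}

# Shared machinery behind compare_stratification / test_shared_dynamics:
# takes named per-group record subsets, runs the two rival global fits
# (least-squares on KM points, or censored-data likelihood), assembles
# the comparison object. For the likelihood route the null model's
# likelihood factorises, so it equals the pooled-cohort fit; the test is
# a likelihood ratio on 2(g - 1) degrees of freedom.
compare_curve_sets <- function(records_by_group, endpoint, config) {
  if (config$loss == "mle") {
    cols <- endpoint_columns(endpoint)
    tm <- lapply(records_by_group, function(df) {
      list(time = df[[cols$time]], event = as.logical(df[[cols$event]]))
    })
    group_fits <- lapply(tm, function(x) mle_fit_group(x$time, x$event))
    pooled <- mle_fit_group(
      unlist(lapply(tm, `[[`, "time"), use.names = FALSE),
      unlist(lapply(tm, `[[`, "event"), use.names = FALSE)
    )
    n <- pooled$n
    k_null <- 2L
    k_strat <- 2L * length(tm)
    ll_null <- pooled$loglik
    ll_strat <- sum(vapply(group_fits, `[[`, numeric(1L), "loglik"))
    aic_null <- -2 * ll_null + 2 * k_null
    aic_strat <- -2 * ll_strat + 2 * k_strat
    delta_aic <- aic_null - aic_strat
    er <- evidence_ratio(delta_aic)
    lr <- max(0, 2 * (ll_strat - ll_null))
    p <- stats::pchisq(lr, df = k_strat - k_null, lower.tail = FALSE)
    strat_fits <- lapply(group_fits, mle_as_plateau_fit, config = config,
                         endpoint = endpoint)
    return(structure(
      list(
        null_fit = list(rss = NA_real_, n = n, k_free = k_null,
                        aic = aic_null, loglik = ll_null,
                        par = c(plateau = pooled$plateau,
                                tau = pooled$tau)),
        strat_fits = strat_fits,
        group_sizes = vapply(records_by_group, nrow, integer(1L)),
        endpoint = endpoint,
        delta_aic = delta_aic,
        evidence_ratio = er$magnitude,
        er_direction = er$direction,
        er_label = er$label,
        test = "lrt",
        f_stat = lr,
        f_p = p,
        n_points = n,
        df_null = n - k_null,
        df_strat = n - k_strat,
        config = config
      ),
      class = "model_comparison"
    ))
  }
  curves <- lapply(records_by_group, km_curve, endpoint = endpoint)
  null_fit <- global_fit(curves, shared = TRUE, config = config)
  strat_fit <- global_fit(curves, shared = FALSE, config = config)
  # nesting can only be violated by optimizer noise; clamp
  rss_null <- max(null_fit$rss, strat_fit$rss)
  delta_aic <- null_fit$aic - strat_fit$aic
  er <- evidence_ratio(delta_aic)
  df_null <- null_fit$n - null_fit$k_free
  df_strat <- strat_fit$n - strat_fit$k_free
  ftest <- extra_ss_f_test(rss_null, df_null, strat_fit$rss, df_strat)
  structure(
    list(
      null_fit = null_fit,
      strat_fits = strat_fit$fits,
      group_sizes = vapply(records_by_group, nrow, integer(1L)),
      endpoint = endpoint,
      delta_aic = delta_aic,
      evidence_ratio = er$magnitude,
      er_direction = er$direction,
      er_label = er$label,
      test = "extra_ss_f",
      f_stat = ftest$f,
      f_p = ftest$p,
      n_points = null_fit$n,
      df_null = df_null,
      df_strat = df_strat,
      config = config
    ),
    class = "model_comparison"
  )
}

#' Compare a pooled survival model against a marker-stratified one
#'
#' Fits the decay-to-plateau model twice over the per-group Kaplan-Meier
#' point sets — once with shared parameters (null: a single survival
#' curve describes every subpopulation) and once with per-group
#' parameters — and reports `delta_aic = AIC(null) - AIC(stratified)`,
#' the evidence ratio, and the extra-sum-of-squares F test. Per-group
#' fits are retained so half-lives and plateaus can be reported.
#'
#' @inheritParams km_curve
#' @param grouping An [assign_groups()] result.
#' @param config A [fit_config()].
#' @return An object of class `model_comparison`; see [tidy()] /
#'   [glance()] methods.
#' @export
compare_stratification <- function(records, endpoint = c("OS", "PFS"),
                                   grouping, config = fit_config()) {
  endpoint <- toupper(match.arg(toupper(endpoint[1L]), c("OS", "PFS")))
  validate_records(records)
  check_columns(records, "sample_id", "records")
  if (!inherits(grouping, "cp_grouping")) {
    stop_cp("`grouping` must come from assign_groups().",
            "cureplateau_validation_error")
  }
  merged <- dplyr::inner_join(
    as_tibble(records),
    grouping$assignment,
    by = "sample_id"
  )
  if (nrow(merged) != nrow(records)) {
    stop_cp("Grouping does not cover every cohort member exactly once.",
            "cureplateau_validation_error")
  }
  by_group <- split(merged, merged$group)
  if (length(by_group) < 2L) {
    stop_cp("Comparison needs at least two groups.",
            "cureplateau_validation_error")
  }
  compare_curve_sets(by_group, endpoint, config)
}

#' Test whether two subpopulations share the same survival dynamics
#'
#' Compares "one decay-to-plateau curve for A and B together" against
#' "separate curves for A and B" with the same AIC / evidence-ratio / F
#' machinery as [compare_stratification()]. Used, e.g., to ask whether a
#' double-negative group and a pooled marker-positive group can be
#' collapsed.
#'
#' @inheritParams km_curve
#' @param group_a,group_b Disjoint character vectors of `sample_id`s.
#' @param config A [fit_config()].
#' @return A `model_comparison` with groups `"A"` and `"B"`.
#' @export
test_shared_dynamics <- function(records, endpoint = c("OS", "PFS"),
                                 group_a, group_b,
                                 config = fit_config()) {
  endpoint <- toupper(match.arg(toupper(endpoint[1L]), c("OS", "PFS")))
  validate_records(records)
  check_columns(records, "sample_id", "records")
  if (length(intersect(group_a, group_b)) > 0L) {
    stop_cp("`group_a` and `group_b` must be disjoint.",
            "cureplateau_validation_error")
  }
  recs <- as_tibble(records)
  sub <- list(
    A = dplyr::filter(recs, .data$sample_id %in% group_a),
    B = dplyr::filter(recs, .data$sample_id %in% group_b)
  )
  if (nrow(sub$A) == 0L || nrow(sub$B) == 0L) {
    stop_cp("Both groups must contain at least one cohort member.",
            "cureplateau_validation_error")
  }
  compare_curve_sets(sub, endpoint, config)
}

#' Association between a marker call and a categorical covariate
#'
#' Cross-tabulates the marker against the covariate and tests
#' independence: Fisher's exact test for 2x2 tables, the chi-square test
#' for larger ones. A constant covariate yields a degenerate-table
#' warning and `p = 1`.
#'
#' @param records Data frame.
#' @param marker Name of the logical marker column (e.g.
#'   `"satb1_positive"`).
#' @param covariate Name of the categorical covariate column.
#' @return A list with the contingency `table`, the `p` value and the
#'   `test` used.
#' @export
covariate_association <- function(records, marker, covariate) {
  check_nonempty(records, "records")
  check_columns(records, c(marker, covariate), "records")
  x <- factor(records[[marker]])
  y <- factor(records[[covariate]])
  keep <- !is.na(x) & !is.na(y)
  tab <- table(marker = x[keep], covariate = y[keep])
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    rlang::warn("Degenerate contingency table (a variable is constant); p set to 1.")
    return(list(table = tab, p = 1, test = "degenerate"))
  }
  if (nrow(tab) == 2L && ncol(tab) == 2L) {
    list(table = tab, p = fisher.test(tab)$p.value, test = "fisher")
  } else {
    list(table = tab,
         p = suppressWarnings(chisq.test(tab))$p.value,
         test = "chisq")
  }
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Null vs stratified survival model (%s, %d groups)\n",
              x$endpoint, length(x$group_sizes)))
  er_txt <- if (grepl("^ER", x$er_label)) x$er_label else
    paste0("ER = ", x$er_label)
  cat(sprintf("  dAIC = %.3f (%s), %s\n", x$delta_aic,
              x$er_direction, er_txt))
  cat(sprintf("  F = %.3f on (%d, %d) df, p = %.4g\n",
              x$f_stat, x$df_null - x$df_strat, x$df_strat, x$f_p))
  for (g in names(x$strat_fits)) {
    f <- x$strat_fits[[g]]
    cat(sprintf(
      "  %-16s n = %3d  plateau %.1f%% ± %.1f  half-life %.1f ± %.1f mo\n",
      g, x$group_sizes[[g]], 100 * f$plateau, 100 * f$se[["plateau"]],
      f$half_life, f$se[["half_life"]]
    ))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.model_comparison <- function(x, ...) {
  purrr::map2_dfr(
    x$strat_fits, names(x$strat_fits),
    function(f, g) {
      tibble(
        group = g,
        n = x$group_sizes[[g]],
        plateau = f$plateau,
        plateau_se = f$se[["plateau"]],
        half_life = f$half_life,
        half_life_se = f$se[["half_life"]],
        k = f$k,
        rss = f$rss
      )
    }
  )
}

#' @exportS3Method generics::glance
glance.model_comparison <- function(x, ...) {
  tibble(
    endpoint = x$endpoint,
    n_groups = length(x$group_sizes),
    n_points = x$n_points,
    delta_aic = x$delta_aic,
    evidence_ratio = x$evidence_ratio,
    er_direction = x$er_direction,
    er_label = x$er_label,
    test = x$test,
    f_stat = x$f_stat,
    f_p = x$f_p,
    df_null = x$df_null,
    df_strat = x$df_strat
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.model_comparison <- function(object, ...) {
  steps <- purrr::map2_dfr(
    object$strat_fits, names(object$strat_fits),
    function(f, g) {
      pts <- f$points
      grid <- tibble(time = seq(0, max(pts$time), length.out = 150))
      grid$fitted <- plateau_survival(grid$time, f$s0, f$plateau, f$k)
      dplyr::bind_rows(
        dplyr::mutate(pts, group = g, kind = "km"),
        dplyr::mutate(grid, group = g, kind = "fit")
      )
    }
  )
  ggplot2::ggplot(mapping = ggplot2::aes(colour = .data$group)) +
    ggplot2::geom_step(
      data = dplyr::filter(steps, .data$kind == "km"),
      ggplot2::aes(x = .data$time, y = .data$survival)
    ) +
    ggplot2::geom_line(
      data = dplyr::filter(steps, .data$kind == "fit"),
      ggplot2::aes(x = .data$time, y = .data$fitted),
      linetype = "dashed"
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  title = sprintf(
                    "Stratified decay-to-plateau fits (%s), dAIC = %.1f",
                    object$endpoint, object$delta_aic
                  )) +
    ggplot2::theme_minimal()
}
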