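# Semi-quantitative IHC scoring: staining-intensity points, percent-positive
# points, the multiplicative immunoreactive score (IRS) for SATB1, and the
# four-tier percent-positivity score for p16, plus binary marker calls.

#' Staining-intensity categories recognised by the scoring functions
#' @format Character vector of the four intensity levels, weakest first.
#' @export
intensity_levels <- c("negative", "weak", "moderate", "strong")

#' Score staining intensity
#'
#' Maps the four-level staining-intensity category to its point value:
#' negative = 0, weak (pale yellow) = 1, moderate (yellow-brown) = 2,
#' strong (dark brown) = 3.
#'
#' @param intensity Character vector of intensity categories
#'   (see [intensity_levels]).
#' @return Integer vector of scores in 0--3.
#' @examples
#' staining_intensity_score(c("negative", "strong"))
#' @export
staining_intensity_score <- function(intensity) {
  idx <- match(intensity, intensity_levels)
  if (anyNA(idx)) {
    bad <- unique(intensity[is.na(idx)])
    stop_cp(
      sprintf(
        "Unknown staining-intensity category: %s. Expected one of %s.",
        paste(bad, collapse = ", "), paste(intensity_levels, collapse = ", ")
      ),
      "cureplateau_category_error"
    )
  }
  as.integer(idx - 1L)
}

#' Name the intensity category for a staining-intensity score
#'
#' Inverse of [staining_intensity_score()].
#'
#' @param score Integer vector of scores in 0--3.
#' @return Character vector of categories.
#' @export
intensity_category <- function(score) {
  if (any(!score %in% 0:3)) {
    stop_cp("Staining-intensity scores must lie in 0..3.",
            "cureplateau_validation_error")
  }
  intensity_levels[score + 1L]
}

#' Score the percentage of positive HRS cells (SATB1 convention)
#'
#' Piecewise-constant mapping of percent-positive Hodgkin/Reed-Sternberg
#' cells to points: below 10% scores 1 point, 10--50% scores 2 points,
#' above 50% scores 3 points. Bins are closed on the left, so exactly 50
#' scores 2 and anything above 50 scores 3.
#'
#' @param percent_positive Numeric vector in \[0, 100\].
#' @return Integer vector of scores in 1--3.
#' @examples
#' percent_positive_score(c(5, 50, 50.1))
#' @export
percent_positive_score <- function(percent_positive) {
  check_fraction_0_100(percent_positive)
  ifelse(percent_positive < 10, 1L, ifelse(percent_positive <= 50, 2L, 3L))
}

#' SATB1 immunoreactive score and positivity call
#'
#' The immunoreactive score (IRS) is the product of the staining-intensity
#' score (0--3) and the percent-positive score (1--3). A product of 1 or
#' lower is called negative; a product above 1 is called positive.
#'
#' @param si_score Integer vector in 0--3.
#' @param pp_score Integer vector in 1--3.
#' @return A tibble with columns `si_score`, `pp_score`, `irs`, `positive`.
#' @examples
#' satb1_irs_call(si_score = 1, pp_score = 1)  # IRS 1, negative
#' satb1_irs_call(si_score = 3, pp_score = 3)  # IRS 9, positive
#' @export
satb1_irs_call <- function(si_score, pp_score) {
  if (any(!si_score %in% 0:3)) {
    stop_cp("`si_score` must lie in 0..3.", "cureplateau_validation_error")
  }
  if (any(!pp_score %in% 1:3)) {
    stop_cp("`pp_score` must lie in 1..3.", "cureplateau_validation_error")
  }
  irs <- as.integer(si_score) * as.integer(pp_score)
  tibble(
    si_score = as.integer(si_score),
    pp_score = as.integer(pp_score),
    irs = irs,
    positive = irs > 1L
  )
}

#' p16 percent-positivity tier
#'
#' Four-tier score for p16 staining: tier 0 (negative) below 10% positive
#' HRS cells, tier 1 (low) for 10--29%, tier 2 (moderate) for 30--59%,
#' tier 3 (high) for 60% and above.
#'
#' @inheritParams percent_positive_score
#' @return Integer vector of tiers in 0--3.
#' @examples
#' p16_tier(c(9.9, 30, 60))
#' @export
p16_tier <- function(percent_positive) {
  check_fraction_0_100(percent_positive)
  as.integer(cut(percent_positive,
                 breaks = c(-Inf, 10, 30, 60, Inf),
                 right = FALSE, labels = FALSE)) - 1L
}

#' p16 binary positivity from the tier score
#'
#' Default cut: any tier of 1 or above (at least 10% positive HRS cells)
#' is positive; tier 0 is negative. The cut is configurable.
#'
#' @param tier Integer vector of tiers in 0--3.
#' @param min_positive_tier Lowest tier called positive (default 1).
#' @return Logical vector.
#' @export
p16_positive <- function(tier, min_positive_tier = 1L) {
  if (any(!tier %in% 0:3)) {
    stop_cp("`tier` must lie in 0..3.", "cureplateau_validation_error")
  }
  tier >= min_positive_tier
}

#' Score a cohort of raw IHC measurements
#'
#' Takes one row per (sample, marker) measurement with the raw
#' staining-intensity category and the percentage of positive HRS cells,
#' and derives the marker-appropriate scores and the binary call:
#' SATB1 uses the multiplicative immunoreactive score, p16 the four-tier
#' percent-positivity score.
#'
#' @param measurements Data frame with columns `sample_id`, `marker`
#'   (`"SATB1"` or `"P16"`, case-insensitive), `intensity`
#'   (see [intensity_levels]) and `percent_positive` (0--100).
#' @param p16_min_positive_tier Lowest p16 tier called positive.
#' @return A tibble with one row per measurement and columns `sample_id`,
#'   `marker`, `si_score`, `pp_score`, `irs`, `tier`, `positive`.
#'   `pp_score` and `irs` are `NA` for p16; `tier` is `NA` for SATB1.
#' @examples
#' m <- tibble::tibble(
#'   sample_id = c("a", "a"), marker = c("SATB1", "P16"),
#'   intensity = c("moderate", "weak"), percent_positive = c(40, 5)
#' )
#' call_markers(m)
#' @export
call_markers <- function(measurements, p16_min_positive_tier = 1L) {
  if (!is.data.frame(measurements)) {
    stop_cp("`measurements` must be a data frame.",
            "cureplateau_validation_error")
  }
  out_cols <- c("sample_id", "marker", "si_score", "pp_score", "irs",
                "tier", "positive")
  if (nrow(measurements) == 0L) {
    return(tibble(
      sample_id = character(), marker = character(),
      si_score = integer(), pp_score = integer(), irs = integer(),
      tier = integer(), positive = logical()
    ))
  }
  check_columns(measurements,
                c("sample_id", "marker", "intensity", "percent_positive"),
                "measurements")
  marker <- toupper(as.character(measurements$marker))
  if (any(!marker %in% c("SATB1", "P16"))) {
    stop_cp("`marker` must be 'SATB1' or 'P16'.",
            "cureplateau_category_error")
  }
  key <- paste(measurements$sample_id, marker, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- measurements$sample_id[duplicated(key)][1L]
    stop_cp(
      sprintf("Duplicate (sample_id, marker) pair: sample '%s'.", dup),
      "cureplateau_duplicate_key_error"
    )
  }
  check_fraction_0_100(measurements$percent_positive)

  si <- staining_intensity_score(as.character(measurements$intensity))
  is_satb1 <- marker == "SATB1"
  pp <- ifelse(is_satb1, percent_positive_score(measurements$percent_positive),
               NA_integer_)
  irs <- ifelse(is_satb1, si * pp, NA_integer_)
  tier <- ifelse(is_satb1, NA_integer_,
                 p16_tier(measurements$percent_positive))
  positive <- ifelse(is_satb1, irs > 1L, tier >= p16_min_positive_tier)

  tibble(
    sample_id = as.character(measurements$sample_id),
    marker = marker,
    si_score = as.integer(si),
    pp_score = as.integer(pp),
    irs = as.integer(irs),
    tier = as.integer(tier),
    positive = as.logical(positive)
  )
}
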