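# Seeded synthetic data: a cure-fraction cohort generator that is the
# exact inverse of the decay-to-plateau model (plateau = cure
# probability, exponential event hazard among the non-cured, uniform
# accrual censoring), plus an expression-matrix generator with planted
# gene-set signatures tied to a driver transcript.

default_marker_cells <- function() {
  tibble(
    cell = c("S+P-", "S+P+", "S-P+", "S-P-"),
    satb1 = c(TRUE, TRUE, FALSE, FALSE),
    p16 = c(FALSE, TRUE, TRUE, FALSE),
    fraction = c(12, 8, 4, 62) / 86,
    os_plateau = c(0.907, 0.75, 0.75, 0.60),
    os_half_life = c(4.5, 1.4, 1.4, 83.6),
    pfs_plateau = c(0.87, 0.67, 0.67, 0.60),
    pfs_half_life = c(14.5, 0.97, 0.97, 31.1)
  )
}

default_covariates <- function() {
  list(
    sex = c(female = 47, male = 39) / 86,
    histology = c(nodular_sclerosis = 60, mixed_cellularity = 20,
                  other = 6) / 86,
    stage = c(I = 9, II = 42, III = 16, IV = 19) / 86,
    b_symptoms = c(yes = 54, no = 32) / 86,
    bulky = c(yes = 15, no = 71) / 86,
    extranodal = c(yes = 15, no = 71) / 86,
    ecog = c(`0` = 64, `1` = 18, `2` = 4) / 86
  )
}

#' Specification of a synthetic cure-fraction cohort
#'
#' The defaults describe a cohort with the structure of a retrospective
#' Hodgkin-lymphoma series: 86 patients, joint marker split
#' 12/8/4/62 over SATB1+/p16-, SATB1+/p16+, SATB1-/p16+, SATB1-/p16-,
#' per-cell cure fractions (survival plateaus) and event half-lives
#' taken from the fitted stratified survival curves, uniform accrual
#' censoring over 1--197 months of follow-up, and Table-1-style
#' covariate frequencies independent of the markers.
#'
#' @param n Cohort size.
#' @param cells Data frame with one row per joint marker cell: `cell`,
#'   logical `satb1` and `p16`, `fraction` (sums to 1), `os_plateau`,
#'   `os_half_life`, `pfs_plateau`, `pfs_half_life` (plateaus are cure
#'   probabilities in \[0, 1\], half-lives in months; progression
#'   precedes or coincides with death, so `pfs_plateau <= os_plateau`).
#' @param censor_min,censor_max Uniform accrual-censoring window
#'   (months).
#' @param covariates Named list of categorical covariate distributions
#'   (named probability vectors).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 86L,
                        cells = default_marker_cells(),
                        censor_min = 1,
                        censor_max = 197,
                        covariates = default_covariates()) {
  problems <- character()
  if (n < 1L) problems <- c(problems, "n must be >= 1")
  if (abs(sum(cells$fraction) - 1) > 1e-8) {
    problems <- c(problems, "cell fractions must sum to 1")
  }
  for (col in c("os_plateau", "pfs_plateau")) {
    if (any(cells[[col]] < 0 | cells[[col]] > 1)) {
      problems <- c(problems, sprintf("%s must lie in [0, 1]", col))
    }
  }
  for (col in c("os_half_life", "pfs_half_life")) {
    if (any(cells[[col]] <= 0)) {
      problems <- c(problems, sprintf("%s must be > 0", col))
    }
  }
  if (any(cells$pfs_plateau > cells$os_plateau + 1e-9)) {
    problems <- c(problems,
                  "pfs_plateau must not exceed os_plateau (death is a PFS event)")
  }
  if (censor_min <= 0 || censor_max <= censor_min) {
    problems <- c(problems, "need 0 < censor_min < censor_max")
  }
  cov_ok <- vapply(covariates,
                   function(p) abs(sum(p) - 1) < 1e-8 && all(p >= 0),
                   logical(1L))
  if (!all(cov_ok)) {
    problems <- c(problems,
                  sprintf("covariate distribution(s) not a probability vector: %s",
                          paste(names(covariates)[!cov_ok], collapse = ", ")))
  }
  if (length(problems) > 0L) {
    stop_cp(paste0("Invalid cohort spec:\n- ",
                   paste(problems, collapse = "\n- ")),
            "cureplateau_validation_error")
  }
  structure(
    list(n = as.integer(n), cells = as_tibble(cells),
         censor_min = censor_min, censor_max = censor_max,
         covariates = covariates),
    class = "cohort_spec"
  )
}

sample_satb1_measurement <- function(positive) {
  pairs_pos <- expand.grid(si = 0:3, pp = 1:3)
  pairs_pos <- pairs_pos[pairs_pos$si * pairs_pos$pp > 1, ]
  pairs_neg <- expand.grid(si = 0:3, pp = 1:3)
  pairs_neg <- pairs_neg[pairs_neg$si * pairs_neg$pp <= 1, ]
  n <- length(positive)
  si <- integer(n); pp <- integer(n)
  idx_pos <- sample.int(nrow(pairs_pos), n, replace = TRUE)
  idx_neg <- sample.int(nrow(pairs_neg), n, replace = TRUE)
  si <- ifelse(positive, pairs_pos$si[idx_pos], pairs_neg$si[idx_neg])
  pp <- ifelse(positive, pairs_pos$pp[idx_pos], pairs_neg$pp[idx_neg])
  lo <- c(0, 10, 50.5)[pp]
  hi <- c(9.9, 50, 100)[pp]
  tibble(
    intensity = intensity_category(si),
    percent_positive = runif(n, lo, hi)
  )
}

sample_p16_measurement <- function(positive) {
  n <- length(positive)
  tier <- ifelse(positive, sample(1:3, n, replace = TRUE), 0L)
  lo <- c(0, 10, 30, 60)[tier + 1L]
  hi <- c(9.9, 29.9, 59.9, 100)[tier + 1L]
  pct <- runif(n, lo, hi)
  intensity <- ifelse(
    positive,
    sample(c("weak", "moderate", "strong"), n, replace = TRUE),
    sample(c("negative", "weak"), n, replace = TRUE)
  )
  tibble(intensity = intensity, percent_positive = pct)
}

#' Simulate a cure-fraction cohort
#'
#' Per subject: a joint marker cell is drawn from the spec's fractions;
#' a shared uniform latent decides cure status for both endpoints (being
#' progression-free forever implies surviving forever, so the PFS cure
#' indicator nests inside the OS one); non-cured subjects draw an
#' exponential death time with rate `ln 2 / os_half_life` and an
#' exponential relapse time with rate `ln 2 / pfs_half_life`; the PFS
#' event is the earlier of relapse and death; censoring is uniform over
#' the accrual window; observed times are the minimum of event and
#' censoring times. Raw IHC fields are sampled consistently with each
#' marker call, and covariates are drawn independently of the markers.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return A list of class `synthetic_cohort` with `records` (one row
#'   per patient), `measurements` (two IHC rows per patient) and `truth`
#'   (the generating spec and seed).
#' @examples
#' sc <- simulate_cohort(cohort_spec(n = 40), seed = 1)
#' head(sc$records)
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  if (!inherits(spec, "cohort_spec")) {
    stop_cp("`spec` must come from cohort_spec().",
            "cureplateau_validation_error")
  }
  set.seed(seed)
  n <- spec$n
  cells <- spec$cells
  cell_idx <- sample.int(nrow(cells), n, replace = TRUE,
                         prob = cells$fraction)

  u <- runif(n)
  os_cured <- u < cells$os_plateau[cell_idx]
  pfs_cured <- u < cells$pfs_plateau[cell_idx]  # nested: pfs <= os plateau

  death <- ifelse(os_cured, Inf,
                  rexp(n, rate = log(2) / cells$os_half_life[cell_idx]))
  relapse <- ifelse(pfs_cured, Inf,
                    rexp(n, rate = log(2) / cells$pfs_half_life[cell_idx]))
  pfs_latent <- pmin(relapse, death)

  censor <- runif(n, spec$censor_min, spec$censor_max)
  os_time <- pmin(death, censor)
  os_event <- death <= censor
  pfs_time <- pmin(pfs_latent, censor)
  pfs_event <- pfs_latent <= censor

  covs <- lapply(spec$covariates, function(p) {
    sample(names(p), n, replace = TRUE, prob = p)
  })
  age <- round(pmin(pmax(rnorm(n, mean = 42, sd = 16), 18), 86))

  records <- tibble(
    sample_id = sprintf("pt%03d", seq_len(n)),
    os_time_months = os_time,
    os_event = os_event,
    pfs_time_months = pfs_time,
    pfs_event = pfs_event,
    satb1_positive = cells$satb1[cell_idx],
    p16_positive = cells$p16[cell_idx],
    cell = cells$cell[cell_idx],
    age = age
  )
  for (nm in names(covs)) records[[nm]] <- covs[[nm]]

  m_satb1 <- sample_satb1_measurement(records$satb1_positive)
  m_p16 <- sample_p16_measurement(records$p16_positive)
  measurements <- bind_rows(
    tibble(sample_id = records$sample_id, marker = "SATB1",
           intensity = m_satb1$intensity,
           percent_positive = m_satb1$percent_positive),
    tibble(sample_id = records$sample_id, marker = "P16",
           intensity = m_p16$intensity,
           percent_positive = m_p16$percent_positive)
  ) |> arrange(.data$sample_id, .data$marker)

  structure(
    list(records = records, measurements = measurements,
         truth = list(spec = spec, seed = seed)),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cure-fraction cohort: n = %d (seed %s)\n",
    nrow(x$records), format(x$truth$seed)
  ))
  print(table(x$records$cell))
  invisible(x)
}

#' Simulate an expression matrix with planted gene-set signatures
#'
#' Background genes are independent standard-normal noise. For each
#' planted signature, the driver gene's expression and a latent factor
#' are jointly drawn so they correlate at approximately `target_r`; the
#' member genes of the planted set load on that latent factor (plus
#' gene-level noise), so a rank-based set score recovers a correlation
#' with the driver near `target_r`.
#'
#' @param n_genes Number of background genes in the universe
#'   (`g0001`, `g0002`, ...); drivers and set members must be among
#'   them.
#' @param samples Character vector of sample names (or an integer
#'   count).
#' @param planted List of `list(gene_set = <character>, driver_gene =
#'   <character>, target_r = <number in (-1, 1)>)`. Planted member sets
#'   must not overlap each other, contain their driver, or share a
#'   driver.
#' @param noise_sd Gene-level noise standard deviation around the latent
#'   factor for planted members.
#' @param seed Integer seed.
#' @return Numeric matrix, genes x samples, with dimnames.
#' @export
simulate_expression <- function(n_genes = 500L, samples = 8L,
                                planted = list(), noise_sd = 0.5,
                                seed = 1L) {
  if (is.numeric(samples) && length(samples) == 1L) {
    samples <- sprintf("s%02d", seq_len(samples))
  }
  genes <- sprintf("g%04d", seq_len(n_genes))
  drivers <- vapply(planted, `[[`, character(1L), "driver_gene")
  if (anyDuplicated(drivers)) {
    stop_cp("Planted signatures must not share a driver gene.",
            "cureplateau_validation_error")
  }
  members <- lapply(planted, `[[`, "gene_set")
  all_members <- unlist(members, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    stop_cp("Planted gene sets must not overlap.",
            "cureplateau_validation_error")
  }
  for (p in planted) {
    if (!all(c(p$gene_set, p$driver_gene) %in% genes)) {
      stop_cp("Planted genes must lie within the gene universe.",
              "cureplateau_validation_error")
    }
    if (p$driver_gene %in% p$gene_set) {
      stop_cp("A driver gene must not be a member of its planted set.",
              "cureplateau_validation_error")
    }
    if (abs(p$target_r) >= 1) {
      stop_cp("`target_r` must satisfy |target_r| < 1.",
              "cureplateau_validation_error")
    }
  }
  set.seed(seed)
  ns <- length(samples)
  mat <- matrix(rnorm(n_genes * ns), nrow = n_genes,
                dimnames = list(genes, samples))
  for (p in planted) {
    d <- rnorm(ns)
    latent <- p$target_r * scale(d)[, 1L] +
      sqrt(1 - p$target_r^2) * rnorm(ns)
    mat[p$driver_gene, ] <- d
    for (g in p$gene_set) {
      mat[g, ] <- latent + rnorm(ns, sd = noise_sd)
    }
  }
  mat
}
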