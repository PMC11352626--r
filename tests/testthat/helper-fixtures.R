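# Shared fixtures built in code.

# minimal single-group spec for survival simulations
one_group_spec <- function(n, plateau, half_life,
                           pfs_plateau = plateau,
                           pfs_half_life = half_life,
                           censor_max = 197) {
  cohort_spec(
    n = n,
    cells = tibble::tibble(
      cell = "g", satb1 = TRUE, p16 = FALSE, fraction = 1,
      os_plateau = plateau, os_half_life = half_life,
      pfs_plateau = pfs_plateau, pfs_half_life = pfs_half_life
    ),
    censor_min = 1, censor_max = censor_max
  )
}

# two marker-defined groups (SATB1 +/-) with their own survival laws
two_group_spec <- function(n, frac_pos, plateau_pos, hl_pos,
                           plateau_neg, hl_neg, censor_max = 197) {
  cohort_spec(
    n = n,
    cells = tibble::tibble(
      cell = c("pos", "neg"),
      satb1 = c(TRUE, FALSE), p16 = FALSE,
      fraction = c(frac_pos, 1 - frac_pos),
      os_plateau = c(plateau_pos, plateau_neg),
      os_half_life = c(hl_pos, hl_neg),
      pfs_plateau = c(plateau_pos, plateau_neg),
      pfs_half_life = c(hl_pos, hl_neg)
    ),
    censor_min = 1, censor_max = censor_max
  )
}

# cohort records with explicit times/events and no marker structure
records_from_times <- function(time, event) {
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_along(time)),
    os_time_months = time, os_event = event,
    pfs_time_months = time, pfs_event = event,
    satb1_positive = FALSE, p16_positive = FALSE
  )
}

# empirical survival function at distinct event times (no censoring):
# the independent oracle for the product-limit estimate
empirical_survival <- function(time) {
  tt <- sort(unique(time))
  surv <- vapply(tt, function(x) mean(time > x), numeric(1))
  tibble::tibble(time = tt, survival = surv)
}

# brute-force ssGSEA walk: plain loops, no vectorised tricks
ssgsea_bruteforce <- function(expr, genes, alpha) {
  r <- rank(expr, ties.method = "average")
  ord <- order(-r, names(expr))
  es <- 0
  cum_in <- 0
  cum_out <- 0
  total_in <- sum((abs(r)^alpha)[names(expr) %in% genes])
  n_out <- sum(!names(expr) %in% genes)
  for (g in names(expr)[ord]) {
    if (g %in% genes) {
      cum_in <- cum_in + abs(r[[g]])^alpha
    } else {
      cum_out <- cum_out + 1
    }
    es <- es + (cum_in / total_in - cum_out / n_out)
  }
  es
}

# Fisher exact p for a 2x2 table by hypergeometric enumeration
fisher_bruteforce <- function(tab) {
  m <- sum(tab[1, ]); n_ <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(support, m, n_, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
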