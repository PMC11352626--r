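make_marker_records <- function(counts, seed = 1) {
  # counts in order S+P-, S+P+, S-P+, S-P-
  pat <- rbind(c(TRUE, FALSE), c(TRUE, TRUE), c(FALSE, TRUE),
               c(FALSE, FALSE))
  idx <- rep(1:4, counts)
  set.seed(seed)
  n <- length(idx)
  t <- round(runif(n, 1, 100), 1)
  tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n)),
    os_time_months = t, os_event = runif(n) < 0.5,
    pfs_time_months = t, pfs_event = runif(n) < 0.5,
    satb1_positive = pat[idx, 1], p16_positive = pat[idx, 2]
  )
}

test_that("small joint-marker groups merge into the pooled positive group", {
  rec <- make_marker_records(c(12, 8, 4, 62))
  g <- assign_groups(rec, c("satb1", "p16"), min_group_size = 10)
  expect_setequal(g$labels, c("SATB1+/p16-", "p16+", "SATB1-/p16-"))
  expect_identical(g$sizes[["p16+"]], 12L)
  expect_identical(g$sizes[["SATB1+/p16-"]], 12L)
  expect_identical(g$sizes[["SATB1-/p16-"]], 62L)
  expect_setequal(g$merged_from[["p16+"]],
                  c("SATB1+/p16+", "SATB1-/p16+"))
  # every cohort member assigned exactly once
  expect_identical(sort(g$assignment$sample_id), sort(rec$sample_id))
})

test_that("single-marker grouping and min_group_size = 1 never merge", {
  rec <- make_marker_records(c(16, 0, 0, 70))
  g <- assign_groups(rec, "satb1", min_group_size = 10)
  expect_setequal(g$labels, c("SATB1+", "SATB1-"))
  expect_identical(unname(sort(g$sizes)), c(16L, 70L))

  g2 <- assign_groups(make_marker_records(c(12, 8, 4, 62)),
                      c("satb1", "p16"), min_group_size = 1)
  expect_identical(length(g2$labels), 4L)
  expect_identical(length(g2$merged_from), 0L)
})

test_that("an unmergeable grouping is rejected", {
  rec <- make_marker_records(c(2, 2, 2, 2))
  expect_error(assign_groups(rec, c("satb1", "p16"), min_group_size = 10),
               class = "cureplateau_unmergeable_grouping_error")
})

test_that("evidence ratio reproduces the printed magnitudes", {
  er <- evidence_ratio(-9.672)
  expect_identical(round(er$magnitude), 126)
  expect_identical(er$direction, "favors_null")
  expect_identical(er$label, "1/126")

  er2 <- evidence_ratio(-0.03)
  expect_equal(round(er2$magnitude, 2), 1.02)

  expect_gt(evidence_ratio(148.9)$magnitude, 100)
  expect_identical(evidence_ratio(148.9)$label, "ER > 100")
  expect_gt(evidence_ratio(30.65)$magnitude, 100)

  er0 <- evidence_ratio(0)
  expect_identical(er0$magnitude, 1)
  expect_identical(er0$direction, "equivocal")
})

test_that("evidence ratio is reciprocal in sign and exp-half-linear", {
  for (d in c(0.5, 2, 9.672, 20)) {
    expect_equal(evidence_ratio(d)$magnitude,
                 evidence_ratio(-d)$magnitude)
    expect_equal(evidence_ratio(2 * d)$magnitude,
                 evidence_ratio(d)$magnitude^2)
  }
  expect_error(evidence_ratio(Inf), class = "cureplateau_validation_error")
})

test_that("extra-sum-of-squares F matches arithmetic and the F CDF", {
  res <- extra_ss_f_test(20, 18, 10, 16)
  expect_equal(res$f, 8)
  # independent route to the F tail probability via the incomplete beta
  p_beta <- pbeta(16 / (16 + 2 * 8), 16 / 2, 2 / 2)
  expect_equal(res$p, p_beta, tolerance = 1e-12)

  # equal RSS: F = 0, p = 1
  res0 <- extra_ss_f_test(10, 18, 10, 16)
  expect_equal(res0$f, 0)
  expect_equal(res0$p, 1)

  # scale invariance
  res2 <- extra_ss_f_test(40, 18, 20, 16)
  expect_equal(res2$f, res$f)
  expect_equal(res2$p, res$p)

  expect_error(extra_ss_f_test(20, 16, 10, 18),
               class = "cureplateau_validation_error")
  expect_error(extra_ss_f_test(5, 18, 10, 16),
               class = "cureplateau_validation_error")
})

test_that("global fit bookkeeping: penalty-only difference on identical data", {
  cv <- tibble::tibble(time = 1:30,
                       survival = plateau_survival(1:30, 1, 0.6, 0.1))
  curves <- list(a = cv, b = cv)
  shared <- global_fit(curves, shared = TRUE)
  separate <- global_fit(curves, shared = FALSE)
  expect_equal(shared$n, separate$n)
  expect_identical(shared$k_free, 2L)
  expect_identical(separate$k_free, 4L)
  # identical noise-free groups: equal (near-zero) RSS either way
  expect_equal(shared$rss, separate$rss, tolerance = 1e-8)

  # three groups, s0 fixed, plateau + k free -> 6 free curve parameters
  expect_identical(global_fit(list(a = cv, b = cv, c = cv),
                              shared = FALSE)$k_free, 6L)
})

test_that("very different groups make the shared fit much worse", {
  t <- 1:40
  curves <- list(
    hi = tibble::tibble(time = t, survival = plateau_survival(t, 1, 0.9, 0.2)),
    lo = tibble::tibble(time = t, survival = plateau_survival(t, 1, 0.3, 0.2))
  )
  shared <- global_fit(curves, shared = TRUE)
  separate <- global_fit(curves, shared = FALSE)
  expect_gt(shared$rss, 100 * max(separate$rss, 1e-9))
})

test_that("stratification comparison detects strong marker separation", {
  sc <- simulate_cohort(two_group_spec(86, 16 / 86, 0.87, 4.5, 0.58, 84),
                        seed = 2)
  g <- assign_groups(sc$records, "satb1", min_group_size = 1)
  cmp <- compare_stratification(sc$records, "OS", g, fit_config())
  expect_s3_class(cmp, "model_comparison")
  expect_identical(cmp$er_direction, "favors_stratified")
  expect_gt(cmp$delta_aic, 2)
  expect_lt(cmp$f_p, 0.01)
  expect_gte(cmp$null_fit$rss, sum(sapply(cmp$strat_fits, `[[`, "rss")) - 1e-9)
  td <- tidy(cmp)
  expect_identical(nrow(td), 2L)
  expect_true(all(c("plateau", "half_life", "n") %in% names(td)))
})

test_that("comparison is invariant to row order and group labels", {
  sc <- simulate_cohort(two_group_spec(80, 0.3, 0.8, 10, 0.4, 40), seed = 4)
  g <- assign_groups(sc$records, "satb1", min_group_size = 1)
  cmp1 <- compare_stratification(sc$records, "OS", g)

  shuffled <- sc$records[sample(nrow(sc$records)), ]
  g2 <- assign_groups(shuffled, "satb1", min_group_size = 1)
  cmp2 <- compare_stratification(shuffled, "OS", g2)
  expect_equal(cmp1$delta_aic, cmp2$delta_aic, tolerance = 1e-8)
  expect_equal(cmp1$f_stat, cmp2$f_stat, tolerance = 1e-6)
})

test_that("a single-group comparison is rejected as degenerate", {
  sc <- simulate_cohort(one_group_spec(40, 0.5, 20), seed = 6)
  g <- assign_groups(sc$records, "satb1", min_group_size = 1)
  expect_error(compare_stratification(sc$records, "OS", g),
               class = "cureplateau_validation_error")
})

test_that("shared-dynamics test distinguishes identical from opposite groups", {
  # duplicated data: RSS identical, the parameter penalty decides for null
  sc <- simulate_cohort(one_group_spec(60, 0.5, 20), seed = 8)
  rec_a <- sc$records
  rec_b <- sc$records
  rec_b$sample_id <- paste0("dup_", rec_b$sample_id)
  both <- dplyr::bind_rows(rec_a, rec_b)
  cmp <- test_shared_dynamics(both, "OS", rec_a$sample_id, rec_b$sample_id)
  expect_identical(cmp$er_direction, "favors_null")
  strat_rss <- sum(sapply(cmp$strat_fits, `[[`, "rss"))
  expect_equal(cmp$null_fit$rss, strat_rss, tolerance = 1e-6)

  # extreme separation favors stratification
  sc2 <- simulate_cohort(two_group_spec(120, 0.5, 0.9, 8, 0.2, 8), seed = 9)
  pos <- sc2$records$sample_id[sc2$records$satb1_positive]
  neg <- sc2$records$sample_id[!sc2$records$satb1_positive]
  cmp2 <- test_shared_dynamics(sc2$records, "OS", pos, neg)
  expect_identical(cmp2$er_direction, "favors_stratified")

  expect_error(test_shared_dynamics(both, "OS", rec_a$sample_id[1:5],
                                    rec_a$sample_id[3:8]),
               class = "cureplateau_validation_error")
})

test_that("covariate association: Fisher matches hypergeometric enumeration", {
  rec <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:24),
    satb1_positive = rep(c(TRUE, FALSE), c(10, 14)),
    grp = c(rep("x", 1), rep("y", 9), rep("x", 11), rep("y", 3))
  )
  res <- covariate_association(rec, "satb1_positive", "grp")
  tab <- res$table
  expect_identical(res$test, "fisher")
  expect_equal(res$p, fisher_bruteforce(tab), tolerance = 1e-9)
  expect_equal(res$p, 0.0028, tolerance = 0.05)

  # no association / perfect association
  bal <- tibble::tibble(sample_id = as.character(1:40),
                        satb1_positive = rep(c(TRUE, FALSE), 20),
                        grp = rep(c("x", "x", "y", "y"), 10))
  expect_equal(covariate_association(bal, "satb1_positive", "grp")$p, 1)
  perf <- tibble::tibble(sample_id = as.character(1:40),
                         satb1_positive = rep(c(TRUE, FALSE), each = 20),
                         grp = rep(c("x", "y"), each = 20))
  expect_lt(covariate_association(perf, "satb1_positive", "grp")$p, 1e-6)

  # constant covariate degenerates with a warning
  con <- tibble::tibble(sample_id = as.character(1:10),
                        satb1_positive = rep(c(TRUE, FALSE), 5),
                        grp = "x")
  expect_warning(res_c <- covariate_association(con, "satb1_positive", "grp"))
  expect_equal(res_c$p, 1)
})
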