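test_that("the generator is reproducible and seed-sensitive", {
  a <- simulate_cohort(cohort_spec(), seed = 13)
  b <- simulate_cohort(cohort_spec(), seed = 13)
  expect_identical(a$records, b$records)
  expect_identical(a$measurements, b$measurements)
  c <- simulate_cohort(cohort_spec(), seed = 14)
  expect_false(identical(a$records, c$records))
})

test_that("event-time consistency holds for every record", {
  sc <- simulate_cohort(cohort_spec(n = 500), seed = 17)
  r <- sc$records
  expect_true(all(r$pfs_time_months <= r$os_time_months + 1e-12))
  # death implies a PFS event at or before the death time
  expect_true(all(!r$os_event | r$pfs_event))
  expect_true(all(r$os_time_months > 0))
})

test_that("a plateau of 1 produces no events at all", {
  sc <- simulate_cohort(one_group_spec(200, 1, 10), seed = 19)
  expect_identical(sum(sc$records$os_event), 0L)
  expect_identical(sum(sc$records$pfs_event), 0L)
})

test_that("plateau 0 with short half-life: all events, median near truth", {
  sc <- simulate_cohort(one_group_spec(10000, 0, 1, censor_max = 1000),
                        seed = 23)
  r <- sc$records
  expect_gt(mean(r$os_event), 0.99)
  med <- median(r$os_time_months[r$os_event])
  expect_equal(med, 1, tolerance = 0.05)
})

test_that("marker counts follow the joint distribution", {
  sc <- simulate_cohort(cohort_spec(), seed = 31)
  counts <- table(sc$records$cell)
  # seeded regression pin plus binomial sanity on expectation 12/8/4/62
  expect_identical(sum(counts), 86L)
  expect_true(abs(counts[["S+P-"]] - 12) <= 10)
  expect_true(abs(counts[["S-P-"]] - 62) <= 14)
  expect_identical(
    as.integer(counts[c("S+P-", "S+P+", "S-P+", "S-P-")]),
    c(14L, 3L, 2L, 67L)
  )
})

test_that("follow-up times respect the censoring window", {
  sc <- simulate_cohort(cohort_spec(n = 400), seed = 37)
  cens <- sc$records[!sc$records$os_event, ]
  expect_true(all(cens$os_time_months >= 1 - 1e-9))
  expect_true(all(cens$os_time_months <= 197 + 1e-9))
})

test_that("round trip: fitting a large simulated group recovers the truth", {
  sc <- simulate_cohort(one_group_spec(2000, 0.6, 30, censor_max = 400),
                        seed = 41)
  fit <- fit_plateau(km_curve(sc$records, "OS"))
  expect_lt(abs(fit$plateau - 0.6), 0.03)
  expect_lt(abs(fit$half_life - 30) / 30, 0.10)
})

test_that("invalid specs are rejected with the violation listed", {
  expect_error(cohort_spec(n = 0), class = "cureplateau_validation_error")
  cells <- default_cells <- cohort_spec()$cells
  cells$fraction <- cells$fraction * 2
  expect_error(cohort_spec(cells = cells),
               class = "cureplateau_validation_error")
  cells2 <- default_cells
  cells2$pfs_plateau[1] <- cells2$os_plateau[1] + 0.1
  expect_error(cohort_spec(cells = cells2),
               regexp = "pfs_plateau")
})

test_that("expression generator plants recoverable signatures", {
  genes <- sprintf("g%04d", 1:300)
  planted <- list(list(gene_set = genes[2:31], driver_gene = genes[1],
                       target_r = 0.9))
  m <- simulate_expression(300, 50, planted, seed = 51)
  expect_identical(dim(m), c(300L, 50L))
  # byte-identical reproducibility
  m2 <- simulate_expression(300, 50, planted, seed = 51)
  expect_identical(m, m2)

  scores <- score_matrix(m, list(SIG = genes[2:31]), alpha = 0.75)
  fit <- rma_regression(scores$es, m[genes[1], scores$sample_id])
  expect_gt(fit$r, 0.7)
  expect_lt(fit$r, 0.98)

  # target_r = 0: no systematic association at 50 samples
  planted0 <- list(list(gene_set = genes[2:31], driver_gene = genes[1],
                        target_r = 0))
  r0 <- vapply(1:10, function(s) {
    m0 <- simulate_expression(300, 50, planted0, seed = 50 + s)
    sc0 <- score_matrix(m0, list(SIG = genes[2:31]), alpha = 0.75)
    cor(sc0$es, m0[genes[1], sc0$sample_id])
  }, numeric(1))
  expect_lt(median(abs(r0)), 0.2)
  expect_lt(abs(mean(r0)), 0.15)
})

test_that("expression generator rejects inconsistent plantings", {
  genes <- sprintf("g%04d", 1:100)
  expect_error(simulate_expression(100, 10, list(
    list(gene_set = genes[2:10], driver_gene = genes[1], target_r = 0.5),
    list(gene_set = genes[5:20], driver_gene = genes[30], target_r = 0.5)
  )), class = "cureplateau_validation_error")
  expect_error(simulate_expression(100, 10, list(
    list(gene_set = genes[2:10], driver_gene = "nope", target_r = 0.5)
  )), class = "cureplateau_validation_error")
  expect_error(simulate_expression(100, 10, list(
    list(gene_set = genes[2:10], driver_gene = genes[1], target_r = 1.2)
  )), class = "cureplateau_validation_error")
})
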