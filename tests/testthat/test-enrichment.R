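test_that("GMT round trip, deduplication and format errors", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SETA\tdesc\tG1\tG2", "SETB\tother\tG2\tG3\tG4"), path)
  sets <- read_gmt(path)
  expect_identical(sets$name, c("SETA", "SETB"))
  expect_identical(sets$genes[[1]], c("G1", "G2"))
  expect_identical(sets$n_genes, c(2L, 3L))

  # empty file
  writeLines(character(), path)
  expect_identical(nrow(read_gmt(path)), 0L)

  # duplicate genes collapse with a warning
  writeLines("SETC\tdesc\tG1\tG1\tG2", path)
  expect_warning(dup <- read_gmt(path), "duplicate")
  expect_identical(dup$genes[[1]], c("G1", "G2"))

  writeLines("SETD\tdesc_only", path)
  expect_error(read_gmt(path), class = "cureplateau_format_error")

  # write_gmt inverts read_gmt
  write_gmt(sets_list <- list(S1 = c("A", "B"), S2 = c("C")), path)
  back <- read_gmt(path)
  expect_identical(back$genes, list(c("A", "B"), "C"))
})

test_that("enrichment score sign follows where the set sits in the ranking", {
  expr <- setNames(as.numeric(100:1), sprintf("G%03d", 1:100))
  top <- ssgsea_score(expr, sprintf("G%03d", 1:10), alpha = 0.75)
  bottom <- ssgsea_score(expr, sprintf("G%03d", 91:100), alpha = 0.75)
  expect_gt(top$es, 0)
  expect_lt(bottom$es, 0)
  expect_error(ssgsea_score(expr, c("nope1", "nope2")),
               class = "cureplateau_empty_overlap_error")
})

test_that("unweighted score equals the brute-force ECDF walk", {
  set.seed(61)
  for (i in 1:20) {
    expr <- setNames(rnorm(20), sprintf("G%02d", 1:20))
    genes <- sample(names(expr), 4)
    for (alpha in c(0, 0.75, 1)) {
      expect_equal(ssgsea_score(expr, genes, alpha = alpha)$es,
                   ssgsea_bruteforce(expr, genes, alpha),
                   tolerance = 1e-12)
    }
  }
})

test_that("scores are rank-based: monotone transforms and row order", {
  set.seed(67)
  expr <- setNames(rnorm(50), sprintf("G%02d", 1:50))
  genes <- sprintf("G%02d", c(3, 7, 21, 40))
  base <- ssgsea_score(expr, genes)$es
  expect_equal(ssgsea_score(exp(expr), genes)$es, base)
  expect_equal(ssgsea_score(rank(expr), genes)$es, base)
  perm <- sample(length(expr))
  expect_equal(ssgsea_score(expr[perm], genes)$es, base)
})

test_that("a uniformly spread set scores near zero", {
  expr <- setNames(as.numeric(60:1), sprintf("G%02d", 1:60))
  spread <- sprintf("G%02d", seq(5, 60, by = 5))  # every 5th by rank
  es <- ssgsea_score(expr, spread, alpha = 0)$es
  # enumeration on this universe gives -2.5, i.e. < 5% of a position
  # per step; far below the top-decile set's score
  expect_lt(abs(es), 3)
  top <- ssgsea_score(expr, sprintf("G%02d", 1:12), alpha = 0)$es
  expect_gt(top, 5 * abs(es))
})

test_that("score_matrix is consistent per column and normalizes by range", {
  set.seed(71)
  m <- matrix(rnorm(200), nrow = 20,
              dimnames = list(sprintf("G%02d", 1:20), sprintf("s%d", 1:10)))
  sets <- list(A = sprintf("G%02d", 1:5), B = sprintf("G%02d", 16:20))
  scores <- score_matrix(m, sets)
  expect_identical(nrow(scores), 20L)
  one <- ssgsea_score(setNames(m[, "s3"], rownames(m)), sets$A,
                      set_name = "A")
  expect_equal(scores$es[scores$sample_id == "s3" & scores$set_name == "A"],
               one$es)

  # duplicated sample duplicates its scores
  m2 <- cbind(m, s11 = m[, "s1"])
  scores2 <- score_matrix(m2, sets)
  expect_equal(scores2$es[scores2$sample_id == "s11"],
               scores2$es[scores2$sample_id == "s1"])

  norm <- score_matrix(m, sets, normalize = TRUE)
  expect_equal(diff(range(norm$es)), 1)
})

test_that("RMA regression matches its closed form and symmetry", {
  # exact line
  fit <- rma_regression(1:10, 2 * (1:10) + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r, 1)
  expect_equal(fit$p, 0)

  # worked example: r = 0.6, slope = sd(y)/sd(x) = 1
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  fit2 <- rma_regression(x, y)
  expect_equal(fit2$r, 0.6)
  expect_equal(fit2$slope, 1)
  expect_equal(fit2$intercept, mean(y) - mean(x))
  # p agrees with the covariance-formula t route
  tstat <- 0.6 * sqrt(2 / (1 - 0.36))
  expect_equal(fit2$p, 2 * pt(-tstat, 2))

  # symmetry: swapping x and y inverts the slope
  set.seed(73)
  a <- rnorm(30); b <- 0.7 * a + rnorm(30, 0, 0.5)
  f_ab <- rma_regression(a, b)
  f_ba <- rma_regression(b, a)
  expect_equal(f_ab$slope, 1 / f_ba$slope)
  expect_equal(f_ab$r, f_ba$r)

  # |slope_RMA| = |slope_OLS| / |r|
  ols <- coef(lm(b ~ a))[["a"]]
  expect_equal(abs(f_ab$slope), abs(ols) / abs(f_ab$r))

  expect_error(rma_regression(1:2, 1:2),
               class = "cureplateau_validation_error")
  expect_error(rma_regression(rep(1, 5), 1:5),
               class = "cureplateau_degenerate_input_error")
})

test_that("planted signature is recovered end to end at small n", {
  genes <- sprintf("g%04d", 1:200)
  hits <- 0
  for (s in 1:40) {
    m <- simulate_expression(
      200, 8,
      list(list(gene_set = genes[2:26], driver_gene = genes[1],
                target_r = 0.7)),
      seed = 600 + s
    )
    scores <- score_matrix(m, list(SIG = genes[2:26]))
    fit <- rma_regression(scores$es, m[genes[1], scores$sample_id])
    if (fit$r > 0) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
})
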