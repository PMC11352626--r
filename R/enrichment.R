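# Single-sample gene-set enrichment with rank normalisation, and reduced
# major axis (geometric-mean) regression of signature scores on a
# transcript. Both are implemented here: the enrichment score is the
# integrated difference between the rank-weighted in-set ECDF and the
# out-of-set ECDF along the descending-rank walk.

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT dialect: set name, description, then the
#' member genes. Duplicate genes within a line are deduplicated with a
#' warning.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `name`, `description`, `genes`
#'   (list-column of character vectors) and `n_genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble(name = character(), description = character(),
                  genes = list(), n_genes = integer()))
  }
  parsed <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop_cp(
        sprintf("GMT line %d has %d field(s); need name, description and at least one gene.",
                i, length(fields)),
        "cureplateau_format_error"
      )
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      rlang::warn(sprintf("GMT set '%s': duplicate genes deduplicated.",
                          fields[[1L]]))
      genes <- unique(genes)
    }
    list(name = fields[[1L]], description = fields[[2L]], genes = genes)
  })
  tibble(
    name = vapply(parsed, `[[`, character(1L), "name"),
    description = vapply(parsed, `[[`, character(1L), "description"),
    genes = lapply(parsed, `[[`, "genes"),
    n_genes = vapply(parsed, function(p) length(p$genes), integer(1L))
  )
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets A tibble as returned by [read_gmt()], or a named
#'   list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  if (is.list(gene_sets) && !is.data.frame(gene_sets)) {
    gene_sets <- tibble(
      name = names(gene_sets),
      description = "na",
      genes = unname(gene_sets)
    )
  }
  lines <- vapply(seq_len(nrow(gene_sets)), function(i) {
    paste(c(gene_sets$name[[i]], gene_sets$description[[i]],
            gene_sets$genes[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Single-sample enrichment score
#'
#' Genes are ranked by expression within the sample (ties get the
#' average rank); the ranks, raised to the weighting exponent `alpha`,
#' weight the in-set empirical distribution. Walking the genes in
#' decreasing rank order (rank ties broken by gene identifier for
#' determinism), the score is the sum over positions of the difference
#' between the weighted in-set ECDF and the unweighted out-of-set ECDF.
#' Scores are invariant to any strictly monotone transform of the
#' expression values.
#'
#' @param expression Named numeric vector: one sample's expression over
#'   the gene universe.
#' @param genes Character vector, the gene set; must overlap the
#'   universe in at least one gene.
#' @param alpha Rank-weighting exponent (default 0.75).
#' @param set_name Optional set label carried into the result.
#' @return A one-row tibble with `set_name`, `es`, `alpha`, `n_overlap`.
#' @export
ssgsea_score <- function(expression, genes, alpha = 0.75,
                         set_name = NA_character_) {
  if (is.null(names(expression)) || anyNA(expression)) {
    stop_cp("`expression` must be a named numeric vector without NA.",
            "cureplateau_validation_error")
  }
  universe <- names(expression)
  in_set <- universe %in% genes
  if (!any(in_set)) {
    stop_cp(
      sprintf("Gene set '%s' has no overlap with the expression universe.",
              set_name %||% "unnamed"),
      "cureplateau_empty_overlap_error"
    )
  }
  r <- rank(expression, ties.method = "average")
  ord <- order(-r, universe)  # descending rank, ties by identifier
  r_ord <- r[ord]
  in_ord <- in_set[ord]
  w <- abs(r_ord)^alpha
  w[!in_ord] <- 0
  denom_in <- sum(w)
  n_out <- sum(!in_ord)
  p_in <- cumsum(w) / denom_in
  p_out <- if (n_out > 0) cumsum(!in_ord) / n_out else rep(0, length(r_ord))
  es <- sum(p_in - p_out)
  tibble(set_name = set_name, es = es, alpha = alpha,
         n_overlap = sum(in_set))
}

#' Score every sample against every gene set
#'
#' @param expression_matrix Numeric matrix, genes x samples, with
#'   dimnames.
#' @param gene_sets A [read_gmt()] tibble or a named list of character
#'   vectors.
#' @param alpha Rank-weighting exponent.
#' @param normalize If `TRUE`, all scores are divided by the range
#'   (max - min) of the whole score table.
#' @return A tibble with one row per (sample, set): `sample_id`,
#'   `set_name`, `es`, `alpha`.
#' @export
score_matrix <- function(expression_matrix, gene_sets, alpha = 0.75,
                         normalize = FALSE) {
  if (is.null(rownames(expression_matrix)) ||
      is.null(colnames(expression_matrix))) {
    stop_cp("`expression_matrix` needs gene rownames and sample colnames.",
            "cureplateau_validation_error")
  }
  if (is.list(gene_sets) && !is.data.frame(gene_sets)) {
    gene_sets <- tibble(
      name = names(gene_sets),
      description = "na",
      genes = unname(gene_sets)
    )
  }
  out <- purrr::map_dfr(colnames(expression_matrix), function(s) {
    expr <- expression_matrix[, s]
    names(expr) <- rownames(expression_matrix)
    purrr::map_dfr(seq_len(nrow(gene_sets)), function(i) {
      sc <- ssgsea_score(expr, gene_sets$genes[[i]], alpha = alpha,
                         set_name = gene_sets$name[[i]])
      dplyr::mutate(sc, sample_id = s, .before = 1L)
    })
  })
  if (normalize && nrow(out) > 0L) {
    rng <- diff(range(out$es))
    if (rng > 0) out$es <- out$es / rng
  }
  dplyr::select(out, "sample_id", "set_name", "es", "alpha")
}

#' Reduced major axis regression
#'
#' Geometric-mean (model II) regression, symmetric in `x` and `y`:
#' `slope = sign(r) * sd(y)/sd(x)`,
#' `intercept = mean(y) - slope * mean(x)`, with `r` the Pearson
#' correlation and a two-sided t test on `r` with `n - 2` degrees of
#' freedom for the p-value.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, each with
#'   positive standard deviation.
#' @return A one-row tibble of class `rma_fit` with `slope`,
#'   `intercept`, `r`, `p`, `n`.
#' @examples
#' rma_regression(1:10, 2 * (1:10) + 1)  # slope 2, intercept 1, r 1
#' @export
rma_regression <- function(x, y) {
  if (length(x) != length(y)) {
    stop_cp("`x` and `y` must have equal length.",
            "cureplateau_validation_error")
  }
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) {
    stop_cp("Need at least 3 complete observations.",
            "cureplateau_validation_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_cp("`x` and `y` must each have positive standard deviation.",
            "cureplateau_degenerate_input_error")
  }
  r <- cor(x, y)
  s <- if (r < 0) -1 else 1
  slope <- s * sd(y) / sd(x)
  intercept <- mean(y) - slope * mean(x)
  p <- if (abs(r) >= 1) {
    0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  out <- tibble(slope = slope, intercept = intercept, r = r, p = p, n = n)
  class(out) <- c("rma_fit", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.rma_fit <- function(object, x = NULL, y = NULL, ...) {
  if (is.null(x) || is.null(y)) {
    stop_cp("Supply the original `x` and `y` vectors to plot an RMA fit.",
            "cureplateau_validation_error")
  }
  df <- tibble(x = x, y = y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(
      title = sprintf("RMA regression: slope %.3f, r = %.2f, p = %.3g",
                      object$slope, object$r, object$p)
    ) +
    ggplot2::theme_minimal()
}
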