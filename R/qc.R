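#' Log2 normalized expression table
#'
#' Normalizes counts by median-of-ratios size factors and returns
#' `log2(normalized count + 1)` — the scale used by the sample-level QC,
#' co-expression, and guilt-by-association stages.
#'
#' @inheritParams size_factors
#' @param factors Size factors; computed with [size_factors()] when `NULL`.
#' @return A tibble: `gene_id` plus one column per sample.
#' @export
normalized_log_expr <- function(counts, factors = NULL) {
  m <- check_counts(as_count_matrix(counts))
  if (is.null(factors)) factors <- size_factors(counts)
  x <- log2(normalize_counts(m, factors[colnames(m)]) + 1)
  as_tibble(x, rownames = "gene_id")
}

expr_matrix <- function(expr) {
  if (is.matrix(expr)) return(expr)
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- as.character(expr[[1]])
  m
}

#' Pairwise sample Pearson correlation
#'
#' Pearson correlation between every pair of samples across genes, computed
#' on a log2 normalized expression table. Samples with constant expression
#' have no defined correlation and are reported as `NA` with a warning.
#'
#' @param expr Expression table from [normalized_log_expr()] (or any data
#'   frame with a gene-id column followed by sample columns).
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(expr) {
  m <- expr_matrix(expr)
  if (ncol(m) < 2) abort("at least 2 samples are required")
  sds <- apply(m, 2, sd)
  r <- suppressWarnings(cor(m))
  if (any(sds == 0)) {
    warn(paste0("constant expression in sample(s) ",
                paste(colnames(m)[sds == 0], collapse = ", "),
                "; correlations reported as NA"))
    r[sds == 0, ] <- NA_real_
    r[, sds == 0] <- NA_real_
  }
  diag(r) <- 1
  r
}

#' Principal component analysis of samples
#'
#' Samples are projected onto principal components of the gene-wise centered
#' log2 expression (singular value decomposition via [stats::prcomp()]).
#' Component signs are fixed deterministically: each component is flipped so
#' that its largest-magnitude gene loading is positive, making scores
#' byte-reproducible across platforms.
#'
#' @inheritParams sample_correlation
#' @return A list with `scores` (tibble: sample, PC1...), `var_explained`
#'   (fractions summing to 1), and `loadings`.
#' @export
pca_samples <- function(expr) {
  m <- expr_matrix(expr)
  if (ncol(m) < 2) abort("at least 2 samples are required for PCA")
  fit <- prcomp(t(m), center = TRUE, scale. = FALSE)
  flip <- apply(fit$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(fit$rotation, 2, flip, "*")
  scores <- sweep(fit$x, 2, flip, "*")
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = as_tibble(scores, rownames = "sample"),
       var_explained = setNames(ve, colnames(scores)),
       loadings = rot)
}

#' Sample-level quality control
#'
#' Bundles the two sample-level checks run before any downstream analysis:
#' the pairwise Pearson correlation matrix (replicates of the same condition
#' should correlate highly) and PCA (the two groups should separate).
#'
#' @inheritParams nb_test
#' @return An object of class `cerna_qc` with elements `correlation`,
#'   `pca`, and `samples`. [tidy()] returns PC scores with group labels;
#'   [autoplot()] draws the PCA map.
#' @export
qc_samples <- function(counts, samples) {
  expr <- normalized_log_expr(counts)
  groups <- check_groups(samples, names(expr)[-1])
  structure(list(correlation = sample_correlation(expr),
                 pca = pca_samples(expr),
                 samples = tibble(sample = names(groups), group = unname(groups))),
            class = "cerna_qc")
}

#' @export
print.cerna_qc <- function(x, ...) {
  r <- x$correlation
  off <- r[upper.tri(r)]
  cat("<cerna_qc> ", nrow(r), " samples; off-diagonal correlation ",
      sprintf("%.3f-%.3f", min(off), max(off)), "; PC1 explains ",
      sprintf("%.1f%%", 100 * x$pca$var_explained[1]), "\n", sep = "")
  invisible(x)
}

#' @rdname qc_samples
#' @param x A `cerna_qc` object.
#' @param ... Unused.
#' @method tidy cerna_qc
#' @export
tidy.cerna_qc <- function(x, ...) {
  left_join(x$pca$scores, x$samples, by = "sample") |>
    relocate("sample", "group")
}

#' @rdname qc_samples
#' @method glance cerna_qc
#' @export
glance.cerna_qc <- function(x, ...) {
  off <- x$correlation[upper.tri(x$correlation)]
  tibble(n_samples = nrow(x$correlation),
         min_cor = min(off), median_cor = median(off),
         pc1_var = x$pca$var_explained[[1]],
         pc2_var = x$pca$var_explained[[2]])
}
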