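#' Median-of-ratios size factors
#'
#' Per-sample scaling constants computed with the median-of-ratios estimator:
#' each sample's factor is the median, over genes expressed in every sample,
#' of the ratio of its count to the gene's geometric mean. Factors are
#' rescaled so their geometric mean is 1, which leaves ratios between samples
#' untouched but fixes the overall scale.
#'
#' @param counts Count data: a data frame whose first column holds gene ids
#'   followed by one column per sample, or a numeric matrix with gene-id
#'   rownames.
#' @return A named numeric vector of positive size factors, one per sample.
#' @examples
#' counts <- tibble::tibble(gene = c("g1", "g2", "g3"),
#'                          s1 = c(10, 20, 30), s2 = c(20, 40, 60))
#' size_factors(counts)
#' @export
size_factors <- function(counts) {
  m <- check_counts(as_count_matrix(counts))
  ref <- m[rowSums(m > 0) == ncol(m), , drop = FALSE]
  if (nrow(ref) == 0) {
    abort(paste0(
      "no gene has nonzero counts in every sample; median-of-ratios ",
      "normalization needs at least one such reference gene. Filter samples ",
      "or provide size factors computed elsewhere."))
  }
  gm <- apply(ref, 1, geometric_mean)
  sf <- apply(ref / gm, 2, median)
  sf / geometric_mean(sf)
}

# normalized count matrix (counts / size factor, per sample)
normalize_counts <- function(m, factors) {
  sweep(m, 2, factors, "/")
}

#' Negative-binomial Wald test for a two-group design
#'
#' Tests each gene for a difference in mean normalized expression between the
#' knockout and control groups under a negative-binomial model with variance
#' `m + phi * m^2`. The per-gene dispersion `phi` is estimated by the method
#' of moments within each group and pooled, floored at 0 (a Poisson fallback
#' for underdispersed genes). The Wald statistic on the log2 mean difference
#' is referred to a Student t distribution with `n1 + n2 - 2` degrees of
#' freedom, which keeps the test calibrated at the small group sizes typical
#' of this design.
#'
#' @inheritParams size_factors
#' @param samples Sample sheet: data frame with columns `sample` and `group`
#'   (`control` / `knockout`).
#' @param factors Size factors; computed with [size_factors()] when `NULL`.
#' @param dispersion Optional fixed dispersion used for every gene instead of
#'   the method-of-moments estimate (0 gives a Poisson Wald test).
#' @return A tibble with one row per gene: group means of normalized counts,
#'   `basemean`, the pooled `dispersion`, Wald `statistic`, `p_value`, and a
#'   `flagged` column marking low-information genes (fewer than two nonzero
#'   samples, or a zero group mean handled with a half-count floor).
#' @export
nb_test <- function(counts, samples, factors = NULL, dispersion = NULL) {
  m <- check_counts(as_count_matrix(counts))
  groups <- check_groups(samples, colnames(m))
  if (is.null(factors)) factors <- size_factors(counts)
  factors <- factors[colnames(m)]
  x <- normalize_counts(m, factors)

  ctl <- which(groups == "control")
  ko <- which(groups == "knockout")
  nA <- length(ko); nB <- length(ctl)

  # the model operates on normalized counts: mean m, variance m + phi*m^2,
  # so rescaling a sample's counts (and hence its size factor) changes nothing
  mA <- rowMeans(x[, ko, drop = FALSE])
  mB <- rowMeans(x[, ctl, drop = FALSE])
  vA <- apply(x[, ko, drop = FALSE], 1, var)
  vB <- apply(x[, ctl, drop = FALSE], 1, var)

  if (is.null(dispersion)) {
    phiA <- ifelse(mA > 0, (vA - mA) / mA^2, NA_real_)
    phiB <- ifelse(mB > 0, (vB - mB) / mB^2, NA_real_)
    phi <- rowMeans(cbind(phiA, phiB), na.rm = TRUE)
    phi[is.nan(phi)] <- 0
    phi <- pmax(0, phi)
  } else {
    stopifnot(length(dispersion) %in% c(1L, nrow(m)), all(dispersion >= 0))
    phi <- rep_len(dispersion, nrow(m))
  }

  all_zero <- mA == 0 & mB == 0
  low_info <- rowSums(m > 0) < 2
  # a zero group mean leaves log2 undefined; floor it at half a normalized count
  floorA <- mA == 0 & !all_zero
  floorB <- mB == 0 & !all_zero
  mA2 <- ifelse(floorA, 0.5 / nA, mA)
  mB2 <- ifelse(floorB, 0.5 / nB, mB)

  varA <- pmax((mA2 + phi * mA2^2) / nA, 1e-8)
  varB <- pmax((mB2 + phi * mB2^2) / nB, 1e-8)
  se <- sqrt(varA / (mA2 * log(2))^2 + varB / (mB2 * log(2))^2)
  stat <- (log2(mA2) - log2(mB2)) / se
  df <- nA + nB - 2
  p <- 2 * pt(-abs(stat), df = df)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  stat[all_zero] <- 0
  p[all_zero] <- 1

  tibble(
    gene_id = rownames(m),
    mean_control = unname(mB), mean_knockout = unname(mA),
    basemean = unname(rowMeans(x)),
    dispersion = unname(phi),
    statistic = unname(stat),
    p_value = unname(p),
    flagged = unname(all_zero | low_info | floorA | floorB)
  )
}

#' Log2 fold change of normalized group means
#'
#' `log2((mean_knockout + pseudocount) / (mean_control + pseudocount))`. The
#' pseudocount stabilizes the display value for low counts; the significance
#' test itself uses the model means without it.
#'
#' @inheritParams nb_test
#' @param pseudocount Constant added to both group means (default 1).
#' @return A tibble with `gene_id` and `log2fc`.
#' @export
fold_change <- function(counts, samples, factors = NULL, pseudocount = 1) {
  m <- check_counts(as_count_matrix(counts))
  groups <- check_groups(samples, colnames(m))
  if (is.null(factors)) factors <- size_factors(counts)
  x <- normalize_counts(m, factors[colnames(m)])
  mA <- rowMeans(x[, groups == "knockout", drop = FALSE])
  mB <- rowMeans(x[, groups == "control", drop = FALSE])
  tibble(gene_id = rownames(m),
         log2fc = unname(log2((mA + pseudocount) / (mB + pseudocount))))
}

#' Screen differential-expression results
#'
#' A gene is called differentially expressed when `p_value < p_threshold` and
#' `|log2fc| > lfc_threshold`, both strict (`lfc_threshold = 1` is the
#' fold-change > 2 rule). The raw p value is screened; the BH-adjusted value
#' is reported alongside for transparency.
#'
#' @param results Data frame with at least `p_value` and `log2fc` columns.
#' @param p_threshold Raw p-value cutoff (strict `<`, default 0.05).
#' @param lfc_threshold Absolute log2 fold-change cutoff (strict `>`, default 1).
#' @return `results` with a `direction` column (`up`, `down`, `ns`).
#' @export
screen_de <- function(results, p_threshold = 0.05, lfc_threshold = 1) {
  stopifnot(all(c("p_value", "log2fc") %in% names(results)))
  results |>
    mutate(direction = case_when(
      .data$p_value < p_threshold & .data$log2fc > lfc_threshold ~ "up",
      .data$p_value < p_threshold & .data$log2fc < -lfc_threshold ~ "down",
      TRUE ~ "ns"
    ))
}

#' Differential expression analysis of a two-group count matrix
#'
#' Runs the full differential-expression stage: median-of-ratios
#' normalization, the negative-binomial Wald test, pseudocounted log2 fold
#' changes, BH adjustment, and the screening rule (`p < 0.05`, `|log2FC| > 1`
#' by default).
#'
#' @inheritParams nb_test
#' @inheritParams screen_de
#' @inheritParams fold_change
#' @return An object of class `cerna_de`. Use [tidy()] for the per-gene
#'   table, [glance()] for a one-row summary, and [autoplot()] for a volcano
#'   plot.
#' @examples
#' study <- simulate_cerna_study(simulation_config(n_genes = 120, n_lncrnas = 20,
#'                                                 n_mirnas = 4, rng_seed = 7))
#' de <- diff_expression(study$counts, study$samples)
#' glance(de)
#' @export
diff_expression <- function(counts, samples, p_threshold = 0.05,
                            lfc_threshold = 1, pseudocount = 1) {
  factors <- size_factors(counts)
  res <- nb_test(counts, samples, factors = factors) |>
    left_join(fold_change(counts, samples, factors = factors,
                          pseudocount = pseudocount), by = "gene_id") |>
    mutate(p_adjusted = bh_adjust(.data$p_value)) |>
    screen_de(p_threshold = p_threshold, lfc_threshold = lfc_threshold) |>
    select("gene_id", "basemean", "mean_control", "mean_knockout",
           "log2fc", "dispersion", "statistic", "p_value", "p_adjusted",
           "direction", "flagged")
  structure(
    list(results = res, size_factors = factors,
         thresholds = list(p = p_threshold, lfc = lfc_threshold),
         samples = as_tibble(samples)),
    class = "cerna_de")
}

#' @export
print.cerna_de <- function(x, ...) {
  n <- table(factor(x$results$direction, levels = c("up", "down", "ns")))
  cat("<cerna_de> ", nrow(x$results), " genes tested (",
      n[["up"]], " up, ", n[["down"]], " down at p<", x$thresholds$p,
      ", |log2FC|>", x$thresholds$lfc, ")\n", sep = "")
  invisible(x)
}

#' @rdname diff_expression
#' @param x,object A `cerna_de` object.
#' @param ... Unused.
#' @method tidy cerna_de
#' @export
tidy.cerna_de <- function(x, ...) x$results

#' @rdname diff_expression
#' @method glance cerna_de
#' @export
glance.cerna_de <- function(x, ...) {
  tibble(n_genes = nrow(x$results),
         n_up = sum(x$results$direction == "up"),
         n_down = sum(x$results$direction == "down"),
         p_threshold = x$thresholds$p,
         lfc_threshold = x$thresholds$lfc)
}
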