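#' lncRNA-mRNA co-expression edges
#'
#' Pearson correlation between every lncRNA and every mRNA across samples on
#' the log2 normalized expression scale, with a two-sided p value from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#' Both groups are pooled: with three replicates per condition only the
#' six-sample correlation makes an `|r| > 0.8` screen meaningful.
#'
#' @param lnc_expr,mrna_expr Expression tables (gene-id column + identical
#'   sample columns), typically rows of [normalized_log_expr()] split by
#'   biotype.
#' @return A tibble of all pairs: `lncrna_id`, `mrna_id`, `r`, `p_value`,
#'   `sign`. Zero-variance genes are skipped with a warning.
#' @export
correlate_pairs <- function(lnc_expr, mrna_expr) {
  L <- expr_matrix(lnc_expr)
  M <- expr_matrix(mrna_expr)
  if (!identical(colnames(L), colnames(M))) {
    abort("lncRNA and mRNA tables must share the same sample columns")
  }
  n <- ncol(L)
  if (n < 3) abort("at least 3 samples are required for correlation p values")
  keepL <- apply(L, 1, sd) > 0
  keepM <- apply(M, 1, sd) > 0
  if (!all(keepL) || !all(keepM)) {
    warn(paste0(sum(!keepL) + sum(!keepM),
                " zero-variance gene(s) skipped in correlation"))
  }
  L <- L[keepL, , drop = FALSE]; M <- M[keepM, , drop = FALSE]
  if (nrow(L) == 0 || nrow(M) == 0) {
    return(tibble(lncrna_id = character(), mrna_id = character(),
                  r = double(), p_value = double(), sign = character()))
  }
  R <- cor(t(L), t(M))
  R <- pmin(pmax(R, -1), 1)
  tstat <- R * sqrt(n - 2) / sqrt(pmax(1 - R^2, .Machine$double.eps))
  P <- 2 * pt(-abs(tstat), df = n - 2)
  P <- pmin(pmax(P, .Machine$double.xmin), 1)
  tibble(
    lncrna_id = rep(rownames(L), times = ncol(R)),
    mrna_id = rep(colnames(R), each = nrow(R)),
    r = as.vector(R),
    p_value = as.vector(P)
  ) |>
    mutate(sign = if_else(.data$r >= 0, "positive", "negative"))
}

#' Screen co-expression edges
#'
#' Keeps pairs with `|r| > r_threshold` and `p_value < p_threshold`, both
#' strict — the published screening rule for lncRNA-mRNA pairs.
#'
#' @param edges Output of [correlate_pairs()].
#' @param r_threshold Absolute correlation cutoff, strict (default 0.8).
#' @param p_threshold Raw p-value cutoff, strict (default 0.05).
#' @return The passing edges.
#' @export
screen_edges <- function(edges, r_threshold = 0.8, p_threshold = 0.05) {
  filter(edges, abs(.data$r) > r_threshold, .data$p_value < p_threshold)
}

#' Top co-expression pairs
#'
#' Ranks edges ascending by p value — ties broken by descending `|r|`, then
#' lexicographically by `(lncrna_id, mrna_id)` so the selection is
#' deterministic — and returns the first `n`.
#'
#' @inheritParams screen_edges
#' @param n Number of pairs to keep (default 500).
#' @return At most `n` edges, ranked.
#' @export
top_pairs <- function(edges, n = 500) {
  edges |>
    arrange(.data$p_value, desc(abs(.data$r)), .data$lncrna_id, .data$mrna_id) |>
    slice_head(n = n)
}
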