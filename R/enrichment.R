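#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control: p values are sorted ascending,
#' `adj_i = min_{j >= i} (p_j * m / j)` capped at 1, and the original order
#' is restored. Thin wrapper over [stats::p.adjust()] so every module shares
#' one definition.
#'
#' @param p Numeric vector of p values in (0, 1].
#' @return Adjusted p values, elementwise `>=` the input.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p), all(is.na(p) | (p > 0 & p <= 1)))
  p.adjust(p, method = "BH")
}

harmonize_sets <- function(sets) {
  stopifnot(all(c("term_id", "category", "gene_id") %in% names(sets)))
  distinct(as_tibble(sets), .data$term_id, .data$category, .data$gene_id)
}

#' Hypergeometric over-representation test
#'
#' For each annotation term, tests whether the query gene set hits the term
#' more often than expected by chance under sampling without replacement:
#' the upper-tail probability `P(X >= k)` with `X ~ Hypergeometric(K, N - K,
#' n)`, where `N` is the universe size, `K` the term size, `n` the query
#' size, and `k` the overlap. P values are BH-adjusted within each category
#' (BP, CC, MF, pathway) separately.
#'
#' @param query Character vector of gene ids.
#' @param sets Annotation sets: a long data frame with columns `term_id`,
#'   `category`, `gene_id` (see [read_gmt()]).
#' @param universe Background gene universe; defaults to all genes appearing
#'   in `sets`. Query genes outside the universe are dropped with a warning.
#' @return A tibble per term: `term_id`, `category`, `hit_count`,
#'   `term_size`, `query_size`, `universe_size`, `p_value`, `p_adjusted`,
#'   and a `hits` list-column of overlapping gene ids.
#' @examples
#' sets <- tibble::tibble(term_id = "t1", category = "BP",
#'                        gene_id = paste0("g", 1:5))
#' hypergeom_enrich(paste0("g", 1:5), sets, universe = paste0("g", 1:20))
#' @export
hypergeom_enrich <- function(query, sets, universe = NULL) {
  sets <- harmonize_sets(sets)
  if (is.null(universe)) universe <- unique(sets$gene_id)
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  dropped <- setdiff(query, universe)
  if (length(dropped)) {
    warn(paste0(length(dropped), " query gene(s) outside the universe dropped"))
    query <- intersect(query, universe)
  }
  if (length(query) == 0) {
    warn("empty query after harmonization; no enrichment computed")
    return(tibble(term_id = character(), category = character(),
                  hit_count = integer(), term_size = integer(),
                  query_size = integer(), universe_size = integer(),
                  p_value = double(), p_adjusted = double(),
                  hits = list()))
  }
  sets <- filter(sets, .data$gene_id %in% universe)
  N <- length(universe); n <- length(query)
  res <- sets |>
    group_by(.data$term_id, .data$category) |>
    summarise(term_size = dplyr::n(),
              hits = list(intersect(.data$gene_id, query)),
              .groups = "drop") |>
    filter(.data$term_size > 0) |>
    mutate(hit_count = lengths(.data$hits),
           query_size = n, universe_size = N,
           p_value = phyper(.data$hit_count - 1, .data$term_size,
                            N - .data$term_size, n, lower.tail = FALSE)) |>
    group_by(.data$category) |>
    mutate(p_adjusted = bh_adjust(.data$p_value)) |>
    ungroup() |>
    select("term_id", "category", "hit_count", "term_size", "query_size",
           "universe_size", "p_value", "p_adjusted", "hits") |>
    arrange(.data$p_value, .data$term_id)
  res
}

#' Screen enrichment results
#'
#' Keeps terms with at least `min_count` query hits (inclusive) and a
#' BH-adjusted p value strictly below `padj_threshold`.
#'
#' @param results Output of [hypergeom_enrich()].
#' @param min_count Minimum overlap, inclusive (default 3).
#' @param padj_threshold Adjusted p-value cutoff, strict `<` (default 0.05).
#' @return The filtered tibble.
#' @export
screen_terms <- function(results, min_count = 3, padj_threshold = 0.05) {
  filter(results, .data$hit_count >= min_count,
         .data$p_adjusted < padj_threshold)
}

#' Guilt-by-association annotation of lncRNAs
#'
#' A lncRNA inherits putative functions from the coding genes it is
#' co-expressed with: for each lncRNA, the query is the set of mRNAs whose
#' co-expression edge passed screening, and that query is run through
#' [hypergeom_enrich()] and [screen_terms()] unchanged. lncRNAs with no
#' passing partners yield no rows.
#'
#' @param edges Screened co-expression edges ([screen_edges()] output) with
#'   columns `lncrna_id` and `mrna_id`.
#' @inheritParams hypergeom_enrich
#' @inheritParams screen_terms
#' @param lncrnas Optional subset of lncRNA ids to annotate.
#' @return A tibble of screened enrichment results with a leading
#'   `lncrna_id` column.
#' @export
annotate_lncrna <- function(edges, sets, universe = NULL, lncrnas = NULL,
                            min_count = 3, padj_threshold = 0.05) {
  stopifnot(all(c("lncrna_id", "mrna_id") %in% names(edges)))
  ids <- sort(unique(edges$lncrna_id))
  if (!is.null(lncrnas)) ids <- intersect(sort(unique(lncrnas)), c(ids, lncrnas))
  purrr::map(ids, function(id) {
    partners <- sort(unique(edges$mrna_id[edges$lncrna_id == id]))
    if (length(partners) == 0) return(NULL)
    out <- suppressWarnings(hypergeom_enrich(partners, sets, universe)) |>
      screen_terms(min_count = min_count, padj_threshold = padj_threshold)
    if (nrow(out) == 0) return(NULL)
    mutate(out, lncrna_id = id, .before = 1)
  }) |>
    purrr::list_rbind()
}

#' Rank lncRNAs by number of enriched terms
#'
#' Orders lncRNAs by how many annotation terms their co-expressed partners
#' are enriched in — the criterion used to shortlist the most functionally
#' connected lncRNAs.
#'
#' @param annotations Output of [annotate_lncrna()].
#' @param category Optional category filter (e.g. count GO and pathway
#'   enrichments separately).
#' @return A tibble `lncrna_id`, `n_terms`, ordered decreasing with
#'   lexicographic tie-break.
#' @export
rank_lncrnas <- function(annotations, category = NULL) {
  if (is.null(annotations) || nrow(annotations) == 0) {
    return(tibble(lncrna_id = character(), n_terms = integer()))
  }
  if (!is.null(category)) {
    annotations <- filter(annotations, .data$category %in% !!category)
  }
  annotations |>
    count(.data$lncrna_id, name = "n_terms") |>
    arrange(desc(.data$n_terms), .data$lncrna_id)
}
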