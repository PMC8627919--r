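#' Assemble lncRNA-miRNA-mRNA triples
#'
#' Emits the triple (L, mu, M) when the lncRNA-miRNA pair exists in the
#' binding-site table, the miRNA-mRNA pair exists in the target table, and a
#' co-expression edge between L and M exists with positive correlation above
#' `r_threshold` (strict). Duplicates are collapsed. These are the candidate
#' competing-endogenous-RNA relationships: the lncRNA and mRNA share a miRNA
#' and rise and fall together.
#'
#' @param lnc_mi lncRNA-miRNA pairs (`lncrna_id`, `mirna_id`), e.g. from
#'   [predict_mirna_lncrna()].
#' @param mi_m miRNA-mRNA pairs (`mirna_id`, `mrna_id`), e.g. from
#'   [mirna_mrna_pairs()].
#' @param edges Co-expression edges (`lncrna_id`, `mrna_id`, `r`).
#' @param r_threshold Positive-correlation cutoff, strict (default 0.8).
#' @return A tibble `lncrna_id`, `mirna_id`, `mrna_id`, `coexpression_r`.
#' @export
assemble_triples <- function(lnc_mi, mi_m, edges, r_threshold = 0.8) {
  stopifnot(all(c("lncrna_id", "mirna_id") %in% names(lnc_mi)),
            all(c("mirna_id", "mrna_id") %in% names(mi_m)),
            all(c("lncrna_id", "mrna_id", "r") %in% names(edges)))
  distinct(as_tibble(lnc_mi), .data$lncrna_id, .data$mirna_id) |>
    inner_join(distinct(as_tibble(mi_m), .data$mirna_id, .data$mrna_id),
               by = "mirna_id", relationship = "many-to-many") |>
    inner_join(select(as_tibble(edges), "lncrna_id", "mrna_id", "r"),
               by = c("lncrna_id", "mrna_id")) |>
    filter(.data$r > r_threshold, .data$r > 0) |>
    distinct(.data$lncrna_id, .data$mirna_id, .data$mrna_id,
             coexpression_r = .data$r) |>
    arrange(.data$lncrna_id, .data$mirna_id, .data$mrna_id)
}

#' Strict co-expression filter on triples
#'
#' Narrows assembled triples to those whose lncRNA-mRNA correlation exceeds
#' `r_threshold` (strict; default 0.95) — the rule used to shrink the
#' network to its strongest competing relationships when the full set is
#' too large to interpret.
#'
#' @param triples Output of [assemble_triples()].
#' @param r_threshold Strict lower bound on `coexpression_r` (default 0.95).
#' @return The passing triples.
#' @export
strict_filter <- function(triples, r_threshold = 0.95) {
  filter(triples, .data$coexpression_r > r_threshold)
}

#' Build the typed ceRNA network
#'
#' The union of the three edge types induced by the triples — lncRNA-miRNA,
#' miRNA-mRNA, and lncRNA-mRNA co-expression — with each unique pair
#' contributing one undirected edge regardless of how many triples contain
#' it. Nodes are typed (lncRNA / miRNA / mRNA) and optionally carry the
#' regulation direction from the differential-expression results.
#'
#' @param triples Output of [assemble_triples()] or [strict_filter()].
#' @param directions Optional data frame (`gene_id`, `direction`) used to
#'   label lncRNA and mRNA nodes up/down.
#' @return An object of class `cerna_network` wrapping an [igraph] graph
#'   plus node and edge tibbles. [tidy()] returns the edges, [glance()] the
#'   per-type counts, [autoplot()] a network drawing.
#' @export
build_network <- function(triples, directions = NULL) {
  edges <- bind_rows(
    distinct(triples, from = .data$lncrna_id, to = .data$mirna_id) |>
      mutate(type = "lncRNA-miRNA"),
    distinct(triples, from = .data$mirna_id, to = .data$mrna_id) |>
      mutate(type = "miRNA-mRNA"),
    distinct(triples, from = .data$lncrna_id, to = .data$mrna_id) |>
      mutate(type = "lncRNA-mRNA-coexpression")
  ) |> distinct()
  nodes <- bind_rows(
    tibble(name = unique(triples$lncrna_id), type = "lncRNA"),
    tibble(name = unique(triples$mirna_id), type = "miRNA"),
    tibble(name = unique(triples$mrna_id), type = "mRNA")
  ) |> arrange(.data$type, .data$name)
  if (!is.null(directions)) {
    nodes <- left_join(nodes,
                       distinct(as_tibble(directions),
                                name = .data$gene_id, .data$direction),
                       by = "name")
  } else {
    nodes$direction <- NA_character_
  }
  graph <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = nodes)
  structure(list(graph = graph, nodes = nodes, edges = edges,
                 triples = as_tibble(triples)),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat("<cerna_network> ", nrow(x$nodes), " nodes (",
      paste(capture_counts(x$nodes$type), collapse = ", "), "); ",
      nrow(x$edges), " edges (",
      paste(capture_counts(x$edges$type), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

capture_counts <- function(x) {
  tab <- table(x)
  paste0(names(tab), ": ", as.integer(tab))
}

#' @rdname build_network
#' @param x A `cerna_network` object.
#' @param ... Unused.
#' @method tidy cerna_network
#' @export
tidy.cerna_network <- function(x, ...) as_tibble(x$edges)

#' @rdname build_network
#' @method glance cerna_network
#' @export
glance.cerna_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_lncrna = sum(x$nodes$type == "lncRNA"),
    n_mirna = sum(x$nodes$type == "miRNA"),
    n_mrna = sum(x$nodes$type == "mRNA"),
    n_edges = nrow(x$edges),
    n_lnc_mi = sum(x$edges$type == "lncRNA-miRNA"),
    n_mi_m = sum(x$edges$type == "miRNA-mRNA"),
    n_coexpr = sum(x$edges$type == "lncRNA-mRNA-coexpression")
  )
}

#' Degree ranking of network hubs
#'
#' Node degree counts every distinct incident edge across all edge types
#' (the mixed counting a degree of 19 for an mRNA in a triple network
#' requires). Nodes are ranked within their class (lncRNA, mRNA, miRNA)
#' by decreasing degree with lexicographic tie-break, and the top `top_k`
#' of each class are returned.
#'
#' @param network A [build_network()] result.
#' @param top_k Rows per node class (default 5).
#' @return A tibble `node`, `degree`, `type`, `direction`, `rank`.
#' @export
degree_ranking <- function(network, top_k = 5) {
  deg <- igraph::degree(network$graph)
  tibble(node = names(deg), degree = as.integer(deg)) |>
    left_join(rename(network$nodes, node = "name"), by = "node") |>
    group_by(.data$type) |>
    arrange(desc(.data$degree), .data$node, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    slice_head(n = top_k) |>
    ungroup() |>
    select("node", "degree", "type", "direction", "rank")
}
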