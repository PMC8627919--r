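check_features <- function(features) {
  stopifnot(all(c("feature_id", "chromosome", "start", "end", "biotype")
                %in% names(features)))
  if (any(features$start > features$end)) abort("features with start > end")
  as_tibble(features)
}

#' Cis lncRNA target candidates
#'
#' A coding gene is a cis candidate of a lncRNA when (i) both lie on the
#' same chromosome with an interval distance of at most `window` bases
#' (distance 0 when the loci overlap; the window boundary is inclusive —
#' "within 100 kb upstream or downstream", read as bidirectional genomic
#' distance with strand ignored), and (ii) the pair passed co-expression
#' screening. Pairs whose members lack annotation are skipped with a
#' warning.
#'
#' @param features Annotation table (`feature_id`, `chromosome`, `start`,
#'   `end`, `strand`, `biotype`), 1-based inclusive coordinates.
#' @param edges Screened co-expression edges (`lncrna_id`, `mrna_id`, `r`,
#'   `p_value`).
#' @param window Maximum genomic distance in bases (default 100000,
#'   inclusive).
#' @return A tibble `lncrna_id`, `gene_id`, `chromosome`, `distance`, `r`,
#'   `p_value`.
#' @export
cis_candidates <- function(features, edges, window = 100000) {
  features <- check_features(features)
  known <- features$feature_id
  miss <- edges$lncrna_id %in% known & edges$mrna_id %in% known
  if (!all(miss)) {
    warn(paste0(sum(!miss), " co-expression pair(s) skipped: member missing",
                " from the annotation"))
  }
  f <- select(features, "feature_id", "chromosome", "start", "end")
  edges[miss, , drop = FALSE] |>
    inner_join(rename_with(f, ~ paste0("lnc_", .x)),
               by = c(lncrna_id = "lnc_feature_id")) |>
    inner_join(rename_with(f, ~ paste0("m_", .x)),
               by = c(mrna_id = "m_feature_id")) |>
    filter(.data$lnc_chromosome == .data$m_chromosome) |>
    mutate(distance = interval_distance(.data$lnc_start, .data$lnc_end,
                                        .data$m_start, .data$m_end)) |>
    filter(.data$distance <= window) |>
    transmute(lncrna_id = .data$lncrna_id, gene_id = .data$mrna_id,
              chromosome = .data$lnc_chromosome, distance = .data$distance,
              r = .data$r, p_value = .data$p_value) |>
    arrange(.data$lncrna_id, .data$gene_id)
}

#' Trans lncRNA target candidates
#'
#' Co-expressed lncRNA-mRNA pairs whose members lie on different
#' chromosomes — distant partners that cannot be explained by genomic
#' proximity and are screened next for direct RNA-RNA binding.
#'
#' @inheritParams cis_candidates
#' @return A tibble `lncrna_id`, `mrna_id`, `r`, `p_value`, with the number
#'   of pairs dropped for missing annotation in attribute `n_dropped`.
#' @export
trans_candidates <- function(edges, features) {
  features <- check_features(features)
  chrom <- setNames(features$chromosome, features$feature_id)
  keep <- edges$lncrna_id %in% names(chrom) & edges$mrna_id %in% names(chrom)
  out <- edges[keep, , drop = FALSE] |>
    filter(chrom[.data$lncrna_id] != chrom[.data$mrna_id]) |>
    select("lncrna_id", "mrna_id", "r", "p_value") |>
    arrange(.data$lncrna_id, .data$mrna_id)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Duplex-binding screen of trans candidates
#'
#' Aligns each candidate lncRNA against its mRNA partner with the duplex
#' engine and keeps pairs whose hybridizing core — the minimum-energy
#' contiguous segment of the best local alignment — pairs at least
#' `min_paired` bases directly and has free energy at or below `max_energy`
#' (both boundaries inclusive). Candidates lacking a sequence are dropped
#' and counted.
#'
#' @param candidates Output of [trans_candidates()].
#' @param transcripts Named RNA sequence vector for both lncRNAs and mRNAs.
#' @param params A [duplex_params()] object.
#' @param min_paired Minimum number of directly paired bases (default 10).
#' @param max_energy Maximum duplex free energy (default -50).
#' @return A tibble of passing duplex hits with the co-expression columns
#'   carried along.
#' @export
trans_binding_screen <- function(candidates, transcripts,
                                 params = duplex_params(),
                                 min_paired = 10, max_energy = -50) {
  transcripts <- clean_rna_set(transcripts, "transcript sequences")
  have <- candidates$lncrna_id %in% names(transcripts) &
    candidates$mrna_id %in% names(transcripts)
  n_dropped <- sum(!have)
  candidates <- candidates[have, , drop = FALSE]
  hits <- purrr::pmap(candidates, function(lncrna_id, mrna_id, r, p_value, ...) {
    h <- duplex_align(transcripts[[lncrna_id]], transcripts[[mrna_id]],
                      params, query_id = lncrna_id, target_id = mrna_id)
    if (nrow(h) == 0) return(NULL)
    core <- duplex_core(h)
    if (core$n_paired >= min_paired && core$energy <= max_energy) {
      # the screened and ranked energy is the hybridizing core's
      mutate(h, energy = core$energy, core_paired = core$n_paired,
             r = r, p_value = p_value)
    } else NULL
  }) |> purrr::list_rbind()
  if (is.null(hits) || nrow(hits) == 0) {
    hits <- mutate(empty_hits(), core_paired = integer(), r = double(),
                   p_value = double())
  }
  hits <- rename(hits, lncrna_id = "query_id", mrna_id = "target_id")
  attr(hits, "n_dropped") <- n_dropped
  hits
}

#' Top trans-regulation network edges
#'
#' Ranks screened trans hits by binding free energy from smallest (most
#' negative, strongest) to largest, breaking ties by descending paired
#' bases, then lexicographic ids, and keeps the first `n` edges.
#'
#' @param hits Output of [trans_binding_screen()].
#' @param n Maximum number of edges (default 200).
#' @return At most `n` hits, ranked.
#' @export
top_trans_network <- function(hits, n = 200) {
  hits |>
    arrange(.data$energy, desc(.data$paired_bases), .data$lncrna_id,
            .data$mrna_id) |>
    slice_head(n = n)
}
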