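#' Duplex alignment scoring parameters
#'
#' Scoring constants for the RNA-RNA local complementarity engine. The
#' substitution scores follow the miranda tradition: Watson-Crick pair +5,
#' G:U wobble +1, mismatch -3, affine gaps -9/-4, and pair scores inside the
#' query seed region (positions 2-8 from the 5' end) scaled by 4. The two
#' published screening regimes differ only in thresholds: miRNA-site calling
#' uses `score >= 140` and `energy <= -20` (both inclusive); the trans
#' lncRNA-target screen uses `paired bases >= 10` and `energy <= -50`.
#'
#' @param match_score,gu_wobble_score,mismatch_score Pair scores.
#' @param gap_open,gap_extend Affine gap penalties (negative).
#' @param seed_start,seed_end Query seed region, 1-based inclusive.
#' @param seed_scale Multiplier applied to pair scores inside the seed.
#' @param score_threshold,energy_threshold Default reporting thresholds
#'   (miRNA regime).
#' @return A `duplex_params` list.
#' @export
duplex_params <- function(match_score = 5, gu_wobble_score = 1,
                          mismatch_score = -3, gap_open = -9,
                          gap_extend = -4, seed_start = 2, seed_end = 8,
                          seed_scale = 4, score_threshold = 140,
                          energy_threshold = -20) {
  stopifnot(match_score > 0, mismatch_score < 0, gap_open < 0,
            gap_extend < 0, seed_scale > 0, seed_start <= seed_end,
            is.finite(score_threshold), is.finite(energy_threshold))
  structure(list(match_score = match_score,
                 gu_wobble_score = gu_wobble_score,
                 mismatch_score = mismatch_score,
                 gap_open = gap_open, gap_extend = gap_extend,
                 seed_start = seed_start, seed_end = seed_end,
                 seed_scale = seed_scale,
                 score_threshold = score_threshold,
                 energy_threshold = energy_threshold),
            class = "duplex_params")
}

#' Reduced nearest-neighbor stack energy table
#'
#' Free-energy contributions (kcal/mol scale) for two adjacent base pairs in
#' a duplex, keyed by the pair types of the stack. The table is a reduced
#' nearest-neighbor set: Watson-Crick stacks depend on how many of the two
#' pairs are G:C (-1.1 for none, -2.1 for one, -3.3 for two), and stacks
#' involving a G:U wobble are weaker (-1.0, or -0.5 when both pairs are
#' wobbles). Pair types are written query-base then target-base.
#'
#' @return A tibble with columns `pair1`, `pair2`, `energy`.
#' @export
stack_energy_table <- function() {
  pairs <- c("AU", "UA", "GC", "CG", "GU", "UG")
  grid <- expand.grid(pair1 = pairs, pair2 = pairs,
                      stringsAsFactors = FALSE)
  tibble(pair1 = grid$pair1, pair2 = grid$pair2,
         energy = mapply(stack_energy_one, grid$pair1, grid$pair2,
                         USE.NAMES = FALSE))
}

stack_energy_one <- function(p1, p2) {
  gu <- c("GU", "UG")
  if (p1 %in% gu && p2 %in% gu) return(-0.5)
  if (p1 %in% gu || p2 %in% gu) return(-1.0)
  n_gc <- (p1 %in% c("GC", "CG")) + (p2 %in% c("GC", "CG"))
  c(-1.1, -2.1, -3.3)[n_gc + 1]
}

# per-column decomposition of an alignment: query char, target char, bond
alignment_columns <- function(hit) {
  q <- strsplit(hit$align_query, "")[[1]]
  b <- strsplit(hit$align_bond, "")[[1]]
  t <- strsplit(hit$align_target, "")[[1]]
  tibble(q = q, t = t, paired = b %in% c("|", ":"))
}

# energy-optimal contiguous sub-duplex of an alignment: the sequence of
# events between successive paired columns (a stack energy when adjacent,
# a fixed +4 interior-loop penalty otherwise) is scanned for its
# minimum-sum contiguous segment; returns that energy (capped at 0) and
# the number of paired columns the segment spans
duplex_core <- function(hit) {
  if (is.data.frame(hit)) {
    stopifnot(nrow(hit) == 1)
    hit <- as.list(hit)
  }
  cols <- alignment_columns(hit)
  paired_idx <- which(cols$paired)
  np <- length(paired_idx)
  if (np == 0) return(list(energy = 0, n_paired = 0L))
  if (np == 1) return(list(energy = 0, n_paired = 1L))
  pair_type <- paste0(cols$q, cols$t)
  events <- vapply(seq_len(np - 1), function(k) {
    i <- paired_idx[k]; j <- paired_idx[k + 1]
    if (j == i + 1) stack_energy_one(pair_type[i], pair_type[j]) else 4
  }, numeric(1))
  best <- 0; best_len <- 0L
  cur <- 0; cur_start <- 1L
  for (k in seq_along(events)) {
    if (cur > 0) { cur <- 0; cur_start <- k }
    cur <- cur + events[k]
    if (cur < best) { best <- cur; best_len <- k - cur_start + 1L }
  }
  if (best >= 0) return(list(energy = 0, n_paired = 1L))
  list(energy = best, n_paired = best_len + 1L)
}

#' Duplex free energy of an alignment
#'
#' Additive estimate over the aligned duplex: each stack of two adjacent
#' paired columns contributes its [stack_energy_table()] entry; every
#' interior loop (a maximal run of unpaired or gapped columns between two
#' paired columns) contributes a fixed +4 penalty. The total is capped at
#' 0, so an isolated pair has energy 0 and every duplex energy is
#' non-positive. This whole-alignment energy is the right summary for a
#' short query such as a miRNA, whose reported alignment is the site
#' duplex itself; the trans screen for long RNA pairs instead evaluates
#' the minimum-energy contiguous segment of the alignment (the hybridizing
#' core — see [trans_binding_screen()]), because best-scoring local
#' alignments of two long molecules are patchworks of short stacks whose
#' loop penalties would wash out any genuine core.
#'
#' @param hit A one-row duplex hit (from [duplex_align()]) carrying the
#'   alignment strings.
#' @return The energy (a single non-positive number).
#' @export
duplex_energy <- function(hit) {
  if (is.data.frame(hit)) {
    stopifnot(nrow(hit) == 1)
    hit <- as.list(hit)
  }
  cols <- alignment_columns(hit)
  paired_idx <- which(cols$paired)
  if (length(paired_idx) < 2) return(0)
  pair_type <- paste0(cols$q, cols$t)
  e <- 0
  for (k in seq_len(length(paired_idx) - 1)) {
    i <- paired_idx[k]; j <- paired_idx[k + 1]
    if (j == i + 1) {
      e <- e + stack_energy_one(pair_type[i], pair_type[j])
    } else {
      e <- e + 4 # interior loop penalty
    }
  }
  min(e, 0)
}

empty_hits <- function() {
  tibble(query_id = character(), target_id = character(), score = double(),
         energy = double(), paired_bases = integer(),
         q_start = integer(), q_end = integer(),
         t_start = integer(), t_end = integer(),
         align_query = character(), align_bond = character(),
         align_target = character())
}

#' Local RNA-RNA complementarity alignment
#'
#' Smith-Waterman-style local alignment of a query RNA against the reverse
#' orientation of a target RNA, scored by base-pairing complementarity
#' (A:U/G:C match, G:U wobble, affine gaps, seed-region scaling — see
#' [duplex_params()]). Spans are reported on each molecule's own 5'->3'
#' coordinates, 1-based inclusive; the aligned target string is shown
#' 3'->5' so paired bases line up column-wise.
#'
#' @param query,target RNA sequences (strings over A/C/G/U; length >= 8).
#'   DNA `T` is accepted and transcribed to `U`.
#' @param params A [duplex_params()] object.
#' @param query_id,target_id Optional ids carried into the result.
#' @return A tibble with 0 rows (no positive-scoring duplex) or 1 row:
#'   `score`, `energy`, `paired_bases`, spans, and alignment strings.
#' @examples
#' mir <- "ACGUACGUACGUACGUACGUAC"
#' hit <- duplex_align(mir, paste0("GGGG", rna_reverse_complement(mir), "GGGG"))
#' hit$score # 7 seed positions x 20 + 15 x 5 = 215
#' @export
duplex_align <- function(query, target, params = duplex_params(),
                         query_id = "query", target_id = "target") {
  query <- clean_rna(query, "query")
  target <- clean_rna(target, "target")
  if (nchar(query) < 8 || nchar(target) < 8) {
    abort("sequences must be at least 8 nt long")
  }
  res <- .duplex_align_cpp(query, target, params$match_score,
                           params$gu_wobble_score, params$mismatch_score,
                           params$gap_open, params$gap_extend,
                           params$seed_start, params$seed_end,
                           params$seed_scale)
  if (isTRUE(res$empty)) return(empty_hits())
  hit <- tibble(query_id = query_id, target_id = target_id,
                score = res$score, energy = NA_real_,
                paired_bases = res$paired_bases,
                q_start = res$q_start, q_end = res$q_end,
                t_start = res$t_start, t_end = res$t_end,
                align_query = res$align_query,
                align_bond = res$align_bond,
                align_target = res$align_target)
  hit$energy <- duplex_energy(hit)
  hit
}

#' Predict miRNA binding sites on lncRNAs
#'
#' Aligns every miRNA against every lncRNA with [duplex_align()] and reports
#' the pairs whose best duplex satisfies the miRNA-site regime:
#' `score >= score_min` and `energy <= energy_max`, both boundaries
#' inclusive.
#'
#' @param mirnas,lncrnas Named character vectors of RNA sequences (e.g. from
#'   [read_fasta_rna()]).
#' @param params A [duplex_params()] object.
#' @param score_min Minimum alignment score, inclusive (default 140).
#' @param energy_max Maximum duplex energy, inclusive (default -20).
#' @return A tibble of passing pairs: `mirna_id`, `lncrna_id`, plus the hit
#'   columns of [duplex_align()].
#' @export
predict_mirna_lncrna <- function(mirnas, lncrnas, params = duplex_params(),
                                 score_min = 140, energy_max = -20) {
  if (length(mirnas) == 0 || length(lncrnas) == 0) {
    abort("empty input sequence set")
  }
  mirnas <- clean_rna_set(mirnas, "miRNA sequences")
  lncrnas <- clean_rna_set(lncrnas, "lncRNA sequences")
  hits <- purrr::map(names(mirnas), function(mi) {
    purrr::map(names(lncrnas), function(ln) {
      h <- duplex_align(mirnas[[mi]], lncrnas[[ln]], params,
                        query_id = mi, target_id = ln)
      if (nrow(h) == 0) return(NULL)
      if (h$score >= score_min && h$energy <= energy_max) h else NULL
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  if (is.null(hits) || nrow(hits) == 0) return(empty_hits() |>
    rename(mirna_id = "query_id", lncrna_id = "target_id"))
  rename(hits, mirna_id = "query_id", lncrna_id = "target_id")
}

#' miRNA-mRNA interaction pairs
#'
#' Two sources are supported. Mode A (preferred): a curated interaction
#' table — a validated-target resource stand-in — with columns `mirna_id`
#' and `mrna_id`, passed through after id harmonization against the
#' expressed genes. Mode B (predictive fallback when no table is available):
#' an exact seed match, i.e. the reverse complement of miRNA positions 2-8
#' found verbatim in the 3' region (final third, at least 60 nt) of the mRNA
#' sequence.
#'
#' @param table Optional curated data frame with `mirna_id`, `mrna_id`.
#' @param mirnas,mrnas Named RNA sequence vectors (mode B).
#' @param expressed Optional character vector of expressed mRNA ids; pairs
#'   whose mRNA is absent are dropped (count reported as an attribute).
#' @param seed_start,seed_end Seed region on the miRNA (default 2-8).
#' @return A tibble `mirna_id`, `mrna_id` (mode B adds the site position).
#' @export
mirna_mrna_pairs <- function(table = NULL, mirnas = NULL, mrnas = NULL,
                             expressed = NULL, seed_start = 2, seed_end = 8) {
  if (is.null(table) && (is.null(mirnas) || is.null(mrnas))) {
    abort("provide either a curated `table` or both `mirnas` and `mrnas`")
  }
  if (!is.null(table)) {
    stopifnot(all(c("mirna_id", "mrna_id") %in% names(table)))
    out <- distinct(as_tibble(table), .data$mirna_id, .data$mrna_id)
  } else {
    mirnas <- clean_rna_set(mirnas, "miRNA sequences")
    mrnas <- clean_rna_set(mrnas, "mRNA sequences")
    out <- purrr::map(names(mirnas), function(mi) {
      seed <- substr(mirnas[[mi]], seed_start, seed_end)
      probe <- rna_revcomp(seed)
      purrr::map(names(mrnas), function(mr) {
        s <- mrnas[[mr]]
        region_start <- max(1, nchar(s) - max(60, ceiling(nchar(s) / 3)) + 1)
        pos <- regexpr(probe, substr(s, region_start, nchar(s)), fixed = TRUE)
        if (pos < 0) return(NULL)
        tibble(mirna_id = mi, mrna_id = mr,
               site_start = region_start + as.integer(pos) - 1L)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
    if (is.null(out)) out <- tibble(mirna_id = character(),
                                    mrna_id = character(),
                                    site_start = integer())
  }
  dropped <- 0L
  if (!is.null(expressed)) {
    keep <- out$mrna_id %in% expressed
    dropped <- sum(!keep)
    out <- out[keep, , drop = FALSE]
  }
  attr(out, "n_dropped") <- dropped
  out
}

#' Reverse complement of an RNA sequence
#'
#' @param x RNA string(s) over A/C/G/U (T accepted, transcribed).
#' @return The antiparallel complement, 5'->3'.
#' @export
rna_reverse_complement <- function(x) {
  rna_revcomp(vapply(x, clean_rna, character(1), USE.NAMES = FALSE))
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Shuffles a sequence while preserving its exact dinucleotide composition
#' (random Eulerian walk on the dinucleotide transition multigraph, with
#' rejection of incomplete walks). Used to build matched negative controls
#' for binding-site specificity checks.
#'
#' @param x An RNA string.
#' @param max_tries Retry budget for the rejection step.
#' @return A shuffled string with identical dinucleotide counts.
#' @export
shuffle_dinucleotide <- function(x, max_tries = 200) {
  chars <- strsplit(clean_rna(x), "")[[1]]
  n <- length(chars)
  if (n < 3) return(paste(chars, collapse = ""))
  edges <- split(chars[-1], chars[-n]) # outgoing edges per vertex
  for (try in seq_len(max_tries)) {
    bag <- lapply(edges, sample)
    walk <- character(n)
    walk[1] <- chars[1]
    ok <- TRUE
    for (i in 2:n) {
      v <- walk[i - 1]
      out <- bag[[v]]
      if (is.null(out) || length(out) == 0) { ok <- FALSE; break }
      walk[i] <- out[1]
      bag[[v]] <- out[-1]
    }
    if (ok) return(paste(walk, collapse = ""))
  }
  # fall back to the identity (preserves composition trivially)
  paste(chars, collapse = "")
}
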