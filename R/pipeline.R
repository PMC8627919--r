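#' Pipeline configuration
#'
#' All screening thresholds of the published protocol, with their printed
#' defaults: differential expression at raw `p < 0.05` and `|log2FC| > 1`;
#' enrichment at `count >= 3` and adjusted `p < 0.05`; co-expression at
#' `|r| > 0.8` and `p < 0.05` with the top 500 pairs networked; cis within
#' 100 kb; trans binding at `>= 10` paired bases and energy `<= -50` with
#' the top 200 edges networked; miRNA sites at `score >= 140` and energy
#' `<= -20`; ceRNA triples at positive correlation above 0.8, narrowed to 0.95;
#' hub tables report the top 5 per node class.
#'
#' @param de_p,de_lfc Differential-expression screen.
#' @param enrich_min_count,enrich_padj Enrichment screen.
#' @param coexpr_r,coexpr_p,coexpr_top Co-expression screen and network size.
#' @param cis_window Cis window in bases.
#' @param trans_min_paired,trans_max_energy,trans_top Trans binding screen
#'   and network size.
#' @param mirna_score_min,mirna_energy_max miRNA-site regime.
#' @param triple_r,strict_r ceRNA assembly and strict narrowing thresholds.
#' @param degree_top_k Hub rows per node class.
#' @param pseudocount Pseudocount for display fold changes.
#' @param rng_seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A `cerna_config` list.
#' @export
cerna_config <- function(de_p = 0.05, de_lfc = 1,
                         enrich_min_count = 3, enrich_padj = 0.05,
                         coexpr_r = 0.8, coexpr_p = 0.05, coexpr_top = 500,
                         cis_window = 100000,
                         trans_min_paired = 10, trans_max_energy = -50,
                         trans_top = 200,
                         mirna_score_min = 140, mirna_energy_max = -20,
                         triple_r = 0.8, strict_r = 0.95,
                         degree_top_k = 5, pseudocount = 1, rng_seed = 1) {
  structure(list(de_p = de_p, de_lfc = de_lfc,
                 enrich_min_count = enrich_min_count,
                 enrich_padj = enrich_padj,
                 coexpr_r = coexpr_r, coexpr_p = coexpr_p,
                 coexpr_top = coexpr_top, cis_window = cis_window,
                 trans_min_paired = trans_min_paired,
                 trans_max_energy = trans_max_energy, trans_top = trans_top,
                 mirna_score_min = mirna_score_min,
                 mirna_energy_max = mirna_energy_max,
                 triple_r = triple_r, strict_r = strict_r,
                 degree_top_k = degree_top_k, pseudocount = pseudocount,
                 rng_seed = as.integer(rng_seed)),
            class = "cerna_config")
}

#' Run the full ceRNA pipeline
#'
#' Executes the stages in protocol order on an in-memory study (as returned
#' by [simulate_cerna_study()], or assembled from files with the package's
#' readers): sample QC, differential expression, lncRNA-mRNA co-expression,
#' enrichment of the differential mRNAs and guilt-by-association annotation
#' of the differential lncRNAs, cis and trans target analysis, miRNA-site
#' prediction, and ceRNA network assembly with degree ranking. All stages
#' are deterministic; when `out_dir` is given every stage table is written
#' as TSV (networks additionally as SIF/GraphML) together with a JSON run
#' manifest recording input hashes, thresholds, seed, and per-stage row
#' counts.
#'
#' @param study A list with `counts`, `samples`, `features`, `transcripts`,
#'   `mirnas`, and optionally `mirna_targets` and `term_sets`.
#' @param config A [cerna_config()].
#' @param out_dir Optional output directory.
#' @return A list of stage results (`qc`, `de`, `edges`, `edges_top`,
#'   `enrichment`, `lncrna_annotation`, `cis`, `trans`, `trans_top`,
#'   `lnc_mi`, `mi_m`, `triples`, `triples_strict`, `network`, `degree`)
#'   plus the `manifest`.
#' @export
run_cerna_pipeline <- function(study, config = cerna_config(),
                               out_dir = NULL) {
  stopifnot(inherits(config, "cerna_config"))
  for (f in c("counts", "samples", "features", "transcripts", "mirnas")) {
    if (is.null(study[[f]])) abort(paste0("study is missing `", f, "`"))
  }
  msg <- function(stage, ...) message("[", stage, "] ", ...)
  counts <- study$counts; samples <- study$samples
  features <- as_tibble(study$features)

  msg("qc", "sample correlation and PCA")
  qc <- qc_samples(counts, samples)

  msg("de", "normalization and NB Wald test")
  de <- diff_expression(counts, samples, p_threshold = config$de_p,
                        lfc_threshold = config$de_lfc,
                        pseudocount = config$pseudocount)
  det <- tidy(de)
  biotype <- setNames(features$biotype, features$feature_id)
  det$biotype <- unname(biotype[det$gene_id])
  dels <- det$gene_id[det$direction != "ns" & det$biotype %in% "lncRNA"]
  dems <- det$gene_id[det$direction != "ns" & det$biotype %in% "mRNA"]
  msg("de", length(dels), " DELs, ", length(dems), " DEMs")
  if (length(dels) == 0 || length(dems) == 0) {
    warn("no differential lncRNAs and/or mRNAs; downstream outputs are empty")
  }

  expr <- normalized_log_expr(counts, de$size_factors)
  lnc_expr <- expr[expr$gene_id %in% dels, , drop = FALSE]
  mrna_expr <- expr[expr$gene_id %in% dems, , drop = FALSE]

  msg("coexpress", "DEL x DEM Pearson correlation")
  edges_all <- if (length(dels) && length(dems)) {
    correlate_pairs(lnc_expr, mrna_expr)
  } else {
    tibble(lncrna_id = character(), mrna_id = character(), r = double(),
           p_value = double(), sign = character())
  }
  edges <- screen_edges(edges_all, r_threshold = config$coexpr_r,
                        p_threshold = config$coexpr_p)
  edges_top <- top_pairs(edges, n = config$coexpr_top)
  msg("coexpress", nrow(edges), " passing pairs")

  enr <- NULL; annot <- NULL
  if (!is.null(study$term_sets)) {
    msg("enrich", "hypergeometric enrichment of DEMs")
    universe <- intersect(unique(study$term_sets$gene_id), counts[[1]])
    enr <- suppressWarnings(
      hypergeom_enrich(dems, study$term_sets, universe)) |>
      screen_terms(min_count = config$enrich_min_count,
                   padj_threshold = config$enrich_padj)
    msg("enrich", nrow(enr), " enriched terms")
    annot <- annotate_lncrna(edges, study$term_sets, universe,
                             min_count = config$enrich_min_count,
                             padj_threshold = config$enrich_padj)
    annot <- annot %||% tibble()
  }

  msg("cistrans", "cis window and trans duplex screens")
  cis <- cis_candidates(features, edges, window = config$cis_window)
  trans <- trans_candidates(edges, features)
  trans_hits <- trans_binding_screen(trans, study$transcripts,
                                     min_paired = config$trans_min_paired,
                                     max_energy = config$trans_max_energy)
  trans_top <- top_trans_network(trans_hits, n = config$trans_top)
  msg("cistrans", nrow(cis), " cis pairs, ", nrow(trans_hits),
      " trans binding pairs")

  msg("duplex", "miRNA site prediction on DELs")
  del_seqs <- study$transcripts[intersect(dels, names(study$transcripts))]
  lnc_mi <- if (length(del_seqs)) {
    predict_mirna_lncrna(study$mirnas, del_seqs,
                         score_min = config$mirna_score_min,
                         energy_max = config$mirna_energy_max)
  } else {
    tibble(mirna_id = character(), lncrna_id = character())
  }
  mi_m <- if (!is.null(study$mirna_targets)) {
    mirna_mrna_pairs(table = study$mirna_targets, expressed = counts[[1]])
  } else {
    dem_seqs <- study$transcripts[intersect(dems, names(study$transcripts))]
    if (length(dem_seqs)) {
      mirna_mrna_pairs(mirnas = study$mirnas, mrnas = dem_seqs,
                       expressed = counts[[1]])
    } else {
      tibble(mirna_id = character(), mrna_id = character())
    }
  }

  msg("cerna", "triple assembly and network")
  triples <- assemble_triples(lnc_mi, mi_m, edges,
                              r_threshold = config$triple_r)
  triples_strict <- strict_filter(triples, r_threshold = config$strict_r)
  network <- build_network(triples_strict,
                           directions = select(det, "gene_id", "direction"))
  degree <- degree_ranking(network, top_k = config$degree_top_k)
  msg("cerna", nrow(triples), " triples (", nrow(triples_strict),
      " after strict filter)")

  result <- list(qc = qc, de = de, edges = edges, edges_top = edges_top,
                 enrichment = enr, lncrna_annotation = annot, cis = cis,
                 trans = trans, trans_top = trans_top, lnc_mi = lnc_mi,
                 mi_m = mi_m, triples = triples,
                 triples_strict = triples_strict, network = network,
                 degree = degree, config = config)
  result$manifest <- list(
    thresholds = unclass(config),
    stages = list(
      n_samples = nrow(samples), n_features = nrow(counts),
      n_dels = length(dels), n_dems = length(dems),
      n_edges = nrow(edges), n_edges_top = nrow(edges_top),
      n_enriched_terms = if (is.null(enr)) NA_integer_ else nrow(enr),
      n_cis = nrow(cis), n_trans_candidates = nrow(trans),
      n_trans_hits = nrow(trans_hits), n_lnc_mi = nrow(lnc_mi),
      n_mi_m = nrow(mi_m), n_triples = nrow(triples),
      n_triples_strict = nrow(triples_strict),
      n_network_nodes = nrow(network$nodes),
      n_network_edges = nrow(network$edges)))
  if (!is.null(out_dir)) {
    result$manifest$files <- write_pipeline_outputs(result, out_dir)
  }
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(tidy(result$de), p("de_results.tsv"))
  readr::write_tsv(tidy(result$qc), p("qc_pca_scores.tsv"))
  readr::write_tsv(as_tibble(result$qc$correlation, rownames = "sample"),
                   p("qc_sample_correlation.tsv"))
  readr::write_tsv(result$edges, p("coexpression_edges.tsv"))
  readr::write_tsv(result$edges_top, p("coexpression_top.tsv"))
  if (!is.null(result$enrichment)) {
    readr::write_tsv(select(result$enrichment, -"hits"),
                     p("enrichment.tsv"))
  }
  if (!is.null(result$lncrna_annotation) &&
      nrow(result$lncrna_annotation) > 0) {
    readr::write_tsv(select(result$lncrna_annotation, -"hits"),
                     p("lncrna_annotation.tsv"))
  }
  readr::write_tsv(result$cis, p("cis_pairs.tsv"))
  readr::write_tsv(select(result$trans_top, -"align_query", -"align_bond",
                          -"align_target"), p("trans_network.tsv"))
  readr::write_tsv(result$triples, p("cerna_triples.tsv"))
  readr::write_tsv(result$triples_strict, p("cerna_triples_strict.tsv"))
  readr::write_tsv(result$degree, p("degree_ranking.tsv"))
  write_sif(result$network$edges, p("cerna_network.sif"))
  write_graphml(result$network, p("cerna_network.graphml"))
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- result$manifest
  manifest$files <- tibble(file = basename(files),
                           md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, p("manifest.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  manifest$files
}
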