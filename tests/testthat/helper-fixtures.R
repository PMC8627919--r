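# shared fixtures, generated in code and cached for the whole test run

.fixture_cache <- new.env(parent = emptyenv())

# the default synthetic study (the dataset the recovery checks run on)
default_study <- function() {
  if (is.null(.fixture_cache$study)) {
    .fixture_cache$study <- simulate_cerna_study(simulation_config())
  }
  .fixture_cache$study
}

# all lncRNA x mRNA co-expression edges of the default study
default_edges <- function() {
  if (is.null(.fixture_cache$edges)) {
    study <- default_study()
    expr <- normalized_log_expr(study$counts)
    .fixture_cache$edges <- correlate_pairs(
      expr[grepl("^lnc", expr$gene_id), ],
      expr[grepl("^gene", expr$gene_id), ])
  }
  .fixture_cache$edges
}

# miRNA-site predictions over every lncRNA of the default study
default_lnc_mi <- function() {
  if (is.null(.fixture_cache$lnc_mi)) {
    study <- default_study()
    .fixture_cache$lnc_mi <- predict_mirna_lncrna(
      study$mirnas,
      study$transcripts[grepl("^lnc", names(study$transcripts))])
  }
  .fixture_cache$lnc_mi
}

# a small study for fast pipeline tests
small_config <- function(seed = 5) {
  simulation_config(n_genes = 250, n_lncrnas = 50, n_mirnas = 6,
                    coexpression_block_count = 2,
                    coexpression_block_size = 12,
                    rng_seed = seed)
}

# a tiny two-group count tibble built by hand
toy_counts <- function() {
  tibble::tibble(
    gene_id = paste0("g", 1:5),
    WT_1 = c(10, 100, 30, 0, 7), WT_2 = c(12, 110, 28, 0, 9),
    WT_3 = c(11, 95, 33, 0, 8),
    KO_1 = c(40, 101, 31, 0, 8), KO_2 = c(43, 99, 29, 0, 7),
    KO_3 = c(38, 104, 35, 0, 9))
}

toy_samples <- function() {
  tibble::tibble(sample = c("WT_1", "WT_2", "WT_3", "KO_1", "KO_2", "KO_3"),
                 group = rep(c("control", "knockout"), each = 3))
}

pair_key <- function(a, b) paste(a, b)
triple_key <- function(d) paste(d$lncrna_id, d$mirna_id, d$mrna_id)
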