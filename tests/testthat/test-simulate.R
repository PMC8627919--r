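test_that("configuration is validated", {
  expect_error(simulation_config(n_genes = 0), "count")
  expect_error(simulation_config(planted_de_fraction = 1.2), "\\[0,1\\]")
  expect_error(simulation_config(nb_dispersion = -1), "dispersion")
  expect_error(simulation_config(n_genes = 10, n_lncrnas = 4,
                                 coexpression_block_count = 3,
                                 coexpression_block_size = 20),
               "exceed")
})

test_that("count simulation honours the design and plants nothing when asked not to", {
  cfg <- simulation_config(n_genes = 100, n_lncrnas = 20, n_mirnas = 4,
                           planted_de_fraction = 0,
                           coexpression_block_count = 1,
                           coexpression_block_size = 8, rng_seed = 3)
  sim <- simulate_counts(cfg)
  expect_equal(nrow(sim$truth$de), 0)
  expect_equal(ncol(sim$counts) - 1, 6)
  expect_equal(sim$samples$group, rep(c("control", "knockout"), each = 3))
  expect_true(all(sim$counts[-1] >= 0))
  expect_true(all(sapply(sim$counts[-1], function(x) all(x == round(x)))))
})

test_that("counts follow the stated negative-binomial mean-variance law", {
  cfg <- simulation_config(n_genes = 2000, n_lncrnas = 2, nb_dispersion = 0.1,
                           planted_de_fraction = 0,
                           coexpression_block_count = 1,
                           coexpression_block_size = 8, rng_seed = 17)
  sim <- simulate_counts(cfg)
  m <- as.matrix(sim$counts[-1])
  in_block <- sim$counts$feature_id %in% sim$truth$blocks$feature_id
  m <- m[!in_block, ]
  gene_mean <- rowMeans(m)
  gene_var <- apply(m, 1, var)
  expected <- gene_mean + 0.1 * gene_mean^2
  ratio <- mean(gene_var) / mean(expected)
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.15)
})

test_that("planted fold changes are recoverable from group means", {
  study <- default_study()
  m <- as.matrix(study$counts[-1])
  rownames(m) <- study$counts$feature_id
  ko <- study$samples$sample[study$samples$group == "knockout"]
  wt <- study$samples$sample[study$samples$group == "control"]
  de <- study$truth$de
  obs <- log2(rowMeans(m[de$feature_id, ko, drop = FALSE]) /
                rowMeans(m[de$feature_id, wt, drop = FALSE]))
  recovered <- mean(sign(de$log2fc) * obs)
  expect_gt(recovered, 0.9 * study$config$planted_log2fc_magnitude)
  expect_lt(recovered, 1.1 * study$config$planted_log2fc_magnitude)
})

test_that("co-expression blocks correlate strongly at the default setting", {
  study <- default_study()
  expr <- normalized_log_expr(study$counts)
  m <- as.matrix(expr[-1])
  rownames(m) <- expr$gene_id
  rs <- unlist(lapply(split(study$truth$blocks$feature_id,
                            study$truth$blocks$block_id), function(ids) {
    r <- cor(t(m[ids, ]))
    r[upper.tri(r)]
  }))
  expect_gt(median(abs(rs)), 0.8)
})

test_that("the generator is deterministic in config and seed", {
  cfg <- small_config(seed = 9)
  a <- simulate_cerna_study(cfg)
  b <- simulate_cerna_study(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$features, b$features)
  expect_identical(a$transcripts, b$transcripts)
  expect_identical(a$mirnas, b$mirnas)
  expect_identical(a$term_sets, b$term_sets)
  expect_identical(a$truth, b$truth)
  c <- simulate_cerna_study(small_config(seed = 10))
  expect_false(identical(a$counts, c$counts))
})

test_that("annotation places planted cis pairs inside the window and others freely", {
  study <- default_study()
  f <- study$features
  expect_true(all(f$start < f$end))
  cis <- study$truth$cis_pairs
  expect_gt(nrow(cis), 0)
  for (k in seq_len(nrow(cis))) {
    a <- f[f$feature_id == cis$lncrna_id[k], ]
    b <- f[f$feature_id == cis$gene_id[k], ]
    expect_identical(a$chromosome, b$chromosome)
    gap <- max(0, max(a$start, b$start) - min(a$end, b$end))
    expect_lte(gap, 100000)
  }
  cfg0 <- simulation_config(n_genes = 100, n_lncrnas = 20, n_mirnas = 4,
                            cis_pair_fraction = 0,
                            coexpression_block_count = 1,
                            coexpression_block_size = 8, rng_seed = 2)
  sim0 <- simulate_counts(cfg0)
  ann0 <- simulate_annotation(cfg0, sim0$truth)
  expect_equal(nrow(ann0$truth$cis_pairs), 0)
})

test_that("planted miRNA sites are perfect complements that clear the score regime", {
  study <- default_study()
  sites <- study$truth$sites
  expect_gt(nrow(sites), 0)
  for (k in head(seq_len(nrow(sites)), 10)) {
    seq <- study$transcripts[[sites$lncrna_id[k]]]
    window <- substr(seq, sites$site_start[k], sites$site_end[k])
    expect_identical(window,
                     rna_reverse_complement(study$mirnas[[sites$mirna_id[k]]]))
    hit <- duplex_align(study$mirnas[[sites$mirna_id[k]]], seq)
    expect_gte(hit$score, 140)
    expect_lte(hit$energy, -20)
  }
  cfg0 <- simulation_config(n_genes = 50, n_lncrnas = 10, n_mirnas = 3,
                            planted_site_fraction = 0,
                            coexpression_block_count = 1,
                            coexpression_block_size = 8, rng_seed = 4)
  sim0 <- simulate_counts(cfg0)
  seqs0 <- simulate_sequences(cfg0, sim0$truth)
  expect_equal(nrow(seqs0$truth$sites), 0)
})

test_that("every planted id exists in the generated dataset", {
  study <- default_study()
  ids <- study$counts$feature_id
  truth <- study$truth
  expect_true(all(truth$de$feature_id %in% ids))
  expect_true(all(truth$blocks$feature_id %in% ids))
  expect_true(all(truth$cis_pairs$lncrna_id %in% ids))
  expect_true(all(truth$cis_pairs$gene_id %in% ids))
  expect_true(all(truth$sites$lncrna_id %in% names(study$transcripts)))
  expect_true(all(truth$sites$mirna_id %in% names(study$mirnas)))
  # planted triples decompose into a planted site, a curated miRNA-mRNA
  # pair, and block co-membership of the lncRNA and mRNA
  tr <- truth$triples
  expect_true(all(pair_key(tr$mirna_id, tr$lncrna_id) %in%
                    pair_key(truth$sites$mirna_id, truth$sites$lncrna_id)))
  expect_true(all(pair_key(tr$mirna_id, tr$mrna_id) %in%
                    pair_key(truth$mirna_mrna$mirna_id,
                             truth$mirna_mrna$mrna_id)))
  blk <- setNames(truth$blocks$block_id, truth$blocks$feature_id)
  expect_true(all(blk[tr$lncrna_id] == blk[tr$mrna_id]))
})

test_that("a written study round-trips through the package readers", {
  dir <- withr::local_tempdir()
  study <- simulate_cerna_study(small_config(seed = 21), dir = dir)
  expect_identical(read_counts(study$files[["counts"]])$feature_id,
                   study$counts$feature_id)
  expect_equal(as.data.frame(read_counts(study$files[["counts"]])[-1]),
               as.data.frame(study$counts[-1]))
  ann <- read_annotation(study$files[["annotation"]])
  expect_equal(ann$start, study$features$start)
  expect_identical(read_fasta_rna(study$files[["transcripts"]]),
                   study$transcripts)
  expect_identical(read_fasta_rna(study$files[["mirnas"]]), study$mirnas)
  gmt <- read_gmt(study$files[["term_sets"]])
  expect_setequal(paste(gmt$term_id, gmt$gene_id),
                  paste(study$term_sets$term_id, study$term_sets$gene_id))
})
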