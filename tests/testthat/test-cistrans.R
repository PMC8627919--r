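feat <- function(id, chrom, start, end, biotype) {
  tibble::tibble(feature_id = id, chromosome = chrom, start = start,
                 end = end, strand = "+", biotype = biotype)
}

test_that("cis candidates apply distance, window boundary, and co-expression jointly", {
  features <- dplyr::bind_rows(
    feat("lncA", "chr1", 10000, 12000, "lncRNA"),
    feat("lncB", "chr1", 10000, 12000, "lncRNA"),
    feat("lncC", "chr1", 10000, 12000, "lncRNA"),
    feat("geneA", "chr1", 100000, 105000, "mRNA"),   # gap 88,000
    feat("geneB", "chr1", 112001, 115000, "mRNA"),   # gap 100,001
    feat("geneC", "chr1", 112000, 115000, "mRNA"))   # gap exactly 100,000
  edges <- tibble::tibble(
    lncrna_id = c("lncA", "lncB", "lncC"),
    mrna_id = c("geneA", "geneB", "geneC"),
    r = 0.9, p_value = 0.01, sign = "positive")
  out <- cis_candidates(features, edges)
  expect_equal(out$gene_id, c("geneA", "geneC"))
  expect_equal(out$distance, c(88000, 100000))
  # within the window but not co-expressed: absent
  out2 <- cis_candidates(features, edges[edges$lncrna_id != "lncA", ])
  expect_false("geneA" %in% out2$gene_id)
  # overlapping features have distance zero
  ovl <- dplyr::bind_rows(feat("lncD", "chr2", 500, 1500, "lncRNA"),
                          feat("geneD", "chr2", 1000, 2000, "mRNA"))
  e <- tibble::tibble(lncrna_id = "lncD", mrna_id = "geneD", r = 0.9,
                      p_value = 0.01, sign = "positive")
  expect_equal(cis_candidates(ovl, e)$distance, 0)
})

test_that("cis candidates equal a brute-force interval scan on random fixtures", {
  set.seed(41)
  for (rep in 1:3) {
    n_l <- 40; n_m <- 120
    features <- dplyr::bind_rows(
      feat(sprintf("lnc%03d", 1:n_l), sample(paste0("chr", 1:3), n_l, TRUE),
           s <- sample.int(5e5, n_l), s + sample.int(5e4, n_l), "lncRNA"),
      feat(sprintf("g%03d", 1:n_m), sample(paste0("chr", 1:3), n_m, TRUE),
           s2 <- sample.int(5e5, n_m), s2 + sample.int(5e4, n_m), "mRNA"))
    edges <- tibble::tibble(
      lncrna_id = sample(sprintf("lnc%03d", 1:n_l), 200, TRUE),
      mrna_id = sample(sprintf("g%03d", 1:n_m), 200, TRUE),
      r = 0.9, p_value = 0.01, sign = "positive") |> dplyr::distinct()
    got <- cis_candidates(features, edges)
    want <- brute_cis(features, edges)
    expect_equal(got$lncrna_id, want$lncrna_id)
    expect_equal(got$gene_id, want$gene_id)
    expect_equal(got$distance, want$distance)
  }
})

test_that("trans candidates are exactly the cross-chromosome co-expressed pairs", {
  features <- dplyr::bind_rows(
    feat("lncA", "chr1", 1, 1000, "lncRNA"),
    feat("geneA", "chr1", 5000, 9000, "mRNA"),
    feat("geneB", "chr2", 5000, 9000, "mRNA"))
  edges <- tibble::tibble(lncrna_id = "lncA",
                          mrna_id = c("geneA", "geneB"),
                          r = 0.9, p_value = 0.01, sign = "positive")
  out <- trans_candidates(edges, features)
  expect_equal(out$mrna_id, "geneB")
  # cis and trans are disjoint by construction
  cis <- cis_candidates(features, edges)
  expect_length(intersect(pair_key(cis$lncrna_id, cis$gene_id),
                          pair_key(out$lncrna_id, out$mrna_id)), 0)
  # no co-expression edge, never a candidate
  expect_equal(nrow(trans_candidates(edges[0, ], features)), 0)
})

test_that("the trans binding screen is conjunctive in paired bases and energy", {
  set.seed(43)
  # planted GC-rich perfect 20-mer complement inside random flanks:
  # the hybridizing core carries 19 all-GC stacks (energy -62.7)
  core <- paste(sample(c("G", "C"), 20, TRUE), collapse = "")
  lnc <- paste0(random_rna_str(100), core, random_rna_str(100))
  mrna <- paste0(random_rna_str(80),
                 cernakit::rna_reverse_complement(core),
                 random_rna_str(120))
  seqs <- c(lnc = lnc, mrna = mrna,
            bg1 = random_rna_str(500), bg2 = random_rna_str(500))
  cand <- tibble::tibble(lncrna_id = c("lnc", "bg1"),
                         mrna_id = c("mrna", "bg2"),
                         r = 0.9, p_value = 0.01)
  hits <- trans_binding_screen(cand, seqs)
  expect_equal(hits$lncrna_id, "lnc")
  expect_gte(hits$core_paired, 10)
  expect_lte(hits$energy, -50)

  # a perfect 9-pair GC duplex in non-pairing poly-A flanks (energy -26.4)
  # fails the >= 10 direct-pairing rule despite clearing a -20 energy bar
  core9 <- "GCGCGCGCG"
  seqs2 <- c(l = paste0(strrep("A", 50), core9, strrep("A", 50)),
             m = paste0(strrep("A", 50),
                        cernakit::rna_reverse_complement(core9),
                        strrep("A", 50)))
  cand2 <- tibble::tibble(lncrna_id = "l", mrna_id = "m", r = 0.9,
                          p_value = 0.01)
  expect_equal(nrow(trans_binding_screen(cand2, seqs2, min_paired = 10,
                                         max_energy = -20)), 0)
  h9 <- trans_binding_screen(cand2, seqs2, min_paired = 9, max_energy = -20)
  expect_equal(nrow(h9), 1)
  expect_equal(h9$energy, -26.4)
})

test_that("the trans network ranks energies from smallest to largest, capped", {
  hits <- tibble::tibble(
    lncrna_id = c("l1", "l2", "l3"), mrna_id = c("m1", "m2", "m3"),
    energy = c(-60, -90, -60), paired_bases = c(12, 15, 20))
  out <- top_trans_network(hits, n = 2)
  expect_equal(out$lncrna_id, c("l2", "l3")) # -90 first; tie by paired bases
  out5 <- top_trans_network(hits, n = 200)
  expect_equal(nrow(out5), 3)
  expect_equal(out5$energy, sort(hits$energy))
})
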