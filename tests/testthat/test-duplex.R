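test_that("a perfect miRNA complement scores exactly as the constants imply", {
  mir <- "ACGUACGUACGUACGUACGUAC" # 22 nt
  tgt <- paste0("GGGG", rna_reverse_complement(mir), "GGGG")
  hit <- duplex_align(mir, tgt)
  # 7 seed positions x 5 x 4 + 15 positions x 5
  expect_equal(hit$score, 215)
  expect_equal(hit$paired_bases, 22)
  expect_equal(c(hit$q_start, hit$q_end), c(1, 22))
  expect_lte(hit$energy, -20)
})

test_that("sequences with no complementarity yield no hit", {
  # poly-A query vs poly-A target: A:A never pairs
  expect_equal(nrow(duplex_align(strrep("A", 22), strrep("A", 50))), 0)
})

test_that("the engine equals an independent dense DP oracle on short sequences", {
  set.seed(53)
  p <- duplex_params()
  for (i in 1:60) {
    q <- random_rna_str(sample(8:12, 1))
    t <- random_rna_str(sample(8:12, 1))
    hit <- duplex_align(q, t, p)
    got <- if (nrow(hit) == 0) 0 else hit$score
    expect_equal(got, r_duplex_score(q, t, p))
  }
})

test_that("complementarity is symmetric under reversal when scoring is position-free", {
  set.seed(54)
  p <- duplex_params(seed_scale = 1)
  revstr <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  score0 <- function(h) if (nrow(h)) h$score else 0
  for (i in 1:15) {
    q <- random_rna_str(15); t <- random_rna_str(30)
    expect_equal(score0(duplex_align(q, t, p)),
                 score0(duplex_align(revstr(q), revstr(t), p)))
  }
})

test_that("duplex energy is the stack sum with loop penalties and a zero cap", {
  # perfect GC 10-mer: 9 stacks at -3.3
  h <- duplex_align("GCGCGCGCGC", rna_reverse_complement("GCGCGCGCGC"),
                    duplex_params(seed_scale = 1))
  expect_equal(h$energy, -29.7)
  # a single isolated pair has no stack: energy 0
  single <- list(align_query = "GAAAAAAA", align_bond = "|       ",
                 align_target = "CUUUUUUU")
  expect_equal(duplex_energy(single), 0)
  # monotone: longer perfect duplex of the same composition, lower energy
  e <- sapply(c(10, 14, 18), function(k) {
    s <- strrep("GC", k / 2)
    duplex_align(s, rna_reverse_complement(s),
                 duplex_params(seed_scale = 1))$energy
  })
  expect_true(all(diff(e) < 0))
  # table bounds: WC stacks within -0.9..-3.4, G:U stacks within -0.5..-1.5
  tab <- stack_energy_table()
  gu <- tab$pair1 %in% c("GU", "UG") | tab$pair2 %in% c("GU", "UG")
  expect_true(all(tab$energy[gu] >= -1.5 & tab$energy[gu] <= -0.5))
  expect_true(all(tab$energy[!gu] >= -3.4 & tab$energy[!gu] <= -0.9))
})

test_that("invalid symbols are rejected by name and DNA is transcribed", {
  expect_error(duplex_align("ACGUNACGUACG", "ACGUACGUACGU"), "N")
  # T is accepted as DNA and treated as U
  h1 <- duplex_align("ACGTACGTACGT", rna_reverse_complement("ACGUACGUACGU"))
  h2 <- duplex_align("ACGUACGUACGU", rna_reverse_complement("ACGUACGUACGU"))
  expect_equal(h1$score, h2$score)
})

test_that("miRNA site prediction applies inclusive thresholds to the best hit", {
  mir <- c(m1 = "ACGUACGUACGUACGUACGUAC")
  lnc <- c(l1 = paste0(random_rna_str(50), rna_reverse_complement(mir[[1]]),
                       random_rna_str(50)))
  hit <- duplex_align(mir[[1]], lnc[[1]])
  # boundary inclusive: thresholds equal to the achieved values still report
  expect_equal(nrow(predict_mirna_lncrna(mir, lnc, score_min = hit$score,
                                         energy_max = hit$energy)), 1)
  expect_equal(nrow(predict_mirna_lncrna(mir, lnc,
                                         score_min = hit$score + 0.1)), 0)
  expect_equal(nrow(predict_mirna_lncrna(mir, lnc, energy_max =
                                           hit$energy - 0.1)), 0)
  expect_error(predict_mirna_lncrna(character(), lnc), "empty")
})

test_that("dinucleotide-shuffled controls of planted sites are almost never called", {
  set.seed(59)
  study <- default_study()
  sites <- study$truth$sites
  # the per-control call rate is ~3.7%; enough controls are drawn that the
  # estimate concentrates well below the 5% specificity bound
  calls <- 0; n <- 0
  for (k in seq_len(nrow(sites))) {
    mir <- study$mirnas[[sites$mirna_id[k]]]
    lnc <- study$transcripts[[sites$lncrna_id[k]]]
    for (s in 1:10) {
      shuf <- shuffle_dinucleotide(mir)
      h <- duplex_align(shuf, lnc)
      n <- n + 1
      if (nrow(h) == 1 && h$score >= 140 && h$energy <= -20) calls <- calls + 1
    }
  }
  expect_lt(calls / n, 0.05)
})

test_that("dinucleotide shuffling preserves dinucleotide composition", {
  set.seed(60)
  dinucs <- function(s) {
    ch <- strsplit(s, "")[[1]]
    sort(paste0(ch[-length(ch)], ch[-1]))
  }
  for (i in 1:10) {
    s <- random_rna_str(22)
    sh <- shuffle_dinucleotide(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(dinucs(sh), dinucs(s))
  }
})

test_that("miRNA-mRNA pairs come from a curated table or a seed-match fallback", {
  tab <- tibble::tibble(mirna_id = c("m1", "m1", "m2"),
                        mrna_id = c("gA", "gB", "gC"))
  out <- mirna_mrna_pairs(table = tab)
  expect_equal(nrow(out), 3)
  out2 <- mirna_mrna_pairs(table = tab, expressed = c("gA", "gC"))
  expect_equal(nrow(out2), 2)
  expect_equal(attr(out2, "n_dropped"), 1L)

  # mode B: exact 7-mer seed complement in the 3' region
  mir <- c(m1 = "UACGUACGUACGUACGUACGU")
  seed_probe <- rna_reverse_complement(substr(mir[[1]], 2, 8))
  set.seed(61)
  with_site <- paste0(strrep("A", 200), seed_probe, strrep("A", 20))
  without <- strrep("A", 240)
  outB <- mirna_mrna_pairs(mirnas = mir,
                           mrnas = c(hit = with_site, miss = without))
  expect_equal(outB$mrna_id, "hit")
  # a seed complement only in the 5' region is not called
  early <- paste0(strrep("A", 5), seed_probe, strrep("A", 300))
  outC <- mirna_mrna_pairs(mirnas = mir, mrnas = c(early = early))
  expect_equal(nrow(outC), 0)
  expect_error(mirna_mrna_pairs(), "curated")
})
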