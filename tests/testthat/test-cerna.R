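test_that("triples require all three relations and a positive strong correlation", {
  lnc_mi <- tibble::tibble(lncrna_id = "L1", mirna_id = "u1")
  mi_m <- tibble::tibble(mirna_id = "u2", mrna_id = "M1")
  edges <- tibble::tibble(lncrna_id = "L1", mrna_id = "M1", r = 0.99)
  # no shared miRNA
  expect_equal(nrow(assemble_triples(lnc_mi, mi_m, edges)), 0)
  # one complete chain
  mi_m2 <- tibble::tibble(mirna_id = "u1", mrna_id = "M1")
  got <- assemble_triples(lnc_mi, mi_m2, edges)
  expect_equal(nrow(got), 1)
  expect_equal(got$coexpression_r, 0.99)
  # strong but negative correlation never qualifies
  edges_neg <- tibble::tibble(lncrna_id = "L1", mrna_id = "M1", r = -0.99)
  expect_equal(nrow(assemble_triples(lnc_mi, mi_m2, edges_neg)), 0)
})

test_that("triple assembly equals brute-force enumeration on random fixtures", {
  set.seed(71)
  for (rep in 1:3) {
    Ls <- paste0("L", 1:8); Us <- paste0("u", 1:6); Ms <- paste0("M", 1:10)
    lnc_mi <- tibble::tibble(lncrna_id = sample(Ls, 14, TRUE),
                             mirna_id = sample(Us, 14, TRUE)) |>
      dplyr::distinct()
    mi_m <- tibble::tibble(mirna_id = sample(Us, 18, TRUE),
                           mrna_id = sample(Ms, 18, TRUE)) |>
      dplyr::distinct()
    edges <- tidyr::crossing(lncrna_id = Ls, mrna_id = Ms) |>
      dplyr::mutate(r = runif(dplyr::n(), -1, 1)) |>
      dplyr::slice_sample(n = 50)
    got <- assemble_triples(lnc_mi, mi_m, edges)
    want <- brute_triples(lnc_mi, mi_m, edges)
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
  }
})

test_that("the strict filter is a plain threshold and composes with assembly", {
  tr <- tibble::tibble(lncrna_id = c("L1", "L2", "L3"),
                       mirna_id = "u", mrna_id = "M",
                       coexpression_r = c(0.96, 0.95, 0.90))
  out <- strict_filter(tr)
  expect_equal(out$lncrna_id, "L1") # 0.95 exactly is excluded
  # composition identity on a random fixture
  set.seed(72)
  lnc_mi <- tibble::tibble(lncrna_id = paste0("L", 1:6),
                           mirna_id = sample(paste0("u", 1:3), 6, TRUE))
  mi_m <- tibble::tibble(mirna_id = paste0("u", 1:3),
                         mrna_id = sample(paste0("M", 1:5), 3))
  edges <- tidyr::crossing(lncrna_id = paste0("L", 1:6),
                           mrna_id = paste0("M", 1:5)) |>
    dplyr::mutate(r = runif(dplyr::n(), 0.5, 1))
  expect_equal(strict_filter(assemble_triples(lnc_mi, mi_m, edges, 0.8), 0.95),
               assemble_triples(lnc_mi, mi_m, edges, 0.95))
})

test_that("a single triple builds a triangle and shared members merge correctly", {
  tr1 <- tibble::tibble(lncrna_id = "L", mirna_id = "u", mrna_id = "M",
                        coexpression_r = 0.99)
  net1 <- build_network(tr1)
  expect_equal(nrow(net1$nodes), 3)
  expect_equal(nrow(net1$edges), 3)
  expect_true(all(igraph::degree(net1$graph) == 2))

  # two triples sharing the lncRNA and miRNA but different mRNAs
  tr2 <- tibble::tibble(lncrna_id = "L", mirna_id = "u",
                        mrna_id = c("M1", "M2"), coexpression_r = 0.99)
  net2 <- build_network(tr2)
  expect_equal(nrow(net2$nodes), 4)
  deg <- igraph::degree(net2$graph)
  expect_equal(unname(deg[["L"]]), 3) # 1 miRNA edge + 2 co-expression edges
  expect_equal(unname(deg[["u"]]), 3)
})

test_that("networks deduplicate edges and satisfy the handshake lemma", {
  set.seed(73)
  tr <- tibble::tibble(
    lncrna_id = sample(paste0("L", 1:5), 30, TRUE),
    mirna_id = sample(paste0("u", 1:4), 30, TRUE),
    mrna_id = sample(paste0("M", 1:6), 30, TRUE),
    coexpression_r = runif(30, 0.81, 1))
  net <- build_network(tr)
  expect_equal(anyDuplicated(net$edges), 0)
  deg <- igraph::degree(net$graph)
  expect_equal(sum(deg), 2 * nrow(net$edges))
  # degrees equal brute-force incidence counting
  bf <- brute_degrees(net$edges)
  expect_equal(unname(deg[names(bf)]), unname(bf))
})

test_that("degree ranking reports top nodes per class with lexicographic ties", {
  tr <- tibble::tibble(lncrna_id = "L", mirna_id = "u", mrna_id = "M",
                       coexpression_r = 0.99)
  rk <- degree_ranking(build_network(tr))
  expect_equal(nrow(rk), 3)
  expect_true(all(rk$degree == 2))
  expect_setequal(rk$type, c("lncRNA", "miRNA", "mRNA"))

  tr2 <- tibble::tibble(lncrna_id = c("Lb", "La"), mirna_id = c("u1", "u2"),
                        mrna_id = "M", coexpression_r = 0.99)
  rk2 <- degree_ranking(build_network(tr2))
  lnc <- rk2[rk2$type == "lncRNA", ]
  expect_equal(lnc$node, c("La", "Lb")) # equal degree, name breaks the tie
})

test_that("directions from the DE stage are carried onto nodes", {
  tr <- tibble::tibble(lncrna_id = "L", mirna_id = "u", mrna_id = "M",
                       coexpression_r = 0.99)
  dirs <- tibble::tibble(gene_id = c("L", "M"), direction = c("down", "up"))
  net <- build_network(tr, directions = dirs)
  expect_equal(net$nodes$direction[net$nodes$name == "L"], "down")
  expect_equal(net$nodes$direction[net$nodes$name == "M"], "up")
  expect_s3_class(tidy(net), "tbl_df")
  expect_equal(glance(net)$n_edges, 3)
})
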