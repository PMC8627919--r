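#' Simulation configuration
#'
#' Parameters of the synthetic two-group RNA-seq study. Defaults describe a
#' desk-scale mouse-heart-like design: 2000 coding genes and 200 lncRNAs
#' measured in 3 knockout vs 3 wild-type animals, negative-binomial counts
#' with dispersion 0.05 and baseline means between 20 and 500, 10% of
#' features differentially expressed at |log2FC| = 2, five co-expression
#' blocks of 20 features driven by a shared latent factor (sd 3 on the
#' log2 scale — strong enough that block pairs clear an |r| > 0.8 screen
#' despite the large sampling variance of a six-sample correlation), 19
#' chromosomes, 30% of lncRNAs placed within 100 kb of a coding partner,
#' 20 miRNAs, and a quarter of lncRNAs carrying a planted miRNA binding
#' site.
#'
#' A single integer seed governs every sub-generator through a fixed
#' splitting scheme (`rng_seed` for counts, `+1` annotation, `+2`
#' sequences, `+3` term sets), so identical configurations reproduce
#' byte-identical datasets.
#'
#' @param n_genes Number of coding genes.
#' @param n_lncrnas Number of lncRNAs.
#' @param n_samples_per_group Replicates per condition (default 3).
#' @param nb_dispersion NB dispersion `phi` in `var = m + phi * m^2`.
#' @param baseline_mean_log_range Range (natural log) of baseline means.
#' @param planted_de_fraction Fraction of features with a planted fold
#'   change.
#' @param planted_log2fc_magnitude Absolute planted log2 fold change.
#' @param coexpression_block_count,coexpression_block_size Number and size
#'   of latent-factor co-expression blocks (each block holds
#'   `max(2, round(size/4))` lncRNAs, the rest mRNAs).
#' @param latent_factor_sd Latent factor standard deviation (log2 scale).
#' @param n_chromosomes Number of chromosomes features are placed on.
#' @param cis_pair_fraction Fraction of lncRNAs planted within 100 kb of a
#'   coding partner.
#' @param n_mirnas Number of miRNAs.
#' @param planted_site_fraction Fraction of lncRNAs given a perfect planted
#'   miRNA binding site.
#' @param rng_seed Master seed (integer).
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000, n_lncrnas = 200,
                              n_samples_per_group = 3,
                              nb_dispersion = 0.05,
                              baseline_mean_log_range = c(log(20), log(500)),
                              planted_de_fraction = 0.1,
                              planted_log2fc_magnitude = 2,
                              coexpression_block_count = 5,
                              coexpression_block_size = 20,
                              latent_factor_sd = 3,
                              n_chromosomes = 19,
                              cis_pair_fraction = 0.3,
                              n_mirnas = 20,
                              planted_site_fraction = 0.25,
                              rng_seed = 1) {
  cfg <- list(n_genes = n_genes, n_lncrnas = n_lncrnas,
              n_samples_per_group = n_samples_per_group,
              nb_dispersion = nb_dispersion,
              baseline_mean_log_range = baseline_mean_log_range,
              planted_de_fraction = planted_de_fraction,
              planted_log2fc_magnitude = planted_log2fc_magnitude,
              coexpression_block_count = coexpression_block_count,
              coexpression_block_size = coexpression_block_size,
              latent_factor_sd = latent_factor_sd,
              n_chromosomes = n_chromosomes,
              cis_pair_fraction = cis_pair_fraction,
              n_mirnas = n_mirnas,
              planted_site_fraction = planted_site_fraction,
              rng_seed = as.integer(rng_seed))
  counts <- c("n_genes", "n_lncrnas", "n_samples_per_group",
              "coexpression_block_count", "coexpression_block_size",
              "n_chromosomes", "n_mirnas")
  for (f in counts) {
    if (cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]])) {
      abort(paste0("`", f, "` must be a count >= 1"))
    }
  }
  for (f in c("planted_de_fraction", "cis_pair_fraction",
              "planted_site_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(paste0("`", f, "` must be in [0,1]"))
  }
  if (cfg$nb_dispersion < 0) abort("`nb_dispersion` must be >= 0")
  if (cfg$latent_factor_sd < 0) abort("`latent_factor_sd` must be >= 0")
  stopifnot(length(cfg$baseline_mean_log_range) == 2,
            diff(cfg$baseline_mean_log_range) >= 0)
  n_lnc_per_block <- max(2, round(cfg$coexpression_block_size / 4))
  n_mrna_per_block <- cfg$coexpression_block_size - n_lnc_per_block
  if (n_mrna_per_block < 1) abort("`coexpression_block_size` too small")
  if (n_lnc_per_block * cfg$coexpression_block_count > cfg$n_lncrnas ||
      n_mrna_per_block * cfg$coexpression_block_count > cfg$n_genes) {
    abort("co-expression blocks exceed the available gene/lncRNA counts")
  }
  cfg$n_lnc_per_block <- n_lnc_per_block
  cfg$n_mrna_per_block <- n_mrna_per_block
  structure(cfg, class = "simulation_config")
}

#' Simulate a two-group RNA-seq count matrix with planted structure
#'
#' Counts are drawn per gene and sample from a negative binomial with mean
#' `m` and variance `m + phi * m^2`. Planted differentially expressed
#' features have their knockout-group mean multiplied by
#' `2^(+-planted_log2fc_magnitude)`; features in a co-expression block share
#' an additive per-sample latent factor on the log2-mean scale, so their
#' pairwise correlation survives count noise the way genuinely co-regulated
#' genes do.
#'
#' @param config A [simulation_config()].
#' @return A list: `counts` (tibble, feature id + one column per sample),
#'   `samples` (sample sheet), and `truth` — the ground-truth manifest with
#'   planted fold changes and block memberships, extended by the other
#'   generators.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$rng_seed)
  n_m <- config$n_genes; n_l <- config$n_lncrnas
  ids <- c(sprintf("gene_%04d", seq_len(n_m)), sprintf("lnc_%04d", seq_len(n_l)))
  biotype <- rep(c("mRNA", "lncRNA"), c(n_m, n_l))
  n_per <- config$n_samples_per_group
  sample_ids <- c(paste0("WT_", seq_len(n_per)), paste0("KO_", seq_len(n_per)))
  groups <- rep(c("control", "knockout"), each = n_per)
  n_s <- 2 * n_per
  n_tot <- n_m + n_l

  lambda <- runif(n_tot, config$baseline_mean_log_range[1],
                  config$baseline_mean_log_range[2])

  # co-expression blocks: sampled without replacement from each biotype
  blocks <- tibble(block_id = integer(), feature_id = character(),
                   biotype = character())
  loading <- rep(0, n_tot)
  block_of <- rep(NA_integer_, n_tot)
  if (config$coexpression_block_count > 0) {
    lnc_pool <- sample(which(biotype == "lncRNA"))
    mrna_pool <- sample(which(biotype == "mRNA"))
    for (b in seq_len(config$coexpression_block_count)) {
      li <- lnc_pool[seq_len(config$n_lnc_per_block) +
                       (b - 1) * config$n_lnc_per_block]
      mi <- mrna_pool[seq_len(config$n_mrna_per_block) +
                        (b - 1) * config$n_mrna_per_block]
      block_of[c(li, mi)] <- b
      loading[c(li, mi)] <- 1
      blocks <- bind_rows(blocks, tibble(block_id = b,
                                         feature_id = ids[c(li, mi)],
                                         biotype = biotype[c(li, mi)]))
    }
  }

  # planted fold changes
  n_de <- round(config$planted_de_fraction * n_tot)
  de_idx <- if (n_de > 0) sample(n_tot, n_de) else integer()
  delta <- rep(0, n_tot)
  delta[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
    config$planted_log2fc_magnitude

  z <- matrix(rnorm(config$coexpression_block_count * n_s, 0,
                    config$latent_factor_sd),
              nrow = config$coexpression_block_count)
  ko <- groups == "knockout"
  log2mu <- matrix(lambda / log(2), n_tot, n_s) +
    outer(delta, as.numeric(ko)) +
    t(vapply(seq_len(n_tot), function(g) {
      if (is.na(block_of[g])) rep(0, n_s) else loading[g] * z[block_of[g], ]
    }, numeric(n_s)))
  mu <- 2^log2mu

  counts <- if (config$nb_dispersion > 0) {
    matrix(rnbinom(n_tot * n_s, mu = mu, size = 1 / config$nb_dispersion),
           n_tot, n_s)
  } else {
    matrix(rpois(n_tot * n_s, lambda = mu), n_tot, n_s)
  }
  dimnames(counts) <- list(ids, sample_ids)

  truth <- structure(list(
    de = tibble(feature_id = ids[de_idx], biotype = biotype[de_idx],
                log2fc = delta[de_idx]),
    blocks = blocks,
    baseline_mean = tibble(feature_id = ids, mean = exp(lambda)),
    cis_pairs = NULL, sites = NULL, triples = NULL, hub = NULL,
    mirna_mrna = NULL
  ), class = "cerna_truth")

  list(counts = as_tibble(counts, rownames = "feature_id"),
       samples = tibble(sample = sample_ids, group = groups),
       truth = truth)
}

#' Simulate genomic annotation with planted cis pairs
#'
#' Places every feature on a chromosome with strand and 1-based inclusive
#' coordinates. A configurable fraction of lncRNAs is planted within
#' 100 kb of a coding partner (cis pairs, drawn preferentially from
#' co-expression-block co-members so the cis screen's intersection rule has
#' something to find); all other features are placed uniformly, so most
#' random lncRNA-mRNA pairs land on different chromosomes and exercise the
#' trans filter.
#'
#' @param config A [simulation_config()].
#' @param truth Ground truth from [simulate_counts()].
#' @return A list: `features` (annotation tibble) and the extended `truth`
#'   (with `cis_pairs`).
#' @export
simulate_annotation <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(truth, "cerna_truth"))
  set.seed(config$rng_seed + 1L)
  ids_m <- sprintf("gene_%04d", seq_len(config$n_genes))
  ids_l <- sprintf("lnc_%04d", seq_len(config$n_lncrnas))
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  chrom_len <- 1e8

  genes <- tibble(
    feature_id = ids_m,
    chromosome = sample(chroms, length(ids_m), replace = TRUE),
    start = floor(runif(length(ids_m), 1, chrom_len - 2e5)),
    length = floor(runif(length(ids_m), 1000, 50000)),
    strand = sample(c("+", "-"), length(ids_m), replace = TRUE),
    biotype = "mRNA"
  ) |> mutate(end = .data$start + .data$length - 1)

  # choose cis pairs: block lncRNA x mRNA co-member pairs first, then random
  n_cis <- round(config$cis_pair_fraction * config$n_lncrnas)
  cis <- tibble(lncrna_id = character(), gene_id = character())
  if (n_cis > 0) {
    block_pairs <- truth$blocks |>
      filter(.data$biotype == "lncRNA") |>
      select(block_id = "block_id", lncrna_id = "feature_id") |>
      inner_join(truth$blocks |>
                   filter(.data$biotype == "mRNA") |>
                   select(block_id = "block_id", gene_id = "feature_id"),
                 by = "block_id", relationship = "many-to-many") |>
      select("lncrna_id", "gene_id")
    block_pairs <- block_pairs[sample(nrow(block_pairs)), ] |>
      distinct(.data$lncrna_id, .keep_all = TRUE)
    cis <- head(block_pairs, n_cis)
    if (nrow(cis) < n_cis) {
      extra_l <- setdiff(ids_l, cis$lncrna_id)
      extra <- tibble(lncrna_id = sample(extra_l, n_cis - nrow(cis)),
                      gene_id = sample(ids_m, n_cis - nrow(cis),
                                       replace = TRUE))
      cis <- bind_rows(cis, extra)
    }
  }

  lnc_len <- floor(runif(length(ids_l), 200, 3000))
  lnc <- tibble(feature_id = ids_l,
                chromosome = sample(chroms, length(ids_l), replace = TRUE),
                start = floor(runif(length(ids_l), 1, chrom_len - 2e5)),
                length = lnc_len,
                strand = sample(c("+", "-"), length(ids_l), replace = TRUE),
                biotype = "lncRNA") |>
    mutate(end = .data$start + .data$length - 1)
  # re-place cis lncRNAs next to their partner (gap 0-80 kb, inside window)
  if (nrow(cis) > 0) {
    gaps <- floor(runif(nrow(cis), 0, 80000))
    for (k in seq_len(nrow(cis))) {
      g <- genes[genes$feature_id == cis$gene_id[k], ]
      i <- match(cis$lncrna_id[k], lnc$feature_id)
      lnc$chromosome[i] <- g$chromosome
      lnc$start[i] <- g$end + gaps[k]
      lnc$end[i] <- lnc$start[i] + lnc$length[i] - 1
    }
  }

  features <- bind_rows(genes, lnc) |>
    select("feature_id", "chromosome", "start", "end", "strand", "biotype")
  truth$cis_pairs <- cis
  list(features = features, truth = truth)
}

random_rna <- function(n, len) {
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "U"), l, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate transcript and miRNA sequences with planted binding sites
#'
#' Background transcripts are uniform random RNA; miRNAs are 20-23 nt. For
#' each planted site the full reverse complement of the miRNA is written
#' into the lncRNA transcript, a perfect duplex that is guaranteed to clear
#' both screening regimes by construction (a perfect >= 20 nt complement
#' scores >= 205 and has energy <= -20.9 even in the worst all-A/U case).
#' One block lncRNA is designated the hub: it receives sites for three
#' different miRNAs, each wired to two block mRNAs in the curated
#' miRNA-mRNA table, planting the ceRNA triples the network stage should
#' recover and making the hub the top-degree lncRNA.
#'
#' @param config A [simulation_config()].
#' @param truth Ground truth carrying block memberships
#'   (from [simulate_counts()]).
#' @return A list: `transcripts` and `mirnas` (named RNA vectors),
#'   `mirna_targets` (curated miRNA-mRNA table with decoys), and the
#'   extended `truth` (`sites`, `triples`, `hub`, `mirna_mrna`).
#' @export
simulate_sequences <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(truth, "cerna_truth"))
  set.seed(config$rng_seed + 2L)
  ids_m <- sprintf("gene_%04d", seq_len(config$n_genes))
  ids_l <- sprintf("lnc_%04d", seq_len(config$n_lncrnas))

  transcripts <- c(
    setNames(random_rna(length(ids_m),
                        sample(400:800, length(ids_m), replace = TRUE)), ids_m),
    setNames(random_rna(length(ids_l),
                        sample(300:600, length(ids_l), replace = TRUE)), ids_l))
  mirna_ids <- sprintf("mir_%02d", seq_len(config$n_mirnas))
  mirnas <- setNames(random_rna(config$n_mirnas,
                                sample(20:23, config$n_mirnas, replace = TRUE)),
                     mirna_ids)

  n_sites <- round(config$planted_site_fraction * config$n_lncrnas)
  sites <- tibble(mirna_id = character(), lncrna_id = character(),
                  site_start = integer(), site_end = integer())
  triples <- tibble(lncrna_id = character(), mirna_id = character(),
                    mrna_id = character())
  hub <- NULL
  if (n_sites > 0) {
    block_lncs <- truth$blocks$feature_id[truth$blocks$biotype == "lncRNA"]
    other_lncs <- setdiff(ids_l, block_lncs)
    site_lncs <- head(c(sample(block_lncs), sample(other_lncs)), n_sites)
    hub <- site_lncs[1]
    # assignment: the hub gets three distinct miRNAs, the rest one each
    assign <- c(list(tibble(lncrna_id = hub,
                            mirna_id = sample(mirna_ids,
                                              min(3, config$n_mirnas)))),
                lapply(site_lncs[-1], function(l) {
                  tibble(lncrna_id = l, mirna_id = sample(mirna_ids, 1))
                }))
    assign <- bind_rows(assign)
    planted_pairs <- list(); site_rows <- list()
    occupied <- list() # per-transcript spans already carrying a site
    for (k in seq_len(nrow(assign))) {
      l <- assign$lncrna_id[k]; mi <- assign$mirna_id[k]
      probe <- rna_revcomp(mirnas[[mi]])
      s <- transcripts[[l]]
      taken <- occupied[[l]]
      # rejection-sample a position that does not overwrite an earlier site
      repeat {
        pos <- sample.int(nchar(s) - nchar(probe) + 1, 1)
        span <- c(pos, pos + nchar(probe) - 1L)
        clash <- !is.null(taken) &&
          any(taken[, 1] <= span[2] & taken[, 2] >= span[1])
        if (!clash) break
      }
      occupied[[l]] <- rbind(taken, span)
      substr(s, pos, pos + nchar(probe) - 1) <- probe
      transcripts[[l]] <- s
      site_rows[[k]] <- tibble(mirna_id = mi, lncrna_id = l,
                               site_start = pos,
                               site_end = pos + nchar(probe) - 1L)
      # wire triples through block co-member mRNAs (up to two per site)
      b <- truth$blocks$block_id[truth$blocks$feature_id == l]
      if (length(b) == 1) {
        partners <- truth$blocks$feature_id[
          truth$blocks$block_id == b & truth$blocks$biotype == "mRNA"]
        partners <- sample(partners, min(2, length(partners)))
        planted_pairs[[k]] <- tibble(lncrna_id = l, mirna_id = mi,
                                     mrna_id = partners)
      }
    }
    sites <- bind_rows(site_rows)
    triples <- bind_rows(planted_pairs)
  }

  curated <- distinct(triples, .data$mirna_id, .data$mrna_id)
  n_decoys <- 30
  decoys <- tibble(mirna_id = sample(mirna_ids, n_decoys, replace = TRUE),
                   mrna_id = sample(ids_m, n_decoys, replace = TRUE))
  mirna_targets <- distinct(bind_rows(curated, decoys))

  truth$sites <- sites
  truth$triples <- arrange(triples, .data$lncrna_id, .data$mirna_id,
                           .data$mrna_id)
  truth$hub <- hub
  truth$mirna_mrna <- mirna_targets
  list(transcripts = transcripts, mirnas = mirnas,
       mirna_targets = mirna_targets, truth = truth)
}

#' Simulate GO/KEGG-style term sets
#'
#' Emits GMT-style annotation sets over the coding genes: random terms in
#' the BP, CC, MF, and pathway categories, plus one "block" BP term per
#' co-expression block whose members are exactly the block's mRNAs — the
#' planted signal the guilt-by-association annotation should rank first.
#'
#' @param config A [simulation_config()].
#' @param truth Ground truth carrying block memberships.
#' @return A long tibble `term_id`, `category`, `gene_id`.
#' @export
simulate_term_sets <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(truth, "cerna_truth"))
  set.seed(config$rng_seed + 3L)
  ids_m <- sprintf("gene_%04d", seq_len(config$n_genes))
  n_per_cat <- c(BP = 40, CC = 15, MF = 15, pathway = 20)
  random_terms <- purrr::imap(n_per_cat, function(n, cat) {
    purrr::map(seq_len(n), function(i) {
      size <- sample(10:min(50, length(ids_m)), 1)
      tibble(term_id = sprintf("%s_%03d", cat, i), category = cat,
             gene_id = sample(ids_m, size))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  block_terms <- truth$blocks |>
    filter(.data$biotype == "mRNA") |>
    transmute(term_id = sprintf("BP_block_%02d", .data$block_id),
              category = "BP", gene_id = .data$feature_id)
  bind_rows(random_terms, block_terms) |>
    distinct(.data$term_id, .data$category, .data$gene_id)
}

#' Simulate a complete synthetic ceRNA study
#'
#' Runs all four generators in order and optionally writes every input file
#' the pipeline consumes (counts TSV, sample sheet, GTF, transcript and
#' miRNA FASTA, GMT, curated miRNA-target TSV, and a JSON ground-truth
#' manifest) to a directory. Identical configurations produce byte-identical
#' studies.
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory.
#' @return A list: `counts`, `samples`, `features`, `transcripts`,
#'   `mirnas`, `mirna_targets`, `term_sets`, `truth`, `config`, and (when
#'   written) `files`.
#' @export
simulate_cerna_study <- function(config = simulation_config(), dir = NULL) {
  cm <- simulate_counts(config)
  ann <- simulate_annotation(config, cm$truth)
  seqs <- simulate_sequences(config, ann$truth)
  terms <- simulate_term_sets(config, seqs$truth)
  study <- list(counts = cm$counts, samples = cm$samples,
                features = ann$features, transcripts = seqs$transcripts,
                mirnas = seqs$mirnas, mirna_targets = seqs$mirna_targets,
                term_sets = terms, truth = seqs$truth, config = config)
  if (!is.null(dir)) {
    study$files <- write_study(study, dir)
  }
  study
}

write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    annotation = file.path(dir, "annotation.gtf"),
    transcripts = file.path(dir, "transcripts.fa"),
    mirnas = file.path(dir, "mirnas.fa"),
    term_sets = file.path(dir, "terms.gmt"),
    mirna_targets = file.path(dir, "mirna_targets.tsv"),
    truth = file.path(dir, "truth.json"))
  readr::write_tsv(study$counts, files[["counts"]])
  readr::write_tsv(study$samples, files[["samples"]])
  write_gtf(study$features, files[["annotation"]])
  write_fasta(study$transcripts, files[["transcripts"]])
  write_fasta(study$mirnas, files[["mirnas"]])
  write_gmt(study$term_sets, files[["term_sets"]])
  readr::write_tsv(study$mirna_targets, files[["mirna_targets"]])
  truth <- study$truth
  jsonlite::write_json(
    list(de = truth$de, blocks = truth$blocks, cis_pairs = truth$cis_pairs,
         sites = truth$sites, triples = truth$triples,
         hub = truth$hub %||% NA_character_),
    files[["truth"]], dataframe = "columns", auto_unbox = TRUE, digits = NA)
  files
}
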