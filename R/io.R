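#' Read a gene-level count matrix
#'
#' TSV with a header row: first column feature ids, remaining columns one
#' per sample. Cells must be non-negative integers; missing or non-numeric
#' cells and duplicated ids are rejected with the offending location.
#'
#' @param path Path to the TSV file.
#' @return A tibble (feature id + sample columns).
#' @export
read_counts <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (ncol(df) < 2) abort("counts file needs an id column plus sample columns")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated feature id '", ids[duplicated(ids)][1],
                 "' in ", path))
  }
  for (j in 2:ncol(df)) {
    v <- df[[j]]
    bad <- which(is.na(v) | !grepl("^[0-9]+$", v))
    if (length(bad)) {
      abort(paste0("non-integer count at row ", bad[1], ", column '",
                   names(df)[j], "' in ", path))
    }
  }
  out <- df
  out[-1] <- lapply(df[-1], as.numeric)
  out
}

#' Read a sample sheet
#'
#' TSV with columns `sample` and `group` (`control` / `knockout`).
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!all(c("sample", "group") %in% names(df))) {
    abort("sample sheet must have columns `sample` and `group`")
  }
  df
}

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexpr(paste0(key, ' "[^"]*"'), attrs))
  out <- rep(NA_character_, length(attrs))
  hit <- lengths(regmatches(attrs, gregexpr(paste0(key, ' "'), attrs))) > 0
  out[hit] <- sub(paste0('^', key, ' "'), "",
                  sub('"$', "", unlist(m)))
  out
}

#' Read genomic feature annotation (GTF or BED6)
#'
#' The format is chosen by extension: `.gtf`/`.gff` parsed as GTF (1-based,
#' inclusive; `gene_id` and `biotype` read from the attribute column) or
#' `.bed` as BED6 (0-based half-open, converted to 1-based inclusive on
#' read; the name column becomes the feature id and ids starting with
#' `lnc` are typed lncRNA). Malformed lines are rejected with their line
#' number.
#'
#' @param path Path to the annotation file.
#' @return A feature tibble: `feature_id`, `chromosome`, `start`, `end`,
#'   `strand`, `biotype` (1-based inclusive).
#' @export
read_annotation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("gtf", "gff", "bed")) {
    abort(paste0("unrecognized annotation format: ", path,
                 " (expected .gtf, .gff or .bed)"))
  }
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (ext %in% c("gtf", "gff")) {
    nf <- lengths(fields)
    if (any(nf != 9)) {
      abort(paste0("malformed GTF line ", idx[which(nf != 9)[1]], " in ",
                   path, " (expected 9 tab-separated fields)"))
    }
    m <- do.call(rbind, fields)
    start <- suppressWarnings(as.integer(m[, 4]))
    end <- suppressWarnings(as.integer(m[, 5]))
    bad <- which(is.na(start) | is.na(end) | start > end)
    if (length(bad)) {
      abort(paste0("malformed GTF coordinates at line ", idx[bad[1]],
                   " in ", path))
    }
    tibble(feature_id = gtf_attr(m[, 9], "gene_id"),
           chromosome = m[, 1], start = start, end = end,
           strand = m[, 7],
           biotype = gtf_attr(m[, 9], "biotype"))
  } else {
    nf <- lengths(fields)
    if (any(nf < 6)) {
      abort(paste0("malformed BED line ", idx[which(nf < 6)[1]], " in ",
                   path, " (expected at least 6 fields)"))
    }
    m <- do.call(rbind, lapply(fields, `[`, 1:6))
    start0 <- suppressWarnings(as.integer(m[, 2]))
    end0 <- suppressWarnings(as.integer(m[, 3]))
    bad <- which(is.na(start0) | is.na(end0) | start0 >= end0)
    if (length(bad)) {
      abort(paste0("malformed BED coordinates at line ", idx[bad[1]],
                   " in ", path))
    }
    tibble(feature_id = m[, 4], chromosome = m[, 1],
           start = start0 + 1L, end = end0, strand = m[, 6],
           biotype = if_else(grepl("^lnc", m[, 4]), "lncRNA", "mRNA"))
  }
}

#' Write feature annotation as GTF
#'
#' One `gene` row per feature, 1-based inclusive, with `gene_id` and
#' `biotype` attributes.
#'
#' @param features Feature tibble (see [read_annotation()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(features, path) {
  lines <- sprintf(
    '%s\tcernakit\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; biotype "%s";',
    features$chromosome, as.integer(features$start),
    as.integer(features$end), features$strand, features$feature_id,
    features$biotype)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read RNA sequences from FASTA
#'
#' Sequences are uppercased and transcribed to the RNA alphabet (`T` to
#' `U`); ambiguity codes are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of RNA sequences.
#' @export
read_fasta_rna <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readBStringSet(path)
    x <- setNames(as.character(set), sub("\\s.*$", "", names(set)))
  } else {
    lines <- readr::read_lines(path, progress = FALSE)
    hdr <- grepl("^>", lines)
    id <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
    x <- setNames(
      vapply(split(lines[!hdr], cumsum(hdr)[!hdr]), paste, character(1),
             collapse = ""),
      id)
  }
  clean_rna_set(x, paste0("FASTA file ", path))
}

#' Write sequences as FASTA
#'
#' @param x Named character vector of sequences.
#' @param path Output path.
#' @param width Line width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  stopifnot(!is.null(names(x)))
  lines <- unlist(purrr::imap(x, function(s, id) {
    starts <- seq(1, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1, nchar(s))))
  }), use.names = FALSE)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read GMT annotation sets
#'
#' Tab-separated: term id, description, then member gene ids. The
#' description field carries the category (BP, CC, MF, pathway).
#'
#' @param path Path to a GMT file.
#' @return A long tibble `term_id`, `category`, `gene_id`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    abort(paste0("malformed GMT line ", bad[1], " in ", path,
                 " (expected term, description, and at least one gene)"))
  }
  purrr::map(fields, function(f) {
    tibble(term_id = f[1], category = f[2], gene_id = f[-(1:2)])
  }) |> purrr::list_rbind()
}

#' Write GMT annotation sets
#'
#' @param sets Long tibble `term_id`, `category`, `gene_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  sets <- harmonize_sets(sets)
  split_sets <- split(sets$gene_id, paste0(sets$term_id, "\t", sets$category))
  keys <- names(split_sets)
  lines <- vapply(seq_along(split_sets), function(i) {
    paste(c(keys[i], split_sets[[i]]), collapse = "\t")
  }, character(1))
  readr::write_lines(sort(lines), path)
  invisible(path)
}

#' Write a network in SIF format
#'
#' `source <TAB> relation <TAB> target`, one edge per line — the plain
#' interchange format Cytoscape reads.
#'
#' @param edges Edge tibble with columns `from`, `type`, `to`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(edges, path) {
  readr::write_lines(paste(edges$from, edges$type, edges$to, sep = "\t"),
                     path)
  invisible(path)
}

#' Write a ceRNA network as GraphML
#'
#' Node attributes `type` and `direction`, edge attribute `type` — openable
#' in Cytoscape.
#'
#' @param network A [build_network()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  g <- network$graph
  igraph::V(g)$direction <- ifelse(is.na(igraph::V(g)$direction %||%
                                           NA_character_),
                                   "", igraph::V(g)$direction)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
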