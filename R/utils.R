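# internal helpers shared across modules

# counts may arrive as a tibble/data.frame (first column = gene ids) or as a
# numeric matrix with rownames; everything downstream works on the matrix form
as_count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    if (is.null(rownames(counts))) abort("count matrix must have gene ids as rownames")
    storage.mode(counts) <- "double"
    return(counts)
  }
  if (!is.data.frame(counts)) abort("`counts` must be a data frame or matrix")
  if (ncol(counts) < 2) abort("`counts` needs a gene-id column plus at least one sample column")
  ids <- as.character(counts[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated gene ids in counts: ",
                 paste(unique(ids[duplicated(ids)])[1:min(3, sum(duplicated(ids)))], collapse = ", ")))
  }
  m <- as.matrix(counts[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

check_counts <- function(m) {
  if (any(is.na(m))) abort("counts contain missing values")
  if (any(m < 0)) abort("counts contain negative entries")
  if (any(m != round(m))) abort("counts contain non-integer entries")
  invisible(m)
}

# sample sheet -> named group factor aligned with count columns
check_groups <- function(samples, sample_ids) {
  if (!is.data.frame(samples) || !all(c("sample", "group") %in% names(samples))) {
    abort("`samples` must be a data frame with columns `sample` and `group`")
  }
  g <- setNames(as.character(samples$group), as.character(samples$sample))
  missing <- setdiff(sample_ids, names(g))
  if (length(missing)) abort(paste0("samples missing from sample sheet: ", paste(missing, collapse = ", ")))
  g <- g[sample_ids]
  lev <- unique(g)
  if (length(lev) != 2) abort("exactly two groups are required")
  if (!all(sort(lev) == c("control", "knockout"))) {
    abort("groups must be labelled 'control' and 'knockout'")
  }
  if (any(table(g) < 2)) abort("each group needs at least 2 samples")
  g
}

# gap in bases between two closed intervals; 0 when they overlap or touch
interval_distance <- function(start1, end1, start2, end2) {
  pmax(0, pmax(start1, start2) - pmin(end1, end2))
}

geometric_mean <- function(x) exp(mean(log(x)))

# validate an RNA string; DNA input (T) is transcribed, ambiguity codes rejected
clean_rna <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- gsub("T", "U", x, fixed = TRUE)
  bad <- regmatches(x, regexpr("[^ACGU]", x))
  if (length(bad) && nzchar(bad)) {
    abort(paste0("invalid RNA symbol '", bad, "' in ", what))
  }
  x
}

clean_rna_set <- function(x, what = "sequences") {
  if (is.null(names(x)) || any(!nzchar(names(x)))) abort(paste0(what, " must be named"))
  vapply(x, clean_rna, character(1), what = what)
}

rna_revcomp <- function(x) {
  chartr("ACGU", "UGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}
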