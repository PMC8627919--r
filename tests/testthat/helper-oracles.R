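# Independent oracles. Each is written from the definition, not by calling
# the implementation it checks.

# all permutations of a vector (n! lists)
all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  unlist(lapply(seq_along(v), function(i) {
    lapply(all_perms(v[-i]), function(p) c(v[i], p))
  }), recursive = FALSE)
}
PERM6 <- do.call(rbind, all_perms(1:6))

# exhaustive two-sided permutation p for a Pearson correlation at n = 6
perm_cor_p <- function(x, y) {
  r_obs <- cor(x, y)
  r_all <- apply(PERM6, 1, function(o) cor(x, y[o]))
  mean(abs(r_all) >= abs(r_obs) - 1e-12)
}

# hypergeometric upper tail by direct enumeration of the mass function
enum_hyper_upper <- function(k, K, N, n) {
  i <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# dense-matrix affine-gap local complementarity DP (score only), written
# independently of the compiled engine
r_duplex_score <- function(q, t, p = duplex_params()) {
  comp <- function(a, b) {
    if ((a == "A" && b == "U") || (a == "U" && b == "A") ||
        (a == "G" && b == "C") || (a == "C" && b == "G")) return("wc")
    if ((a == "G" && b == "U") || (a == "U" && b == "G")) return("gu")
    "mm"
  }
  qs <- strsplit(q, "")[[1]]
  ts <- rev(strsplit(t, "")[[1]]) # antiparallel orientation
  n <- length(qs); m <- length(ts)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      s <- switch(comp(qs[i], ts[j]), wc = p$match_score,
                  gu = p$gu_wobble_score, mm = p$mismatch_score)
      if (i >= p$seed_start && i <= p$seed_end) s <- s * p$seed_scale
      cand <- max(0, M[i, j], X[i, j], Y[i, j]) + s
      M[i + 1, j + 1] <- max(0, cand)
      X[i + 1, j + 1] <- max(M[i + 1, j] + p$gap_open,
                             X[i + 1, j] + p$gap_extend)
      Y[i + 1, j + 1] <- max(M[i, j + 1] + p$gap_open,
                             Y[i, j + 1] + p$gap_extend)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# brute-force cis scan: all lncRNA x mRNA feature pairs, closed-interval gap
brute_cis <- function(features, edges, window = 100000) {
  out <- list()
  lncs <- features[features$biotype == "lncRNA", ]
  genes <- features[features$biotype == "mRNA", ]
  ek <- paste(edges$lncrna_id, edges$mrna_id)
  for (i in seq_len(nrow(lncs))) {
    for (j in seq_len(nrow(genes))) {
      if (lncs$chromosome[i] != genes$chromosome[j]) next
      d <- max(0, max(lncs$start[i], genes$start[j]) -
                 min(lncs$end[i], genes$end[j]))
      if (d > window) next
      if (!paste(lncs$feature_id[i], genes$feature_id[j]) %in% ek) next
      out[[length(out) + 1]] <- data.frame(
        lncrna_id = lncs$feature_id[i], gene_id = genes$feature_id[j],
        distance = d)
    }
  }
  if (length(out) == 0) {
    return(data.frame(lncrna_id = character(), gene_id = character(),
                      distance = numeric()))
  }
  out <- do.call(rbind, out)
  out[order(out$lncrna_id, out$gene_id), ]
}

# brute-force triple enumeration over the full cross product
brute_triples <- function(lnc_mi, mi_m, edges, r_threshold = 0.8) {
  Ls <- unique(c(lnc_mi$lncrna_id, edges$lncrna_id))
  Us <- unique(c(lnc_mi$mirna_id, mi_m$mirna_id))
  Ms <- unique(c(mi_m$mrna_id, edges$mrna_id))
  out <- list()
  for (L in Ls) for (U in Us) for (M in Ms) {
    if (!any(lnc_mi$lncrna_id == L & lnc_mi$mirna_id == U)) next
    if (!any(mi_m$mirna_id == U & mi_m$mrna_id == M)) next
    e <- edges[edges$lncrna_id == L & edges$mrna_id == M, ]
    if (nrow(e) == 0) next
    r <- e$r[1]
    if (!(r > r_threshold && r > 0)) next
    out[[length(out) + 1]] <- data.frame(lncrna_id = L, mirna_id = U,
                                         mrna_id = M, coexpression_r = r)
  }
  if (length(out) == 0) {
    return(data.frame(lncrna_id = character(), mirna_id = character(),
                      mrna_id = character(), coexpression_r = numeric()))
  }
  out <- do.call(rbind, out)
  out <- unique(out)
  out[order(out$lncrna_id, out$mirna_id, out$mrna_id), ]
}

# brute-force degrees by counting incident distinct edges
brute_degrees <- function(edges) {
  und <- unique(data.frame(a = pmin(edges$from, edges$to),
                           b = pmax(edges$from, edges$to),
                           type = edges$type))
  nodes <- unique(c(und$a, und$b))
  sapply(nodes, function(v) sum(und$a == v) + sum(und$b == v))
}

random_rna_str <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}
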