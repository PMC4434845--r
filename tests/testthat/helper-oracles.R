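# Brute-force oracles, deliberately naive and independent of the package's
# implementation paths.

# undirected dedup by frozen unordered key
oracle_dedup_pairs <- function(a, b) {
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  key <- ifelse(a < b, paste(a, b), paste(b, a))
  unique(key)
}

# total merged length by per-base occupancy bitmap (0-based half-open)
oracle_merged_length <- function(starts, ends) {
  hi <- max(ends)
  occ <- logical(hi)
  for (i in seq_along(starts)) occ[(starts[i] + 1):ends[i]] <- TRUE
  sum(occ)
}

# per-exon variant counts by linear scan
oracle_exon_counts <- function(iv, pos) {
  vapply(seq_len(nrow(iv)),
         function(j) sum(pos > iv$start[j] & pos <= iv$end[j]), 0L)
}

# cross-set edge count by scanning every edge
oracle_connectivity <- function(edge_mat, A, B) {
  n <- 0L
  for (i in seq_len(nrow(edge_mat))) {
    u <- edge_mat[i, 1]; v <- edge_mat[i, 2]
    if ((u %in% A && v %in% B) || (u %in% B && v %in% A)) n <- n + 1L
  }
  n
}

# hypergeometric upper tail by pmf summation
oracle_fet <- function(k, size_pathway, size_query, n_background) {
  xs <- k:min(size_pathway, size_query)
  sum(stats::dhyper(xs, size_pathway, n_background - size_pathway,
                    size_query))
}

# Benjamini-Hochberg step-up from the written-out formula
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  pmin(1, q_sorted)[order(o)]
}

# small random catalog with arbitrary membership
rand_catalog <- function(seed, n_diseases = 9, n_genes = 60) {
  set.seed(seed)
  genes <- sprintf("R%03d", seq_len(n_genes))
  diseases <- paste0("D", seq_len(n_diseases))
  catalog <- lapply(diseases, function(d)
    sort(sample(genes, sample(5:25, 1))))
  names(catalog) <- diseases
  catalog
}

# tiny Erdos-Renyi edge matrix over given node labels
rand_edges <- function(seed, nodes, p = 0.1) {
  set.seed(seed)
  cmb <- t(combn(nodes, 2))
  cmb[runif(nrow(cmb)) < p, , drop = FALSE]
}
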