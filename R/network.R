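#' Build an interaction network
#'
#' Constructs a simple undirected graph (no self-loops, no multi-edges) from
#' an edge list; the node set is the set of edge endpoints.
#'
#' @param pairs an \code{"edge_list"} (see [read_edge_list()]) or a
#'   two-column character matrix/data.frame of gene pairs.
#' @return an \code{"interaction_network"}: list with \code{nodes}
#'   (character) and \code{edges} (two-column character matrix, each row an
#'   unordered pair stored lexicographically).
#' @export
build_network <- function(pairs) {
  if (inherits(pairs, "edge_list")) {
    m <- pairs$pairs
  } else {
    m <- as.matrix(pairs)[, 1:2, drop = FALSE]
    el <- as_edge_list(as_gene_symbols(m[, 1L]), as_gene_symbols(m[, 2L]))
    m <- el$pairs
  }
  structure(list(nodes = sort(unique(as.vector(m))), edges = m),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("Interaction network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Number of seed-set neighbours for every gene in `universe`.
# An edge u-v with u in seeds increments v's count (and vice versa); counts
# for genes inside the seed set are irrelevant to callers, which always use
# sets disjoint from the seeds.
seed_degree <- function(net, seeds, universe = net$nodes) {
  seeds <- unique(seeds)
  deg <- stats::setNames(integer(length(universe)), universe)
  a <- net$edges[, 1L]; b <- net$edges[, 2L]
  a_in <- a %in% seeds; b_in <- b %in% seeds
  t1 <- table(b[a_in]); t2 <- table(a[b_in])
  for (tt in list(t1, t2)) {
    hit <- intersect(names(tt), universe)
    deg[hit] <- deg[hit] + as.integer(tt[hit])
  }
  deg
}

#' Cross-set connectivity
#'
#' The number of network edges with one endpoint in \code{set_a} and the
#' other in \code{set_b} (one degree of connectivity per gene pair). The
#' sets must be disjoint; genes absent from the network contribute zero.
#'
#' @param net an \code{"interaction_network"}.
#' @param set_a,set_b disjoint character vectors of gene symbols.
#' @return integer edge count.
#' @export
connectivity <- function(net, set_a, set_b) {
  set_a <- unique(as_gene_symbols(set_a))
  set_b <- unique(as_gene_symbols(set_b))
  if (length(intersect(set_a, set_b)))
    stop("set_a and set_b must be disjoint", call. = FALSE)
  a <- net$edges[, 1L]; b <- net$edges[, 2L]
  sum((a %in% set_a & b %in% set_b) | (a %in% set_b & b %in% set_a))
}

#' Seed-connectivity permutation test
#'
#' Tests whether the observed connectivity between a seed set A and a
#' disjoint test set B exceeds what same-sized random gene sets achieve.
#' Each of \code{n_perm} replicates replaces B by an equal number of genes
#' drawn uniformly (by default without replacement) from the declared
#' background, excluding the seed set; the null connectivity is recorded and
#' the empirical p-value uses the add-one estimator (r+1)/(n+1), where r is
#' the number of null values >= observed. When no null value reaches the
#' observed connectivity the upper bound 1/n_perm is also reported and used
#' for the Bonferroni-corrected headline, min(1, n_tests / n_perm).
#'
#' Background genes absent from the network simply contribute zero
#' connectivity, mirroring a declared protein-coding background larger than
#' the network.
#'
#' @param net an \code{"interaction_network"}.
#' @param set_a seed gene set.
#' @param set_b test gene set, disjoint from \code{set_a}.
#' @param background character vector of background genes to draw
#'   replacements from; must contain at least \code{|set_b|} genes after
#'   excluding the seeds.
#' @param n_perm number of permutations (default 50000).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param n_tests number of disease comparisons in the session, for the
#'   Bonferroni correction (default 1).
#' @param with_replacement draw replacement genes with replacement within a
#'   replicate (default \code{FALSE}).
#' @param allow_seed_overlap keep seed genes in the background pool
#'   (default \code{FALSE}: replacements never overlap the seeds).
#' @return a \code{"connectivity_test"}: list with \code{observed},
#'   \code{null_values}, \code{n_perm}, \code{r_ge}, \code{empirical_p},
#'   \code{p_upper_bound} (\code{NA} unless \code{r_ge == 0}),
#'   \code{corrected_p}, \code{n_tests}, \code{seed}, \code{set_sizes}.
#' @export
permutation_test <- function(net, set_a, set_b, background,
                             n_perm = 50000L, seed, n_tests = 1L,
                             with_replacement = FALSE,
                             allow_seed_overlap = FALSE) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  set_a <- unique(as_gene_symbols(set_a))
  set_b <- unique(as_gene_symbols(set_b))
  background <- unique(as_gene_symbols(background))
  if (!allow_seed_overlap) background <- setdiff(background, set_a)
  m <- length(set_b)
  if (length(background) < m)
    stop("background smaller than |set_b|", call. = FALSE)
  observed <- connectivity(net, set_a, set_b)
  w <- seed_degree(net, set_a, universe = background)
  nbg <- length(background)
  null_values <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      sum(w[sample.int(nbg, m, replace = with_replacement)]), 0)
  })
  r_ge <- sum(null_values >= observed)
  empirical_p <- (r_ge + 1) / (n_perm + 1)
  p_upper_bound <- if (r_ge == 0L) 1 / n_perm else NA_real_
  headline <- if (r_ge == 0L) p_upper_bound else empirical_p
  structure(list(observed = observed, null_values = as.integer(null_values),
                 n_perm = as.integer(n_perm), r_ge = r_ge,
                 empirical_p = empirical_p, p_upper_bound = p_upper_bound,
                 corrected_p = min(1, n_tests * headline),
                 n_tests = as.integer(n_tests), seed = seed,
                 set_sizes = c(a = length(set_a), b = m)),
            class = "connectivity_test")
}

#' @export
print.connectivity_test <- function(x, ...) {
  cat(sprintf("Seed-connectivity permutation test (|A| = %d, |B| = %d, %d permutations)\n",
              x$set_sizes[["a"]], x$set_sizes[["b"]], x$n_perm))
  cat(sprintf("  observed connectivity: %d (null max %d, null mean %.1f)\n",
              x$observed, max(x$null_values), mean(x$null_values)))
  if (x$r_ge == 0L)
    cat(sprintf("  empirical p < %.3g (no null value reached the observation)\n",
                x$p_upper_bound))
  else
    cat(sprintf("  empirical p = %.3g\n", x$empirical_p))
  cat(sprintf("  Bonferroni-corrected (%d tests): %s %.3g\n", x$n_tests,
              if (x$r_ge == 0L) "<" else "=", x$corrected_p))
  invisible(x)
}

#' Plot the permutation null distribution
#'
#' Histogram of the null connectivity values with the observed connectivity
#' marked as a vertical line.
#'
#' @param x a \code{"connectivity_test"}.
#' @param ... passed to [graphics::hist()].
#' @return \code{x}, invisibly.
#' @export
plot.connectivity_test <- function(x, ...) {
  graphics::hist(x$null_values,
                 xlim = range(c(x$null_values, x$observed)),
                 main = "Permutation null connectivity",
                 xlab = "cross-set edge count", ...)
  graphics::abline(v = x$observed, col = "red", lwd = 2)
  invisible(x)
}

#' Rank candidate genes by contributing connectivity to a seed set
#'
#' A candidate's contributing connectivity is the number of seed genes it is
#' directly adjacent to. Candidates are ranked in decreasing order; ties are
#' broken by higher total network degree, then lexicographically, so the
#' ranking is deterministic.
#'
#' @param net an \code{"interaction_network"}.
#' @param seeds seed gene set.
#' @param candidates candidate genes, disjoint from \code{seeds}; genes
#'   absent from the network rank last with count 0.
#' @return data.frame \code{gene}, \code{contributing_connectivity},
#'   \code{degree}, sorted as described.
#' @export
rank_by_seed_connectivity <- function(net, seeds, candidates) {
  seeds <- unique(as_gene_symbols(seeds))
  candidates <- unique(as_gene_symbols(candidates))
  if (length(intersect(seeds, candidates)))
    stop("seeds and candidates must be disjoint", call. = FALSE)
  cc <- seed_degree(net, seeds, universe = candidates)
  all_deg <- table(as.vector(net$edges))
  deg <- stats::setNames(integer(length(candidates)), candidates)
  hit <- intersect(candidates, names(all_deg))
  deg[hit] <- as.integer(all_deg[hit])
  ord <- order(-cc, -deg, candidates)
  data.frame(gene = candidates[ord],
             contributing_connectivity = as.integer(cc[ord]),
             degree = deg[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Count diseases a gene connects to
#'
#' The number of disease sets in the catalog to which the gene has at least
#' one direct network edge (the gene itself is excluded from each set before
#' checking adjacency; every disease, including any set containing the gene,
#' is counted).
#'
#' @param net an \code{"interaction_network"}.
#' @param gene a single gene symbol.
#' @param catalog disease gene catalog.
#' @return integer count of connected diseases.
#' @export
cross_disease_connectivity <- function(net, gene, catalog) {
  gene <- as_gene_symbols(gene)
  stopifnot(length(gene) == 1L)
  catalog <- check_catalog(catalog)
  neigh <- unique(c(net$edges[net$edges[, 1L] == gene, 2L],
                    net$edges[net$edges[, 2L] == gene, 1L]))
  sum(vapply(catalog, function(g)
    length(intersect(neigh, setdiff(g, gene))) > 0L, FALSE))
}
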