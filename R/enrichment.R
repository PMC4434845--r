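#' Size-filter a gene-set database
#'
#' Keeps pathways whose size, measured after restricting to the background
#' universe (when one is given), lies within \code{[min_size, max_size]}
#' inclusive. Broad terms carry little biological signal and tiny terms no
#' statistical power, hence the default 15--1000 window.
#'
#' @param db a \code{"gene_set_db"}.
#' @param min_size,max_size inclusive size bounds (defaults 15 and 1000).
#' @param background optional character vector: the gene universe sets are
#'   intersected with before measuring size.
#' @return the filtered \code{"gene_set_db"} (sets restricted to the
#'   background when one is given).
#' @export
filter_gene_sets <- function(db, min_size = 15L, max_size = 1000L,
                             background = NULL) {
  stopifnot(min_size <= max_size)
  if (!is.null(background)) background <- as_gene_symbols(background)
  out <- lapply(db, function(s) {
    g <- if (is.null(background)) s$genes else intersect(s$genes, background)
    if (length(g) >= min_size && length(g) <= max_size)
      list(source = s$source, genes = g)
    else NULL
  })
  out <- out[!vapply(out, is.null, FALSE)]
  structure(out, class = "gene_set_db")
}

#' One-sided Fisher's exact enrichment p-value
#'
#' Hypergeometric upper tail P(X >= k) for the overlap k between a query
#' gene set and a pathway inside a background universe of
#' \code{background_n} genes: the probability of drawing at least k pathway
#' genes when sampling \code{|query|} genes from the universe.
#'
#' @param query character vector of query genes (restricted to the
#'   universe).
#' @param pathway character vector of pathway genes (restricted to the
#'   universe).
#' @param background_n size of the gene universe.
#' @return the one-sided enrichment p-value.
#' @export
fisher_enrichment <- function(query, pathway, background_n) {
  query <- unique(as_gene_symbols(query))
  pathway <- unique(as_gene_symbols(pathway))
  nq <- length(query); np <- length(pathway)
  k <- length(intersect(query, pathway))
  if (nq > background_n || np > background_n ||
      background_n - np - nq + k < 0)
    stop("inconsistent 2x2 table: sets larger than background", call. = FALSE)
  stats::phyper(k - 1L, np, background_n - np, nq, lower.tail = FALSE)
}

#' Benjamini--Hochberg step-up FDR adjustment
#'
#' @param p_values numeric vector of p-values in \code{[0, 1]}.
#' @return adjusted q-values, aligned with the input, capped at 1 and
#'   element-wise \code{>= p}.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Full enrichment scan of a query set against a gene-set database
#'
#' Runs the one-sided Fisher test for every pathway, adjusts across the
#' whole scan with Benjamini--Hochberg, and flags pathways significant under
#' the dual rule p < \code{p_cut} AND q < \code{q_cut} (defaults 1e-3 and
#' 0.01). The query is intersected with the background universe when one is
#' given, keeping the 2x2 margins consistent; the database should already be
#' size-filtered (see [filter_gene_sets()]).
#'
#' @param query character vector of query genes (non-empty).
#' @param db a \code{"gene_set_db"}, already size-filtered.
#' @param background either a single number (universe size; sets and query
#'   used as-is) or a character vector of universe genes (query and sets
#'   intersected with it). Default 23510, a protein-coding genome scale.
#' @param p_cut,q_cut dual significance thresholds.
#' @return an \code{"enrichment_result"} data.frame with columns
#'   \code{pathway}, \code{source}, \code{set_size}, \code{overlap},
#'   \code{p_value}, \code{q_value}, \code{significant}, ordered by
#'   increasing p.
#' @export
enrich_all <- function(query, db, background = 23510,
                       p_cut = 1e-3, q_cut = 0.01) {
  query <- unique(as_gene_symbols(query))
  if (length(query) == 0L) stop("empty query set", call. = FALSE)
  if (is.character(background)) {
    universe <- unique(as_gene_symbols(background))
    n_bg <- length(universe)
    query <- intersect(query, universe)
    if (length(query) == 0L)
      stop("query has no genes in the background universe", call. = FALSE)
    sets <- lapply(db, function(s) intersect(s$genes, universe))
  } else {
    n_bg <- as.integer(background)
    sets <- lapply(db, function(s) unique(s$genes))
  }
  res <- data.frame(
    pathway = names(db),
    source = vapply(db, function(s) s$source, ""),
    set_size = vapply(sets, length, 0L),
    overlap = vapply(sets, function(g) length(intersect(query, g)), 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$p_value <- vapply(sets, function(g)
    fisher_enrichment(query, g, n_bg), 0)
  res$q_value <- bh_fdr(res$p_value)
  res$significant <- res$p_value < p_cut & res$q_value < q_cut
  res <- res[order(res$p_value, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  attr(res, "query_size") <- length(query)
  attr(res, "background_n") <- n_bg
  res
}

#' Count pathways significant in two enrichment scans
#'
#' @param results_a,results_b \code{"enrichment_result"} tables over the
#'   same database.
#' @return integer: number of pathway names flagged significant in both.
#' @export
pathway_overlap <- function(results_a, results_b) {
  length(intersect(results_a$pathway[results_a$significant],
                   results_b$pathway[results_b$significant]))
}

#' @export
print.enrichment_result <- function(x, n = 5L, ...) {
  cat(sprintf("Enrichment scan: %d pathways, query size %d, background %d\n",
              nrow(x), attr(x, "query_size"), attr(x, "background_n")))
  cat(sprintf("  significant (dual rule): %d\n", sum(x$significant)))
  print.data.frame(utils::head(x, n))
  invisible(x)
}
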