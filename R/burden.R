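#' Build compound exon models
#'
#' Merges each gene's exon intervals across all isoforms into maximal
#' non-overlapping blocks (the compound exon model). Intervals are 0-based
#' half-open; touching blocks (one's end equals the next's start) merge into
#' a single breakpoint. Duplicated isoforms therefore never change the model.
#'
#' @param exons data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{gene} as returned by [read_exon_bed()].
#' @return named list (by gene) of \code{"compound_exon_model"} objects:
#'   list with \code{gene} and a data.frame \code{intervals} (\code{chrom},
#'   \code{start}, \code{end}, \code{length}), sorted, pairwise disjoint.
#' @export
build_compound_exons <- function(exons) {
  stopifnot(all(c("chrom", "start", "end", "gene") %in% names(exons)))
  if (any(exons$end <= exons$start) || any(exons$start < 0))
    stop("require 0 <= start < end for every interval", call. = FALSE)
  ord <- order(exons$gene, exons$chrom, exons$start, exons$end)
  g <- exons$gene[ord]; chr <- exons$chrom[ord]
  s <- exons$start[ord]; e <- exons$end[ord]
  n <- length(s)
  new_grp <- c(TRUE, g[-1L] != g[-n] | chr[-1L] != chr[-n])
  # running max end within each (gene, chrom) run
  ce <- stats::ave(e, cumsum(new_grp), FUN = cummax)
  # a new merged block starts at a group boundary or a gap (touching merges)
  new_block <- new_grp | c(TRUE, s[-1L] > ce[-n])
  block <- cumsum(new_block)
  b_start <- s[new_block]
  b_end <- as.integer(tapply(e, block, max))
  blocks <- data.frame(gene = g[new_block], chrom = chr[new_block],
                       start = b_start, end = b_end,
                       length = b_end - b_start, stringsAsFactors = FALSE)
  out <- lapply(split(blocks[-1L], blocks$gene), function(iv) {
    rownames(iv) <- NULL
    structure(list(gene = NA_character_, intervals = iv),
              class = "compound_exon_model")
  })
  for (nm in names(out)) out[[nm]]$gene <- nm
  out[order(names(out))]
}

#' Total compound exon length of a model
#' @param model a \code{"compound_exon_model"}.
#' @return integer total length in bp.
#' @export
compound_length <- function(model) sum(model$intervals$length)

.lof_consequences <- c("stop_gained", "frameshift", "splice_donor",
                       "splice_acceptor")

#' Filter variants to the deleterious set
#'
#' Keeps rare missense variants (allele frequency strictly below
#' \code{maf_threshold}) and all loss-of-function variants (stop-gain,
#' frameshift, canonical splice donor/acceptor) regardless of frequency.
#' Synonymous and "other" consequences are dropped.
#'
#' @param variants data.frame as returned by [read_variant_table()].
#' @param maf_threshold rarity cutoff for missense variants, in (0, 1);
#'   default 0.01 (the conventional rare-variant cutoff).
#' @return the deleterious subset of \code{variants}.
#' @export
classify_deleterious <- function(variants, maf_threshold = 0.01) {
  stopifnot(maf_threshold > 0, maf_threshold < 1)
  keep <- (variants$consequence == "missense" &
             variants$allele_frequency < maf_threshold) |
    variants$consequence %in% .lof_consequences
  variants[keep, , drop = FALSE]
}

#' Per-exon deleterious burden for one gene
#'
#' Assigns each (pre-filtered) deleterious variant to the compound exon
#' containing it and normalizes the count by exon length in bp. Variant
#' positions are 1-based; exon intervals 0-based half-open, so position
#' \code{p} falls in \code{[start, end)} when \code{start < p <= end}.
#' Variants outside every exon are counted but not assigned.
#'
#' @param model a \code{"compound_exon_model"}.
#' @param deleterious variant data.frame, already filtered by
#'   [classify_deleterious()]; only rows matching the model's gene are used.
#' @return a \code{"burden_profile"}: data.frame \code{chrom, start, end,
#'   length, count, burden} with attribute \code{n_outside}.
#' @export
exon_burden <- function(model, deleterious) {
  iv <- model$intervals
  v <- deleterious[deleterious$gene == model$gene, , drop = FALSE]
  res <- exon_variant_counts(iv, v$chrom, v$pos)
  out <- data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
                    length = iv$length, count = res$counts,
                    burden = res$counts / iv$length,
                    stringsAsFactors = FALSE)
  attr(out, "n_outside") <- res$n_outside
  class(out) <- c("burden_profile", "data.frame")
  out
}

# Count 1-based positions per compound exon block (intervals sorted by
# chrom, start and pairwise disjoint): position p lands in [start, end)
# 0-based half-open, i.e. start < p <= end.
exon_variant_counts <- function(iv, chrom, pos) {
  counts <- integer(nrow(iv))
  n_outside <- 0L
  if (length(pos)) {
    for (chr in unique(chrom)) {
      on_chr <- which(iv$chrom == chr)
      p <- pos[chrom == chr]
      if (!length(on_chr)) { n_outside <- n_outside + length(p); next }
      j <- findInterval(p, iv$start[on_chr] + 1L)
      inside <- j >= 1L & p <= iv$end[on_chr][pmax(j, 1L)]
      n_outside <- n_outside + sum(!inside)
      tab <- tabulate(j[inside], nbins = length(on_chr))
      counts[on_chr] <- counts[on_chr] + tab
    }
  }
  list(counts = counts, n_outside = n_outside)
}

#' Pooled per-exon burdens for a gene set
#'
#' Convenience wrapper: the burden observations a disease gene set
#' contributes to the distributional comparison. By default one observation
#' per compound exon (length-normalized deleterious count), pooled across
#' all genes of the set; \code{per_gene = TRUE} instead yields each gene's
#' mean exon burden.
#'
#' @param models named list of compound exon models, as from
#'   [build_compound_exons()].
#' @param deleterious pre-filtered deleterious variants.
#' @param genes gene symbols of the set (genes without a model are ignored).
#' @param per_gene collapse to gene-level mean burdens.
#' @return numeric vector of burden observations.
#' @export
set_burden <- function(models, deleterious, genes, per_gene = FALSE) {
  genes <- intersect(as_gene_symbols(genes), names(models))
  by_gene <- split(deleterious[c("chrom", "pos")], deleterious$gene)
  empty <- data.frame(chrom = character(0), pos = integer(0))
  obs <- lapply(models[genes], function(m) {
    v <- by_gene[[m$gene]]
    if (is.null(v)) v <- empty
    res <- exon_variant_counts(m$intervals, v$chrom, v$pos)
    res$counts / m$intervals$length
  })
  if (per_gene) vapply(obs, mean, 0) else unlist(obs, use.names = FALSE)
}

#' Two-sample Kolmogorov--Smirnov comparison of burden distributions
#'
#' Two-sided K-S test: D is the supremum distance between the two empirical
#' CDFs; the p-value comes from the asymptotic Kolmogorov distribution with
#' effective sample size n_a*n_b/(n_a+n_b). Ties (common with count-based
#' burdens) make the asymptotic p approximate, as usual for the K-S test.
#'
#' @param burdens_a,burdens_b non-empty numeric vectors of burden
#'   observations.
#' @return a \code{"ks_result"}: list with \code{D}, \code{p_value},
#'   \code{n_a}, \code{n_b}.
#' @export
ks_compare <- function(burdens_a, burdens_b) {
  if (length(burdens_a) == 0L || length(burdens_b) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(burdens_a, burdens_b,
                                        exact = FALSE))
  structure(list(D = unname(kt$statistic), p_value = kt$p.value,
                 n_a = length(burdens_a), n_b = length(burdens_b)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample K-S: D = %.4f, p = %.3g (n = %d vs %d)\n",
              x$D, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' @export
print.compound_exon_model <- function(x, ...) {
  cat(sprintf("Compound exon model for %s: %d blocks, %d bp\n",
              x$gene, nrow(x$intervals), compound_length(x)))
  invisible(x)
}
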