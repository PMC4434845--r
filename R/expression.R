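#' Linear-interpolation percentile
#'
#' The percentile convention used throughout the expression module: sort the
#' values and interpolate linearly at index \code{(q/100) * (n - 1)}
#' (0-based). This is R's quantile type 7 and is pinned here for
#' reproducibility.
#'
#' @param values non-empty numeric vector.
#' @param q percentile in (0, 100); default 75.
#' @return the percentile value.
#' @export
percentile_threshold <- function(values, q = 75) {
  if (length(values) == 0L) stop("values must be non-empty", call. = FALSE)
  stopifnot(q > 0, q < 100)
  stats::quantile(values, q / 100, type = 7, names = FALSE)
}

#' Highly-expressed transcript abundance for a gene set
#'
#' A transcript is "highly expressed" when its mean FPKM across samples
#' exceeds the genome-wide 75th-percentile cutoff of transcript mean FPKM.
#' Per gene, the number of highly-expressed transcripts is counted; the
#' function returns that count averaged over the gene set and over the whole
#' genome (all annotated genes), for comparison against the genome average.
#'
#' @param fpkm an \code{"expression_matrix"} of transcripts by samples with
#'   a \code{row_to_gene} mapping.
#' @param gene_set character vector of gene symbols.
#' @param q percentile cutoff (default 75).
#' @param per_sample if \code{TRUE}, threshold within each sample (per-sample
#'   genome cutoff) and average the per-sample counts, instead of
#'   thresholding the across-sample mean (the default reading).
#' @return list with \code{set_mean}, \code{genome_mean}, \code{cutoff}
#'   (\code{NA} for \code{per_sample = TRUE}), \code{n_set_genes}.
#' @export
transcript_abundance <- function(fpkm, gene_set, q = 75,
                                 per_sample = FALSE) {
  if (is.null(fpkm$row_to_gene))
    stop("fpkm must carry a transcript-to-gene mapping", call. = FALSE)
  gene_set <- as_gene_symbols(gene_set)
  genes <- fpkm$row_to_gene
  missing <- setdiff(gene_set, genes)
  present <- intersect(gene_set, genes)
  if (length(present) == 0L)
    stop("gene set absent from annotation: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (per_sample) {
    counts_by_sample <- apply(fpkm$values, 2L, function(col) {
      cut <- percentile_threshold(col, q)
      tapply(col > cut, genes, sum)
    })
    per_gene <- rowMeans(counts_by_sample)
    cutoff <- NA_real_
  } else {
    m <- rowMeans(fpkm$values)
    cutoff <- percentile_threshold(m, q)
    per_gene <- tapply(m > cutoff, genes, sum)
  }
  list(set_mean = mean(per_gene[present]),
       genome_mean = mean(per_gene),
       cutoff = cutoff,
       n_set_genes = length(present))
}

#' Tissue protein-expression profile of a gene set
#'
#' For a gene-by-tissue spectral-count matrix: per tissue, the mean spectral
#' count over the set's genes, and the ratio of set genes expressed above
#' the 75th-percentile cutoff of the entire genome dataset (by default one
#' global cutoff over the pooled gene-by-tissue value matrix).
#'
#' @param spectra an \code{"expression_matrix"} of genes by tissues;
#'   \code{col_groups} (if present) labels developmental period and
#'   hematopoietic columns and is carried into the summary.
#' @param gene_set character vector of gene symbols.
#' @param q percentile cutoff (default 75).
#' @param per_tissue_cutoff compute the cutoff within each tissue column
#'   instead of one global cutoff.
#' @return a \code{"tissue_expression_summary"}: list with
#'   \code{per_tissue_mean}, \code{per_tissue_ratio}, \code{cutoff},
#'   \code{n_set_genes}, \code{col_groups}.
#' @export
tissue_profile <- function(spectra, gene_set, q = 75,
                           per_tissue_cutoff = FALSE) {
  gene_set <- as_gene_symbols(gene_set)
  rows <- rownames(spectra$values)[toupper(rownames(spectra$values)) %in%
                                     gene_set]
  if (length(rows) == 0L)
    stop("gene set has no overlap with the expression matrix rows",
         call. = FALSE)
  sub <- spectra$values[rows, , drop = FALSE]
  if (per_tissue_cutoff) {
    cutoff <- apply(spectra$values, 2L, percentile_threshold, q = q)
    above <- sweep(sub, 2L, cutoff, `>`)
  } else {
    cutoff <- percentile_threshold(as.vector(spectra$values), q)
    above <- sub > cutoff
  }
  structure(list(
    per_tissue_mean = colMeans(sub),
    per_tissue_ratio = colMeans(above),
    cutoff = cutoff,
    n_set_genes = length(rows),
    col_groups = spectra$col_groups
  ), class = "tissue_expression_summary")
}

#' @export
print.tissue_expression_summary <- function(x, ...) {
  cat(sprintf("Tissue expression summary (%d set genes, cutoff %s)\n",
              x$n_set_genes,
              paste(format(x$cutoff, digits = 4), collapse = "/")))
  top <- sort(x$per_tissue_mean, decreasing = TRUE)[1:min(3, length(x$per_tissue_mean))]
  cat("  highest mean spectra:",
      paste(sprintf("%s (%.2f)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Hematopoietic expression fold
#'
#' Ratio of the mean highly-expressed fraction (or mean spectral count) over
#' hematopoietic tissues to the mean over all other tissues. Returns
#' \code{Inf} when only hematopoietic tissues carry signal and \code{NaN}
#' (with a warning) when neither group does.
#'
#' @param summary a \code{"tissue_expression_summary"}.
#' @param hematopoietic_labels tissue column names of the hematopoietic
#'   group; defaults to columns labelled \code{"hematopoietic"} in the
#'   summary's \code{col_groups}.
#' @param statistic \code{"ratio"} (default; fraction of set genes above the
#'   genome cutoff) or \code{"mean"} (mean spectral counts).
#' @return the fold as a single numeric value.
#' @export
hematopoietic_fold <- function(summary, hematopoietic_labels = NULL,
                               statistic = c("ratio", "mean")) {
  statistic <- match.arg(statistic)
  vals <- if (statistic == "ratio") summary$per_tissue_ratio
          else summary$per_tissue_mean
  if (is.null(hematopoietic_labels)) {
    if (is.null(summary$col_groups))
      stop("no hematopoietic labels given and no col_groups in summary",
           call. = FALSE)
    hematopoietic_labels <-
      names(summary$col_groups)[summary$col_groups == "hematopoietic"]
  }
  hem <- intersect(names(vals), hematopoietic_labels)
  oth <- setdiff(names(vals), hematopoietic_labels)
  if (length(hem) == 0L || length(oth) == 0L)
    stop("both tissue groups must be non-empty", call. = FALSE)
  num <- mean(vals[hem]); den <- mean(vals[oth])
  if (num == 0 && den == 0) {
    warning("fold undefined: no signal in either tissue group",
            call. = FALSE)
    return(NaN)
  }
  if (den == 0) return(Inf)
  num / den
}

#' Comparative threshold cycle (delta-delta-CT) arithmetic
#'
#' Relative quantification for qPCR: \code{delta = ct_target -
#' ct_reference}; \code{ddct = delta - calibrator_delta}; relative quantity
#' \code{rq = 2^(-ddct)}.
#'
#' @param ct_target threshold cycle of the target gene.
#' @param ct_reference threshold cycle of the endogenous reference
#'   (e.g. GAPDH).
#' @param calibrator_delta the calibrator sample's delta-CT (0 for delta-CT
#'   only normalization).
#' @return list with \code{delta}, \code{ddct}, \code{rq}.
#' @export
delta_delta_ct <- function(ct_target, ct_reference, calibrator_delta = 0) {
  stopifnot(is.finite(ct_target), is.finite(ct_reference),
            is.finite(calibrator_delta))
  delta <- ct_target - ct_reference
  ddct <- delta - calibrator_delta
  list(delta = delta, ddct = ddct, rq = 2^(-ddct))
}
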