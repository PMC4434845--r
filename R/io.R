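#' Read disease gene lists
#'
#' Reads a two-column tab-separated file of \code{disease<TAB>gene} rows into
#' a disease gene catalog: a named list mapping each disease label to its set
#' of uppercased gene symbols. A header row is auto-detected by the reserved
#' tokens \code{"disease"} and \code{"gene"} (case-insensitive). Duplicate
#' genes within a disease are collapsed.
#'
#' @param path path to the TSV file.
#' @param strict if \code{TRUE} (default) malformed rows abort with a
#'   line-numbered error; if \code{FALSE} they are skipped with a warning.
#' @return named list of character vectors (class
#'   \code{"disease_gene_catalog"}).
#' @export
read_gene_lists <- function(path, strict = TRUE) {
  lines <- read_tsv_lines(path)
  start <- 1L
  first <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(first) >= 2L &&
      all(tolower(first[1:2]) %in% c("disease", "gene"))) start <- 2L
  if (start > length(lines)) stop(sprintf("%s: no data rows", path),
                                  call. = FALSE)
  disease <- character(0); gene <- character(0)
  for (i in seq(start, length(lines))) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 2L || !all(nzchar(trimws(f)))) {
      if (strict) stop_line(path, i, "expected 2 non-empty tab-separated fields")
      warning(sprintf("%s:%d: skipping malformed row", path, i), call. = FALSE)
      next
    }
    disease <- c(disease, trimws(f[[1L]]))
    gene <- c(gene, f[[2L]])
  }
  gene <- as_gene_symbols(gene)
  catalog <- lapply(split(gene, disease), function(g) sort(unique(g)))
  catalog <- catalog[unique(disease)]  # preserve first-seen disease order
  structure(catalog, class = "disease_gene_catalog")
}

#' Write disease gene lists
#'
#' Inverse of [read_gene_lists()]: writes a catalog as a headered two-column
#' TSV. \code{read_gene_lists(write_gene_lists(x, p))} recovers \code{x}.
#'
#' @param catalog named list of gene-symbol vectors.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gene_lists <- function(catalog, path) {
  catalog <- check_catalog(catalog)
  rows <- unlist(lapply(names(catalog), function(d)
    paste(d, sort(unique(catalog[[d]])), sep = "\t")), use.names = FALSE)
  writeLines(c("disease\tgene", rows), path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' \code{name<TAB>source<TAB>gene1<TAB>gene2...}. Gene symbols are uppercased
#' and de-duplicated within a set.
#'
#' @param path path to the GMT file.
#' @return a gene-set database (class \code{"gene_set_db"}): named list with
#'   elements \code{list(source =, genes =)}.
#' @export
read_gmt <- function(path) {
  lines <- read_tsv_lines(path)
  db <- vector("list", length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop_line(path, i, "GMT line needs >= 3 tab-separated fields")
    if (any(!nzchar(f)))
      stop_line(path, i, "empty field in GMT line")
    nm[[i]] <- f[[1L]]
    db[[i]] <- list(source = f[[2L]],
                    genes = sort(unique(as_gene_symbols(f[-(1:2)]))))
  }
  if (anyDuplicated(nm))
    stop(sprintf("%s: duplicate pathway name(s): %s", path,
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")),
         call. = FALSE)
  names(db) <- nm
  structure(db, class = "gene_set_db")
}

#' Write a GMT gene-set file
#' @param db gene-set database as returned by [read_gmt()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(names(db), function(nm) {
    paste(c(nm, db[[nm]]$source, sort(unique(db[[nm]]$genes))),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene--gene interaction edge list
#'
#' Two or three tab-separated columns: \code{geneA<TAB>geneB[<TAB>weight]}.
#' Self-loops are dropped and symmetric pairs \code{(a,b)}/\code{(b,a)} are
#' collapsed to one undirected pair (one degree of connectivity per pair);
#' the number of dropped rows is recorded in the result.
#'
#' @param path path to the TSV file.
#' @return an \code{"edge_list"}: list with \code{pairs} (two-column
#'   character matrix, each row lexicographically ordered), \code{weight}
#'   (numeric or \code{NULL}; first-seen weight per pair) and
#'   \code{n_dropped} (self-loops plus duplicate/symmetric rows removed).
#' @export
read_edge_list <- function(path) {
  lines <- read_tsv_lines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L | nf > 3L))
    stop_line(path, which(nf < 2L | nf > 3L)[1L],
              "expected 2 or 3 tab-separated fields")
  a <- as_gene_symbols(vapply(parts, `[[`, "", 1L))
  b <- as_gene_symbols(vapply(parts, `[[`, "", 2L))
  w <- NULL
  if (any(nf == 3L)) {
    if (!all(nf == 3L))
      stop(sprintf("%s: mixed 2- and 3-column rows", path), call. = FALSE)
    wraw <- vapply(parts, `[[`, "", 3L)
    w <- suppressWarnings(as.numeric(wraw))
    if (anyNA(w))
      stop_line(path, which(is.na(w))[1L], "non-numeric weight column")
  }
  as_edge_list(a, b, w)
}

# Build a cleaned undirected edge list from endpoint vectors.
as_edge_list <- function(a, b, w = NULL) {
  n_in <- length(a)
  self <- a == b
  a <- a[!self]; b <- b[!self]
  if (!is.null(w)) w <- w[!self]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  keep <- !duplicated(key)
  pairs <- cbind(lo[keep], hi[keep])
  colnames(pairs) <- c("gene_a", "gene_b")
  structure(list(pairs = pairs,
                 weight = if (is.null(w)) NULL else w[keep],
                 n_dropped = n_in - sum(keep)),
            class = "edge_list")
}

#' Write an edge list
#' @param edges an \code{"edge_list"} or two-column character matrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  if (inherits(edges, "edge_list")) {
    m <- edges$pairs
    rows <- if (is.null(edges$weight)) paste(m[, 1L], m[, 2L], sep = "\t")
            else paste(m[, 1L], m[, 2L], edges$weight, sep = "\t")
  } else rows <- paste(edges[, 1L], edges[, 2L], sep = "\t")
  writeLines(rows, path)
  invisible(path)
}

#' Read exon intervals (BED3 + gene name)
#'
#' BED convention: 0-based, half-open \code{[start, end)}. Columns:
#' \code{chrom<TAB>start<TAB>end<TAB>gene}.
#'
#' @param path path to the BED file.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{gene}.
#' @export
read_exon_bed <- function(path) {
  lines <- read_tsv_lines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4L))
    stop_line(path, which(nf != 4L)[1L], "expected 4 tab-separated fields")
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop_line(path, which(is.na(start) | is.na(end))[1L],
              "non-integer start/end")
  bad <- start < 0L | end <= start
  if (any(bad))
    stop_line(path, which(bad)[1L], "require 0 <= start < end (half-open)")
  data.frame(chrom = vapply(parts, `[[`, "", 1L),
             start = start, end = end,
             gene = as_gene_symbols(vapply(parts, `[[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' Write exon intervals as BED3 + gene
#' @param exons data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{gene} (0-based half-open).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_exon_bed <- function(exons, path) {
  writeLines(paste(exons$chrom, exons$start, exons$end, exons$gene,
                   sep = "\t"), path)
  invisible(path)
}

.consequences <- c("missense", "stop_gained", "frameshift", "splice_donor",
                   "splice_acceptor", "synonymous", "other")

#' Read a variant table
#'
#' Tab-separated columns \code{gene}, \code{chrom}, \code{pos} (1-based),
#' \code{consequence} (closed vocabulary: missense, stop_gained, frameshift,
#' splice_donor, splice_acceptor, synonymous, other) and
#' \code{allele_frequency} in \code{[0, 1]}. A header row is auto-detected.
#'
#' @param path path to the TSV file.
#' @param strict hard-fail on malformed rows (default) or warn-and-skip.
#' @return data.frame with the five validated columns.
#' @export
read_variant_table <- function(path, strict = TRUE) {
  lines <- read_tsv_lines(path)
  start <- 1L
  first <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(first) >= 1L && tolower(first[[1L]]) == "gene") start <- 2L
  if (start > length(lines)) stop(sprintf("%s: no data rows", path),
                                  call. = FALSE)
  keep <- list()
  for (i in seq(start, length(lines))) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    pos <- suppressWarnings(as.integer(f[3L]))
    af <- suppressWarnings(as.numeric(f[5L]))
    ok <- length(f) == 5L && !is.na(pos) && pos >= 1L &&
      f[[4L]] %in% .consequences && !is.na(af) && af >= 0 && af <= 1
    if (!ok) {
      if (strict) stop_line(path, i,
        "expected gene, chrom, pos >= 1, consequence in vocabulary, AF in [0,1]")
      warning(sprintf("%s:%d: skipping malformed row", path, i), call. = FALSE)
      next
    }
    keep[[length(keep) + 1L]] <- list(f[[1L]], f[[2L]], pos, f[[4L]], af)
  }
  if (length(keep) == 0L) stop(sprintf("%s: no valid rows", path),
                               call. = FALSE)
  data.frame(gene = as_gene_symbols(vapply(keep, `[[`, "", 1L)),
             chrom = vapply(keep, `[[`, "", 2L),
             pos = vapply(keep, `[[`, 0L, 3L),
             consequence = vapply(keep, `[[`, "", 4L),
             allele_frequency = vapply(keep, `[[`, 0, 5L),
             stringsAsFactors = FALSE)
}

#' Write a variant table
#' @param variants data.frame as returned by [read_variant_table()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  writeLines(c("gene\tchrom\tpos\tconsequence\tallele_frequency",
               paste(variants$gene, variants$chrom, variants$pos,
                     variants$consequence,
                     format(variants$allele_frequency, digits = 15,
                            scientific = FALSE, trim = TRUE),
                     sep = "\t")), path)
  invisible(path)
}

#' Read an expression matrix
#'
#' Tab-separated matrix with a header of column identifiers (samples or
#' tissues) and row identifiers in the first column (named \code{id}). An
#' optional second column named \code{gene} maps transcript rows to gene
#' symbols. All values must be non-negative and finite.
#'
#' @param path path to the TSV file.
#' @param col_groups optional named character vector mapping column ids to
#'   group labels (e.g. \code{"fetal"}, \code{"adult"},
#'   \code{"hematopoietic"}), or a path to a \code{key=value} file.
#' @return an \code{"expression_matrix"}: list with \code{values} (numeric
#'   matrix with dimnames), \code{row_to_gene} (named character or
#'   \code{NULL}) and \code{col_groups} (named character or \code{NULL}).
#' @export
read_expression_matrix <- function(path, col_groups = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[[1L]] != "id")
    stop(sprintf("%s: first column must be named 'id'", path), call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop(sprintf("%s: duplicate row ids", path), call. = FALSE)
  row_to_gene <- NULL
  vstart <- 2L
  if (names(df)[[2L]] == "gene") {
    row_to_gene <- stats::setNames(as_gene_symbols(df[[2L]]), ids)
    vstart <- 3L
  }
  vals <- as.matrix(df[, vstart:ncol(df), drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyNA(vals) || any(vals < 0) || any(!is.finite(vals)))
    stop(sprintf("%s: values must be finite and >= 0", path), call. = FALSE)
  if (anyDuplicated(colnames(vals)))
    stop(sprintf("%s: duplicate column ids", path), call. = FALSE)
  rownames(vals) <- ids
  if (is.character(col_groups) && length(col_groups) == 1L &&
      is.null(names(col_groups)) && file.exists(col_groups))
    col_groups <- read_key_value(col_groups)
  if (!is.null(col_groups)) {
    missing <- setdiff(colnames(vals), names(col_groups))
    if (length(missing))
      stop("col_groups missing labels for: ",
           paste(missing, collapse = ", "), call. = FALSE)
    col_groups <- col_groups[colnames(vals)]
  }
  expression_matrix(vals, row_to_gene = row_to_gene, col_groups = col_groups)
}

#' Construct an expression matrix object
#'
#' @param values non-negative numeric matrix with unique row and column
#'   names (transcripts or genes by samples or tissues).
#' @param row_to_gene optional named character vector covering every row,
#'   mapping transcript ids to gene symbols.
#' @param col_groups optional named character vector covering every column,
#'   assigning each column a group label.
#' @return an object of class \code{"expression_matrix"}.
#' @export
expression_matrix <- function(values, row_to_gene = NULL, col_groups = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0) || anyNA(values))
    stop("expression values must be non-negative and non-missing",
         call. = FALSE)
  if (!is.null(row_to_gene)) {
    if (!all(rownames(values) %in% names(row_to_gene)))
      stop("row_to_gene must cover every row", call. = FALSE)
    row_to_gene <- stats::setNames(as_gene_symbols(row_to_gene),
                                   names(row_to_gene))[rownames(values)]
  }
  structure(list(values = values, row_to_gene = row_to_gene,
                 col_groups = col_groups),
            class = "expression_matrix")
}

#' Write an expression matrix
#' @param mat an \code{"expression_matrix"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  v <- mat$values
  header <- c("id", if (!is.null(mat$row_to_gene)) "gene", colnames(v))
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i],
            if (!is.null(mat$row_to_gene)) mat$row_to_gene[[rownames(v)[i]]],
            format(v[i, ], digits = 15, scientific = FALSE, trim = TRUE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), body), path)
  invisible(path)
}

#' Read a key=value configuration file
#'
#' One \code{key=value} pair per line; blank lines and lines starting with
#' \code{#} are ignored. Used for column-group labels and run configuration.
#'
#' @param path path to the file.
#' @return named character vector.
#' @export
read_key_value <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad))
    stop(sprintf("%s: line without '=': %s", path, lines[bad][1L]),
         call. = FALSE)
  eq <- regexpr("=", lines, fixed = TRUE)
  stats::setNames(trimws(substring(lines, eq + 1L)),
                  trimws(substring(lines, 1L, eq - 1L)))
}

#' Write a key=value configuration file
#' @param x named character (or coercible) vector.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_key_value <- function(x, path) {
  writeLines(paste0(names(x), "=", as.character(x)), path)
  invisible(path)
}

# Shared line reader: UTF-8, '\t'-delimited, no quoting; blank lines rejected.
read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0L) stop(sprintf("%s: empty file", path),
                                call. = FALSE)
  blank <- !nzchar(trimws(lines))
  if (any(blank)) stop_line(path, which(blank)[1L], "blank line")
  lines
}

#' @export
print.disease_gene_catalog <- function(x, ...) {
  cat(sprintf("Disease gene catalog: %d diseases, %d distinct genes\n",
              length(x), length(unique(unlist(x)))))
  for (d in names(x)) cat(sprintf("  %-6s %4d genes\n", d, length(x[[d]])))
  invisible(x)
}

#' @export
print.gene_set_db <- function(x, ...) {
  sizes <- vapply(x, function(s) length(s$genes), 0L)
  cat(sprintf("Gene-set database: %d sets (sizes %d-%d, median %.0f)\n",
              length(x), min(sizes), max(sizes), stats::median(sizes)))
  invisible(x)
}

#' @export
print.edge_list <- function(x, ...) {
  cat(sprintf("Edge list: %d undirected pairs (%d rows dropped as self-loops/duplicates)\n",
              nrow(x$pairs), x$n_dropped))
  invisible(x)
}
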