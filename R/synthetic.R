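#' Synthetic scenario configuration
#'
#' Bundles every parameter of the synthetic emulators: disease catalog
#' design (set sizes and a membership design of planted shared genes), exome
#' burden rates, expression baselines and boosts, gene-set database shape,
#' and interaction-network densities. All generators derive their RNG stream
#' from \code{seed} (each generator uses a fixed offset of it), so an
#' identical configuration reproduces identical data.
#'
#' @param seed integer RNG seed (mandatory).
#' @param diseases disease labels.
#' @param set_sizes named integer vector of risk-gene set sizes per disease.
#' @param membership_design data.frame with columns \code{pattern}
#'   (\code{"|"}-separated disease labels) and \code{count}: each row plants
#'   \code{count} genes shared by exactly the diseases in \code{pattern}.
#'   Remaining genes are unique per disease. \code{NULL} for fully disjoint
#'   sets.
#' @param n_universe total number of genes in the synthetic genome
#'   (catalog genes first, then filler).
#' @param n_tolerated number of tolerated-LOF reference genes (symbols
#'   \code{TOL001}...).
#' @param burden,expression,genesets,network named lists overriding the
#'   module defaults (see the package vignette for every key).
#' @return a \code{"synthetic_config"} list.
#' @export
synthetic_config <- function(seed,
                             diseases = c("AS", "CD", "UC", "CeD", "PS",
                                          "T1D", "MS", "PBC", "RA"),
                             set_sizes = NULL,
                             membership_design = NULL,
                             n_universe = 5000L,
                             n_tolerated = 98L,
                             burden = list(),
                             expression = list(),
                             genesets = list(),
                             network = list()) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(set_sizes))
    set_sizes <- stats::setNames(rep(30L, length(diseases)), diseases)
  burden_def <- list(lambda_tolerated = 0.02, lambda_constrained = 0.01,
                     maf = 0.01, lof_fraction = 0.2, syn_rate = 0.01,
                     common_missense_rate = 0.005, maf_shape = c(0.2, 5),
                     n_exons = c(3L, 8L), exon_bp = c(80L, 400L))
  expr_def <- list(factor = 3, boost_group = "hematopoietic",
                   meanlog = 1, sdlog = 1,
                   n_samples = 45L, transcripts_per_gene = c(1L, 5L),
                   fpkm_meanlog = 1, fpkm_sdlog = 1.5, fpkm_boost = 1)
  gs_def <- list(n_sets = 400L, size_range = c(15L, 400L),
                 planted_size = 50L, query_fraction = 0.5)
  net_def <- list(n_nodes = 2000L, p_background = 0.005,
                  p_planted = 0.005, planted_pairs = list())
  net <- utils::modifyList(net_def, network)
  # modifyList ignores unnamed list elements, so set this one directly
  if (!is.null(network$planted_pairs))
    net$planted_pairs <- network$planted_pairs
  structure(list(
    seed = as.integer(seed), diseases = diseases, set_sizes = set_sizes,
    membership_design = membership_design,
    n_universe = as.integer(n_universe),
    n_tolerated = as.integer(n_tolerated),
    burden = utils::modifyList(burden_def, burden),
    expression = utils::modifyList(expr_def, expression),
    genesets = utils::modifyList(gs_def, genesets),
    network = net
  ), class = "synthetic_config")
}

#' Default nine-disease scenario
#'
#' A desk-scale mirror of the motivating study design: nine immune-mediated
#' diseases totalling 407 distinct risk genes, with the focal AS set (30
#' genes) sharing exactly 11 genes with CD, 8 with UC, 5 with CeD, 5 with
#' PS, 4 with T1D, 4 with MS, 1 with PBC and none with RA, partitioned into
#' 8 genes unique to AS, 17 shared with at most two other diseases and 5
#' shared with more than two. The gene-set database is scaled to 400 sets
#' and the network to 2000 nodes to keep a full run fast; the AS-versus-
#' other-disease gene pairs carry planted interaction density.
#'
#' @param seed integer RNG seed.
#' @return a \code{"synthetic_config"}.
#' @export
as_scenario <- function(seed = 1L) {
  design <- data.frame(
    pattern = c("AS|CD|UC|CeD", "AS|CD|UC|PS", "AS|CD|T1D|MS",
                "AS|CD|UC", "AS|CD|CeD", "AS|CD|PS", "AS|T1D|MS",
                "AS|CD", "AS|UC", "AS|CeD", "AS|PS", "AS|T1D", "AS|MS",
                "AS|PBC"),
    count = c(2L, 2L, 1L,
              3L, 1L, 1L, 1L,
              1L, 1L, 2L, 2L, 2L, 2L,
              1L),
    stringsAsFactors = FALSE
  )
  sizes <- c(AS = 30L, CD = 140L, UC = 100L, CeD = 35L, PS = 30L,
             T1D = 30L, MS = 25L, PBC = 20L, RA = 35L)
  synthetic_config(
    seed = seed,
    set_sizes = sizes,
    membership_design = design,
    network = list(
      p_background = 0.005, p_planted = 0.05,
      planted_pairs = lapply(setdiff(names(sizes), "AS"),
                             function(d) c("AS", d))
    )
  )
}

#' Generate a disease gene catalog with planted overlaps
#'
#' Realizes the configuration's membership design exactly: each design row
#' creates its count of genes belonging to precisely the diseases of its
#' pattern; every set is then filled to its configured size with unique
#' genes. Symbols are synthetic (\code{G000001}...). Pairwise overlaps (and
#' the focal sharing classes) are exact by construction; no randomness is
#' involved.
#'
#' @param config a \code{"synthetic_config"}.
#' @return a \code{"disease_gene_catalog"}.
#' @export
gen_catalog <- function(config) {
  diseases <- config$diseases
  sizes <- config$set_sizes[diseases]
  if (anyNA(sizes)) stop("set_sizes must cover every disease", call. = FALSE)
  catalog <- stats::setNames(
    replicate(length(diseases), character(0), simplify = FALSE), diseases)
  counter <- 0L
  next_ids <- function(n) {
    ids <- sprintf("G%06d", counter + seq_len(n))
    counter <<- counter + n
    ids
  }
  design <- config$membership_design
  if (!is.null(design)) {
    for (i in seq_len(nrow(design))) {
      members <- strsplit(design$pattern[[i]], "|", fixed = TRUE)[[1L]]
      unknown <- setdiff(members, diseases)
      if (length(unknown))
        stop("membership design names unknown disease(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      if (length(members) < 2L)
        stop("membership pattern needs >= 2 diseases: ",
             design$pattern[[i]], call. = FALSE)
      ids <- next_ids(design$count[[i]])
      for (d in members) catalog[[d]] <- c(catalog[[d]], ids)
    }
  }
  shared <- lengths(catalog)
  if (any(shared > sizes))
    stop("infeasible design: planted shared genes exceed set size for ",
         paste(diseases[shared > sizes], collapse = ", "), call. = FALSE)
  for (d in diseases)
    catalog[[d]] <- c(catalog[[d]], next_ids(sizes[[d]] - shared[[d]]))
  structure(lapply(catalog, sort), class = "disease_gene_catalog")
}

#' Generate a synthetic exome and variant table
#'
#' Per gene: 3--8 exons of 80--400 bp laid out on a synthetic chromosome,
#' plus a duplicated partial isoform (same coordinates) so the readers and
#' the compound-exon merge are exercised. Deleterious variants are placed by
#' a per-bp Poisson process at the group's rate (tolerated
#' \code{lambda_tolerated}, constrained \code{lambda_constrained}); each is
#' a rare missense (allele frequency drawn below the rare cutoff from a
#' scaled Beta(0.2, 5)) or, with probability \code{lof_fraction}, a
#' loss-of-function variant of any frequency. Synonymous and common
#' missense decoys are added at their own rates so the deleterious filter
#' has something to reject.
#'
#' @param config a \code{"synthetic_config"}.
#' @param genes character vector of gene symbols to build exons for.
#' @param group_labels named character vector over \code{genes} with values
#'   \code{"tolerated"} or \code{"constrained"}.
#' @return list with \code{intervals} (BED-style exon data.frame, including
#'   the duplicate isoform rows) and \code{variants} (variant table
#'   data.frame).
#' @export
gen_exome_and_variants <- function(config, genes, group_labels) {
  genes <- as_gene_symbols(genes)
  stopifnot(all(genes %in% names(group_labels)),
            all(group_labels %in% c("tolerated", "constrained")))
  p <- config$burden
  with_seed(config$seed + 1L, {
    ng <- length(genes)
    # exon architecture: counts, lengths, gaps drawn per gene, laid out
    # sequentially along one synthetic chromosome
    n_ex <- sample(p$n_exons[1]:p$n_exons[2], ng, replace = TRUE)
    tot <- sum(n_ex)
    lens <- sample(p$exon_bp[1]:p$exon_bp[2], tot, replace = TRUE)
    gaps <- sample(100:500, tot, replace = TRUE)
    gene_of <- rep.int(seq_len(ng), n_ex)
    # per-gene cumulative layout, then shift each gene past the previous one
    within <- sequence(n_ex)
    cum_lens <- stats::ave(lens, gene_of, FUN = cumsum)
    cum_gaps <- stats::ave(gaps, gene_of, FUN = cumsum)
    rel_start <- cum_gaps + cum_lens - lens
    gene_span <- tapply(rel_start + lens, gene_of, max) + 1000L
    gene_offset <- c(0L, cumsum(gene_span))[seq_len(ng)]
    starts <- gene_offset[gene_of] + rel_start
    ends <- starts + lens
    # duplicated partial isoform: roughly half of each gene's exons again
    dup <- which(within <= pmax(1L, n_ex[gene_of] %/% 2L))
    intervals <- data.frame(
      chrom = "CHR1",
      start = c(starts, starts[dup]), end = c(ends, ends[dup]),
      gene = c(genes[gene_of], genes[gene_of[dup]]),
      stringsAsFactors = FALSE)
    # variant placement over each gene's compound (= union) exon space
    L <- as.integer(tapply(lens, gene_of, sum))
    lam <- ifelse(group_labels[genes] == "tolerated",
                  p$lambda_tolerated, p$lambda_constrained)
    n_del <- stats::rpois(ng, lam * L)
    n_syn <- stats::rpois(ng, p$syn_rate * L)
    n_com <- stats::rpois(ng, p$common_missense_rate * L)
    kinds <- c("del", "syn", "com")
    v_gene <- rep.int(rep.int(seq_len(ng), 3L), c(n_del, n_syn, n_com))
    v_kind <- rep.int(rep(kinds, each = ng), c(n_del, n_syn, n_com))
    nv <- length(v_gene)
    if (nv == 0L) {
      variants <- data.frame(gene = character(0), chrom = character(0),
                             pos = integer(0), consequence = character(0),
                             allele_frequency = numeric(0))
      return_value <- list(intervals = intervals, variants = variants)
      return_value
    } else {
    # base offset within the gene's compound space -> genomic position
    k <- floor(stats::runif(nv) * L[v_gene]) + 1L
    exon_starts_by_gene <- split(starts, gene_of)
    cum_by_gene <- split(cum_lens, gene_of)
    pos <- integer(nv)
    for (gi in unique(v_gene)) {
      sel <- v_gene == gi
      cum <- cum_by_gene[[gi]]
      ex <- findInterval(k[sel] - 1L, c(0L, cum))
      pos[sel] <- exon_starts_by_gene[[gi]][ex] +
        (k[sel] - c(0L, cum)[ex])
    }
    is_del <- v_kind == "del"
    is_lof <- is_del & stats::runif(nv) < p$lof_fraction
    cons <- character(nv)
    cons[is_del & !is_lof] <- "missense"
    cons[is_lof] <- sample(c("stop_gained", "frameshift", "splice_donor",
                             "splice_acceptor"), sum(is_lof),
                           replace = TRUE)
    cons[v_kind == "syn"] <- "synonymous"
    cons[v_kind == "com"] <- "missense"
    af <- stats::rbeta(nv, p$maf_shape[1], p$maf_shape[2])
    af[is_del & !is_lof] <- p$maf * af[is_del & !is_lof]
    af[v_kind == "com"] <- stats::runif(sum(v_kind == "com"), p$maf, 0.5)
    variants <- data.frame(gene = genes[v_gene], chrom = "CHR1", pos = pos,
                           consequence = cons, allele_frequency = af,
                           stringsAsFactors = FALSE)
    variants <- variants[order(v_gene, pos), , drop = FALSE]
    rownames(variants) <- NULL
    list(intervals = intervals, variants = variants)
    }
  })
}

.fetal_tissues <- paste0("fetal_", c("heart", "liver", "gut", "ovary",
                                     "testis", "brain"))
.adult_tissues <- paste0("adult_", c("frontal_cortex", "spinal_cord",
                                     "retina", "heart", "liver", "ovary",
                                     "testis", "lung", "adrenal",
                                     "gallbladder", "pancreas", "kidney",
                                     "esophagus", "colon", "rectum",
                                     "urinary_bladder", "prostate",
                                     "placenta"))
.hematopoietic_cells <- paste0("hematopoietic_",
                               c("B", "CD4", "CD8", "NK", "monocytes",
                                 "platelets"))

#' Tissue column labels of the synthetic proteome
#'
#' @return named character vector mapping each of the 30 tissue columns
#'   (6 fetal, 18 adult, 6 hematopoietic cell types) to its group label.
#' @export
tissue_groups <- function() {
  stats::setNames(
    c(rep("fetal", length(.fetal_tissues)),
      rep("adult", length(.adult_tissues)),
      rep("hematopoietic", length(.hematopoietic_cells))),
    c(.fetal_tissues, .adult_tissues, .hematopoietic_cells))
}

#' Generate synthetic transcript FPKM and tissue spectral-count matrices
#'
#' Log-normal baselines. The spectral-count matrix covers 30 tissue columns
#' (6 fetal, 18 adult, 6 hematopoietic); entries of \code{boost_genes} in
#' the boosted tissue group are multiplied by \code{factor}. The FPKM
#' matrix assigns each gene 1--5 transcripts over the configured number of
#' population samples; \code{fpkm_boost} (default 1) multiplies the
#' transcripts of \code{boost_genes}.
#'
#' @param config a \code{"synthetic_config"}.
#' @param genes character vector: the synthetic genome's genes.
#' @param boost_genes genes receiving the planted expression boost
#'   (typically the focal risk genes).
#' @return list with \code{fpkm} and \code{spectra}, both
#'   \code{"expression_matrix"} objects.
#' @export
gen_expression <- function(config, genes, boost_genes = character()) {
  genes <- as_gene_symbols(genes)
  boost_genes <- intersect(as_gene_symbols(boost_genes), genes)
  p <- config$expression
  groups <- tissue_groups()
  with_seed(config$seed + 2L, {
    tis <- names(groups)
    spectra <- matrix(stats::rlnorm(length(genes) * length(tis),
                                    p$meanlog, p$sdlog),
                      nrow = length(genes),
                      dimnames = list(genes, tis))
    boost_cols <- tis[groups == p$boost_group]
    spectra[boost_genes, boost_cols] <-
      spectra[boost_genes, boost_cols] * p$factor
    n_tr <- sample(p$transcripts_per_gene[1]:p$transcripts_per_gene[2],
                   length(genes), replace = TRUE)
    tr_gene <- rep(genes, n_tr)
    tr_ids <- sprintf("T%06d", seq_along(tr_gene))
    samples <- sprintf("S%02d", seq_len(p$n_samples))
    fpkm <- matrix(stats::rlnorm(length(tr_ids) * p$n_samples,
                                 p$fpkm_meanlog, p$fpkm_sdlog),
                   nrow = length(tr_ids),
                   dimnames = list(tr_ids, samples))
    if (p$fpkm_boost != 1)
      fpkm[tr_gene %in% boost_genes, ] <-
        fpkm[tr_gene %in% boost_genes, ] * p$fpkm_boost
    list(fpkm = expression_matrix(fpkm,
                                  row_to_gene = stats::setNames(tr_gene,
                                                                tr_ids)),
         spectra = expression_matrix(spectra, col_groups = groups))
  })
}

#' Generate a synthetic gene-set database with one planted pathway
#'
#' Decoy sets are drawn uniformly from the background universe with sizes
#' uniform over the configured range. One planted set of size
#' \code{planted_size} (named \code{PW_PLANTED}) contains
#' \code{query_fraction} of the supplied query genes, padded with random
#' non-query background genes, so the enrichment scan has a known positive.
#'
#' @param config a \code{"synthetic_config"}.
#' @param genes background gene universe.
#' @param query_genes the designated disease's genes the planted set draws
#'   from (empty vector: the planted set behaves as one more decoy).
#' @return a \code{"gene_set_db"}; the planted set name is stored in
#'   \code{attr(, "planted")}.
#' @export
gen_genesets <- function(config, genes, query_genes = character()) {
  genes <- as_gene_symbols(genes)
  query_genes <- intersect(as_gene_symbols(query_genes), genes)
  p <- config$genesets
  stopifnot(p$planted_size >= 15L, p$planted_size <= 1000L)
  with_seed(config$seed + 3L, {
    sizes <- sample(p$size_range[1]:p$size_range[2], p$n_sets,
                    replace = TRUE)
    sources <- sample(c("GO", "NCI", "KEGG", "Reactome"), p$n_sets,
                      replace = TRUE)
    db <- lapply(seq_len(p$n_sets), function(i)
      list(source = sources[[i]], genes = sort(sample(genes, sizes[[i]]))))
    names(db) <- sprintf("PW%04d", seq_len(p$n_sets))
    n_query <- min(round(p$query_fraction * length(query_genes)),
                   p$planted_size)
    planted <- c(if (n_query > 0) sample(query_genes, n_query),
                 sample(setdiff(genes, query_genes),
                        p$planted_size - n_query))
    db$PW_PLANTED <- list(source = "GO", genes = sort(planted))
    structure(db, class = "gene_set_db", planted = "PW_PLANTED")
  })
}

# Decode 1-based unordered-pair indices over n nodes into (i, j), i < j.
pair_index_decode <- function(k, n) {
  cum <- cumsum((n - 1L):1L)
  i <- findInterval(k - 1L, c(0L, cum), rightmost.closed = FALSE)
  j <- i + (k - c(0L, cum)[i])
  cbind(i, j)
}

#' Generate a synthetic interaction network with planted cross-set density
#'
#' Erdős--Rényi background over \code{n_nodes} (the catalog genes first,
#' filler genes after) at \code{p_background}; for every planted disease
#' pair, the bipartite gene pairs between the two (distinct-gene) sets are
#' wired at \code{p_planted} instead. With \code{p_planted =
#' p_background} the graph is plain Erdős--Rényi.
#'
#' @param config a \code{"synthetic_config"}; uses its \code{network}
#'   entry (\code{n_nodes}, \code{p_background}, \code{p_planted},
#'   \code{planted_pairs}: list of 2-vectors of disease labels).
#' @param catalog a \code{"disease_gene_catalog"} supplying the disease
#'   sets; all its genes must fit inside \code{n_nodes}.
#' @return an \code{"edge_list"}.
#' @export
gen_network <- function(config, catalog) {
  catalog <- check_catalog(catalog)
  p <- config$network
  cat_genes <- sort(unique(unlist(catalog)))
  n <- p$n_nodes
  if (length(cat_genes) > n)
    stop("n_nodes smaller than the catalog gene count", call. = FALSE)
  nodes <- c(cat_genes,
             sprintf("N%05d", seq_len(n - length(cat_genes))))
  with_seed(config$seed + 4L, {
    npairs <- n * (n - 1) / 2
    n_edge <- stats::rbinom(1L, npairs, p$p_background)
    idx <- sample(npairs, n_edge)
    ij <- pair_index_decode(sort(idx), n)
    a <- nodes[ij[, 1L]]; b <- nodes[ij[, 2L]]
    for (pr in p$planted_pairs) {
      A <- catalog[[pr[[1L]]]]; B <- setdiff(catalog[[pr[[2L]]]],
                                             catalog[[pr[[1L]]]])
      grid <- expand.grid(A = A, B = B, stringsAsFactors = FALSE)
      # replace the background in this bipartite block with p_planted wiring
      in_block <- (a %in% A & b %in% B) | (a %in% B & b %in% A)
      a <- a[!in_block]; b <- b[!in_block]
      on <- stats::runif(nrow(grid)) < p$p_planted
      a <- c(a, grid$A[on]); b <- c(b, grid$B[on])
    }
    as_edge_list(a, b)
  })
}

#' Write every synthetic input of a scenario to disk
#'
#' Generates the six pipeline inputs from a configuration and writes them
#' through the package's writers, so reading them back exercises every
#' reader: \code{gene_lists.tsv}, \code{exons.bed}, \code{variants.tsv},
#' \code{fpkm.tsv}, \code{spectra.tsv}, \code{tissue_groups.txt},
#' \code{genesets.gmt}, \code{edges.tsv}, \code{tolerated.txt} and
#' \code{background.txt}. Identical configurations produce byte-identical
#' files.
#'
#' @param config a \code{"synthetic_config"}.
#' @param dir output directory (created if needed).
#' @param focal focal disease whose genes receive the expression boost and
#'   seed the planted pathway (default \code{"AS"}).
#' @return named character vector of the written file paths, invisibly.
#' @export
write_scenario <- function(config, dir, focal = "AS") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  catalog <- gen_catalog(config)
  cat_genes <- sort(unique(unlist(catalog)))
  universe <- c(cat_genes,
                sprintf("G%06d",
                        length(cat_genes) + seq_len(config$n_universe -
                                                      length(cat_genes))))
  tolerated <- sprintf("TOL%03d", seq_len(config$n_tolerated))
  groups <- stats::setNames(
    c(rep("constrained", length(cat_genes)), rep("tolerated",
                                                 length(tolerated))),
    c(cat_genes, tolerated))
  exome <- gen_exome_and_variants(config, names(groups), groups)
  expr <- gen_expression(config, universe, boost_genes = catalog[[focal]])
  db <- gen_genesets(config, universe, query_genes = catalog[[focal]])
  edges <- gen_network(config, catalog)
  paths <- c(
    gene_lists = write_gene_lists(catalog, file.path(dir, "gene_lists.tsv")),
    exons = write_exon_bed(exome$intervals, file.path(dir, "exons.bed")),
    variants = write_variant_table(exome$variants,
                                   file.path(dir, "variants.tsv")),
    fpkm = write_expression_matrix(expr$fpkm, file.path(dir, "fpkm.tsv")),
    spectra = write_expression_matrix(expr$spectra,
                                      file.path(dir, "spectra.tsv")),
    tissue_groups = write_key_value(tissue_groups(),
                                    file.path(dir, "tissue_groups.txt")),
    genesets = write_gmt(db, file.path(dir, "genesets.gmt")),
    edges = write_edge_list(edges, file.path(dir, "edges.tsv")),
    tolerated = {
      writeLines(tolerated, file.path(dir, "tolerated.txt"))
      file.path(dir, "tolerated.txt")
    },
    background = {
      writeLines(universe, file.path(dir, "background.txt"))
      file.path(dir, "background.txt")
    }
  )
  invisible(paths)
}
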