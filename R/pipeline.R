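#' Read / write a plain gene list (one symbol per line)
#'
#' @param path path to the file.
#' @return character vector of uppercased symbols.
#' @export
read_gene_vector <- function(path) {
  lines <- read_tsv_lines(path)
  as_gene_symbols(lines)
}

#' @rdname read_gene_vector
#' @param genes character vector of gene symbols.
#' @return (\code{write_gene_vector}) \code{path}, invisibly.
#' @export
write_gene_vector <- function(genes, path) {
  writeLines(as_gene_symbols(genes), path)
  invisible(path)
}

#' Run configuration for the full pipeline
#'
#' Collects the input paths, focal disease, every threshold the stages use
#' and the RNG seed. The defaults are the analysis constants of the
#' motivating design: 75th-percentile expression cutoff, pathway sizes
#' 15--1000, dual significance rule p < 1e-3 and FDR < 0.01, rare-missense
#' cutoff 0.01, and 50,000 permutations.
#'
#' @param paths named list/vector of input paths with entries
#'   \code{gene_lists}, \code{exons}, \code{variants}, \code{fpkm},
#'   \code{spectra}, \code{tissue_groups}, \code{genesets}, \code{edges},
#'   \code{tolerated}, \code{background} (as written by [write_scenario()]).
#' @param focal focal disease label.
#' @param out_dir output directory for the stage tables and manifest.
#' @param seed RNG seed for the network permutations.
#' @param maf rare-missense allele-frequency cutoff.
#' @param q expression percentile cutoff.
#' @param min_size,max_size pathway size window.
#' @param p_cut,q_cut dual enrichment significance thresholds.
#' @param n_perm number of network permutations.
#' @return a \code{"run_config"} list.
#' @export
run_config <- function(paths, focal = "AS", out_dir, seed,
                       maf = 0.01, q = 75,
                       min_size = 15L, max_size = 1000L,
                       p_cut = 1e-3, q_cut = 0.01,
                       n_perm = 50000L) {
  required <- c("gene_lists", "exons", "variants", "fpkm", "spectra",
                "tissue_groups", "genesets", "edges", "tolerated",
                "background")
  missing <- setdiff(required, names(paths))
  if (length(missing))
    stop("run_config paths missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(list(paths = as.list(paths)[required], focal = focal,
                 out_dir = out_dir, seed = as.integer(seed), maf = maf,
                 q = q, min_size = min_size, max_size = max_size,
                 p_cut = p_cut, q_cut = q_cut, n_perm = as.integer(n_perm)),
            class = "run_config")
}

write_stage_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the complete convergence pipeline
#'
#' Executes the five analysis stages in order -- overlap accounting, exon
#' burden with K-S comparison against the tolerated reference, expression
#' profiling (transcript abundance, tissue ratios, hematopoietic fold),
#' pathway enrichment with the AS-overlap count, and the seed-connectivity
#' permutation test with candidate ranking -- writing one TSV per stage plus
#' a JSON manifest recording the seed, parameters, input checksums and
#' output files. Any stage failure aborts with an error naming the stage.
#'
#' @param config a \code{"run_config"}.
#' @return the manifest, invisibly (list; also written as
#'   \code{manifest.json}).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (nm in names(config$paths))
    if (!file.exists(config$paths[[nm]]))
      stop(sprintf("input '%s' not found: %s", nm, config$paths[[nm]]),
           call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  outputs <- list()

  catalog <- stage("input", read_gene_lists(config$paths$gene_lists))
  focal <- config$focal
  others <- setdiff(names(catalog), focal)

  outputs$overlap <- stage("overlap", {
    s <- sharing_classes(catalog, focal)
    df <- data.frame(disease = names(s$per_disease_overlap),
                     overlap = as.integer(s$per_disease_overlap))
    summary_df <- data.frame(
      disease = c(paste0("unique_to_", focal), "shared_at_most_two",
                  "shared_more_than_two"),
      overlap = c(s$unique_to_focal, s$shared_at_most_two,
                  s$shared_more_than_two))
    write_stage_tsv(rbind(df, summary_df),
                    file.path(config$out_dir, "overlap.tsv"))
  })

  outputs$burden <- stage("burden", {
    exons <- read_exon_bed(config$paths$exons)
    variants <- read_variant_table(config$paths$variants)
    tolerated <- read_gene_vector(config$paths$tolerated)
    models <- build_compound_exons(exons)
    deleterious <- classify_deleterious(variants, config$maf)
    ref <- set_burden(models, deleterious, tolerated)
    rows <- lapply(names(catalog), function(d) {
      ks <- ks_compare(set_burden(models, deleterious, catalog[[d]]), ref)
      data.frame(disease = d, D = ks$D, p_value = ks$p_value,
                 n_exons = ks$n_a, n_ref_exons = ks$n_b)
    })
    write_stage_tsv(do.call(rbind, rows),
                    file.path(config$out_dir, "burden.tsv"))
  })

  outputs$expression <- stage("expression", {
    fpkm <- read_expression_matrix(config$paths$fpkm)
    spectra <- read_expression_matrix(config$paths$spectra,
                                      col_groups = config$paths$tissue_groups)
    rows <- lapply(names(catalog), function(d) {
      ta <- transcript_abundance(fpkm, catalog[[d]], q = config$q)
      tp <- tissue_profile(spectra, catalog[[d]], q = config$q)
      fold <- hematopoietic_fold(tp)
      data.frame(disease = d, transcript_set_mean = ta$set_mean,
                 transcript_genome_mean = ta$genome_mean,
                 hematopoietic_fold = fold,
                 top_tissue = names(which.max(tp$per_tissue_mean)),
                 top_tissue_mean = max(tp$per_tissue_mean))
    })
    write_stage_tsv(do.call(rbind, rows),
                    file.path(config$out_dir, "expression.tsv"))
  })

  outputs$enrichment <- stage("enrichment", {
    db <- read_gmt(config$paths$genesets)
    background <- read_gene_vector(config$paths$background)
    db <- filter_gene_sets(db, config$min_size, config$max_size,
                           background = background)
    scans <- lapply(catalog, function(g)
      enrich_all(g, db, background = background,
                 p_cut = config$p_cut, q_cut = config$q_cut))
    rows <- do.call(rbind, lapply(names(scans), function(d) {
      sc <- scans[[d]]
      data.frame(disease = d, n_significant = sum(sc$significant),
                 top_pathway = sc$pathway[[1L]],
                 top_p = sc$p_value[[1L]],
                 overlap_with_focal = pathway_overlap(sc, scans[[focal]]))
    }))
    write_stage_tsv(rows, file.path(config$out_dir, "enrichment.tsv"))
  })

  outputs$network <- stage("network", {
    edges <- read_edge_list(config$paths$edges)
    background <- read_gene_vector(config$paths$background)
    net <- build_network(edges)
    rows <- lapply(seq_along(others), function(i) {
      d <- others[[i]]
      pair <- deconfounded_pair(catalog, focal, d)
      pt <- permutation_test(net, pair$A, pair$B, background,
                             n_perm = config$n_perm,
                             seed = config$seed + i,
                             n_tests = length(others))
      data.frame(disease = d, observed = pt$observed,
                 null_mean = mean(pt$null_values), r_ge = pt$r_ge,
                 empirical_p = pt$empirical_p,
                 p_upper_bound = pt$p_upper_bound,
                 corrected_p = pt$corrected_p)
    })
    candidates <- setdiff(unique(unlist(catalog[others])), catalog[[focal]])
    ranking <- rank_by_seed_connectivity(net, catalog[[focal]], candidates)
    write_stage_tsv(ranking, file.path(config$out_dir, "ranking.tsv"))
    write_stage_tsv(do.call(rbind, rows),
                    file.path(config$out_dir, "network.tsv"))
  })
  outputs$ranking <- file.path(config$out_dir, "ranking.tsv")

  manifest <- list(
    package = "imdconverge",
    version = as.character(utils::packageVersion("imdconverge")),
    seed = config$seed,
    focal = focal,
    parameters = config[c("maf", "q", "min_size", "max_size", "p_cut",
                          "q_cut", "n_perm")],
    input_checksums = as.list(tools::md5sum(unlist(config$paths))),
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
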