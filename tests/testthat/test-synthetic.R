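test_that("catalog generator realizes membership designs exactly", {
  # arbitrary feasible designs: recount every pairwise overlap by brute force
  set.seed(101)
  for (i in 1:25) {
    diseases <- paste0("D", 1:5)
    pats <- unique(replicate(6, paste(sort(sample(diseases, sample(2:4, 1))),
                                      collapse = "|")))
    design <- data.frame(pattern = pats,
                         count = sample(1:4, length(pats), replace = TRUE))
    shared <- sapply(diseases, function(d)
      sum(design$count[vapply(strsplit(design$pattern, "|", fixed = TRUE),
                              function(m) d %in% m, FALSE)]))
    sizes <- setNames(shared + sample(0:10, 5, replace = TRUE), diseases)
    cfg <- synthetic_config(seed = i, diseases = diseases,
                            set_sizes = sizes,
                            membership_design = design)
    cat <- gen_catalog(cfg)
    expect_equal(unname(lengths(cat)), unname(sizes[names(cat)]))
    for (a in diseases) for (b in setdiff(diseases, a)) {
      planted <- sum(design$count[vapply(
        strsplit(design$pattern, "|", fixed = TRUE),
        function(m) a %in% m && b %in% m, FALSE)])
      expect_equal(length(intersect(cat[[a]], cat[[b]])), planted)
    }
  }
})

test_that("catalog generator handles disjoint and infeasible designs", {
  cfg <- synthetic_config(seed = 1, diseases = c("A", "B"),
                          set_sizes = c(A = 5L, B = 7L))
  cat <- gen_catalog(cfg)
  expect_length(intersect(cat$A, cat$B), 0L)
  expect_length(unique(unlist(cat)), 12L)

  bad <- synthetic_config(seed = 1, diseases = c("A", "B"),
                          set_sizes = c(A = 3L, B = 9L),
                          membership_design = data.frame(pattern = "A|B",
                                                         count = 4L))
  expect_error(gen_catalog(bad), "infeasible")
})

test_that("exome generator plants deleterious variants at the Poisson rate", {
  genes <- sprintf("X%03d", 1:500)
  lab <- setNames(rep(c("tolerated", "constrained"), each = 250), genes)

  # zero constrained rate -> constrained genes receive no deleterious variants
  cfg0 <- synthetic_config(seed = 2, burden = list(lambda_constrained = 0))
  ex0 <- gen_exome_and_variants(cfg0, genes, lab)
  del0 <- classify_deleterious(ex0$variants, cfg0$burden$maf)
  expect_length(intersect(del0$gene, genes[lab == "constrained"]), 0L)

  # mean deleterious count ~ lambda * compound length, within 3 SE
  cfg <- synthetic_config(seed = 3)
  ex <- gen_exome_and_variants(cfg, genes, lab)
  models <- build_compound_exons(ex$intervals)
  del <- classify_deleterious(ex$variants, cfg$burden$maf)
  for (grp in c("tolerated", "constrained")) {
    g <- genes[lab == grp]
    lam <- if (grp == "tolerated") cfg$burden$lambda_tolerated
           else cfg$burden$lambda_constrained
    expected <- lam * sum(vapply(models[g], compound_length, 0L))
    observed <- sum(del$gene %in% g)
    expect_lt(abs(observed - expected), 3 * sqrt(expected))
  }

  # doubling lambda doubles expected counts
  cfg2 <- synthetic_config(seed = 3, burden = list(
    lambda_tolerated = 0.04, lambda_constrained = 0.02))
  ex2 <- gen_exome_and_variants(cfg2, genes, lab)
  del2 <- classify_deleterious(ex2$variants, cfg$burden$maf)
  ratio <- nrow(del2) / nrow(del)
  expect_gt(ratio, 1.8); expect_lt(ratio, 2.2)
})

test_that("expression generator recovers the planted boost", {
  genes <- sprintf("G%04d", 1:400)
  risk <- genes[1:30]
  hits <- 0L
  for (s in 1:40) {
    cfg <- synthetic_config(seed = 6000 + s, expression = list(
      factor = 3, transcripts_per_gene = c(1L, 1L), n_samples = 2L))
    ex <- gen_expression(cfg, genes, boost_genes = risk)
    if (hematopoietic_fold(tissue_profile(ex$spectra, risk)) >= 2)
      hits <- hits + 1L
  }
  expect_gte(hits, 38L)  # >= 95% of seeds

  # no boost: fold hovers near 1
  cfg1 <- synthetic_config(seed = 77, expression = list(
    factor = 1, transcripts_per_gene = c(1L, 1L), n_samples = 2L))
  ex1 <- gen_expression(cfg1, genes, boost_genes = risk)
  f1 <- hematopoietic_fold(tissue_profile(ex1$spectra, risk))
  expect_gt(f1, 0.5); expect_lt(f1, 1.7)
})

test_that("gene-set generator plants a recoverable pathway", {
  universe <- sprintf("G%04d", 1:3000)
  query <- universe[1:30]
  cfg <- synthetic_config(seed = 8, genesets = list(n_sets = 150L))
  db <- gen_genesets(cfg, universe, query_genes = query)
  expect_equal(attr(db, "planted"), "PW_PLANTED")
  sizes <- vapply(db, function(s) length(s$genes), 0L)
  expect_true(all(sizes >= 15 & sizes <= 1000))
  res <- enrich_all(query, db, background = length(universe))
  expect_equal(res$pathway[1], "PW_PLANTED")

  # query_fraction 0: the planted set is one more decoy
  cfg0 <- synthetic_config(seed = 8, genesets = list(n_sets = 150L,
                                                     query_fraction = 0))
  db0 <- gen_genesets(cfg0, universe, query_genes = query)
  expect_length(intersect(db0$PW_PLANTED$genes, query), 0L)
})

test_that("network generator hits exact and degenerate density limits", {
  cfg <- synthetic_config(
    seed = 9, diseases = c("A", "B"),
    set_sizes = c(A = 10L, B = 15L),
    network = list(n_nodes = 100L, p_background = 0, p_planted = 1,
                   planted_pairs = list(c("A", "B"))))
  cat <- gen_catalog(cfg)
  el <- gen_network(cfg, cat)
  net <- build_network(el)
  expect_equal(connectivity(net, cat$A, cat$B), 10L * 15L)
  expect_equal(nrow(el$pairs), 10L * 15L)

  cfg0 <- synthetic_config(seed = 9, diseases = c("A", "B"),
                           set_sizes = c(A = 10L, B = 15L),
                           network = list(n_nodes = 50L, p_background = 0))
  expect_equal(nrow(gen_network(cfg0, gen_catalog(cfg0))$pairs), 0L)
})

test_that("identical configurations write byte-identical files", {
  cfg <- synthetic_config(
    seed = 12, diseases = c("AS", "CD"), set_sizes = c(AS = 8L, CD = 10L),
    membership_design = data.frame(pattern = "AS|CD", count = 2L),
    n_universe = 300L, n_tolerated = 10L,
    expression = list(transcripts_per_gene = c(1L, 2L), n_samples = 3L),
    genesets = list(n_sets = 30L, size_range = c(15L, 40L),
                    planted_size = 15L),
    network = list(n_nodes = 60L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_scenario(cfg, d1)
  p2 <- write_scenario(cfg, d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     info = nm)
  }
  # generated files exercise every reader
  expect_s3_class(read_gene_lists(p1[["gene_lists"]]),
                  "disease_gene_catalog")
  expect_s3_class(read_gmt(p1[["genesets"]]), "gene_set_db")
  expect_s3_class(read_edge_list(p1[["edges"]]), "edge_list")
  expect_true(nrow(read_exon_bed(p1[["exons"]])) > 0)
  expect_true(nrow(read_variant_table(p1[["variants"]])) > 0)
  expect_s3_class(read_expression_matrix(p1[["spectra"]],
                                         p1[["tissue_groups"]]),
                  "expression_matrix")
})
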