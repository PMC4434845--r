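test_that("percentile threshold uses linear interpolation", {
  expect_equal(percentile_threshold(1:8, 75), 6.25)
  expect_equal(percentile_threshold(rep(3.2, 10), 75), 3.2)
  expect_equal(percentile_threshold(42, 50), 42)
  expect_error(percentile_threshold(numeric(0)), "non-empty")
})

test_that("transcript abundance counts top-quartile transcripts per gene", {
  vals <- matrix(5, nrow = 4, ncol = 3,
                 dimnames = list(paste0("T", 1:4), paste0("s", 1:3)))
  map <- setNames(c("A", "A", "B", "C"), paste0("T", 1:4))
  m <- expression_matrix(vals, row_to_gene = map)
  r <- transcript_abundance(m, c("A", "B"))
  expect_equal(r$set_mean, 0)       # constant matrix: nothing above cutoff
  expect_equal(r$genome_mean, 0)

  vals["T3", ] <- 100               # B owns the single top transcript
  m <- expression_matrix(vals, row_to_gene = map)
  r <- transcript_abundance(m, "B")
  expect_equal(r$set_mean, 1)
  expect_equal(r$genome_mean, 1 / 3)
  expect_error(transcript_abundance(m, "ZZZ"), "absent")
})

test_that("transcript counts match a brute-force threshold-and-tally", {
  set.seed(41)
  for (i in 1:30) {
    n_tr <- 60
    genes <- sample(sprintf("G%02d", 1:20), n_tr, replace = TRUE)
    vals <- matrix(rlnorm(n_tr * 5), nrow = n_tr,
                   dimnames = list(sprintf("T%03d", 1:n_tr),
                                   sprintf("s%d", 1:5)))
    m <- expression_matrix(vals,
                           row_to_gene = setNames(genes, rownames(vals)))
    r <- transcript_abundance(m, unique(genes)[1:5])
    mu <- rowMeans(vals)
    cut <- quantile(mu, 0.75, type = 7, names = FALSE)
    per_gene <- sapply(unique(genes), function(g)
      sum(mu[genes == g] > cut))
    expect_equal(r$set_mean, mean(per_gene[unique(genes)[1:5]]))
    expect_equal(r$genome_mean, mean(per_gene))
  }
})

test_that("tissue profile ratios match a brute-force per-tissue tally", {
  set.seed(43)
  vals <- matrix(rlnorm(200 * 6), nrow = 200,
                 dimnames = list(sprintf("G%03d", 1:200), paste0("t", 1:6)))
  m <- expression_matrix(vals)
  set <- sprintf("G%03d", 1:40)
  tp <- tissue_profile(m, set)
  cut <- quantile(as.vector(vals), 0.75, type = 7, names = FALSE)
  for (t in colnames(vals)) {
    expect_equal(tp$per_tissue_ratio[[t]], mean(vals[set, t] > cut))
    expect_equal(tp$per_tissue_mean[[t]], mean(vals[set, t]))
  }
  expect_true(all(tp$per_tissue_ratio >= 0 & tp$per_tissue_ratio <= 1))
  expect_error(tissue_profile(m, "NOPE"), "no overlap")

  # boundary behaviours
  hot <- vals; hot[set, "t1"] <- max(vals) + 1
  tp2 <- tissue_profile(expression_matrix(hot), set)
  expect_equal(tp2$per_tissue_ratio[["t1"]], 1)
})

test_that("ratios and counts are invariant to overall rescaling", {
  set.seed(47)
  vals <- matrix(rlnorm(100 * 4), nrow = 100,
                 dimnames = list(sprintf("G%03d", 1:100), paste0("t", 1:4)))
  set <- sprintf("G%03d", 1:20)
  tp1 <- tissue_profile(expression_matrix(vals), set)
  tp2 <- tissue_profile(expression_matrix(vals * 37.5), set)
  expect_equal(tp1$per_tissue_ratio, tp2$per_tissue_ratio)

  map <- setNames(sample(sprintf("g%02d", 1:25), 100, replace = TRUE),
                  rownames(vals))
  m1 <- expression_matrix(vals, row_to_gene = map)
  m2 <- expression_matrix(vals * 0.01, row_to_gene = map)
  a1 <- transcript_abundance(m1, unique(map)[1:5])
  a2 <- transcript_abundance(m2, unique(map)[1:5])
  expect_equal(a1$set_mean, a2$set_mean)
})

test_that("hematopoietic fold arithmetic and degenerate cases", {
  s <- structure(list(
    per_tissue_ratio = c(B = 0.5, CD4 = 0.4, liver = 0.2, retina = 0.1),
    per_tissue_mean = c(B = 1, CD4 = 1, liver = 1, retina = 1),
    col_groups = NULL), class = "tissue_expression_summary")
  expect_equal(hematopoietic_fold(s, c("B", "CD4")), 3.0)

  s$per_tissue_ratio[] <- 0.3
  expect_equal(hematopoietic_fold(s, c("B", "CD4")), 1.0)

  s$per_tissue_ratio <- c(B = 0.4, CD4 = 0.2, liver = 0, retina = 0)
  expect_equal(hematopoietic_fold(s, c("B", "CD4")), Inf)

  s$per_tissue_ratio[] <- 0
  expect_warning(f <- hematopoietic_fold(s, c("B", "CD4")), "undefined")
  expect_true(is.nan(f))
})

test_that("planted hematopoietic boost raises the fold monotonically", {
  genes <- sprintf("G%04d", 1:400)
  risk <- genes[1:30]
  folds <- sapply(c(1, 2, 4), function(b) {
    cfg <- synthetic_config(seed = 99, expression = list(
      factor = b, transcripts_per_gene = c(1L, 1L), n_samples = 2L))
    ex <- gen_expression(cfg, genes, boost_genes = risk)
    hematopoietic_fold(tissue_profile(ex$spectra, risk))
  })
  expect_true(folds[1] < folds[2] && folds[2] < folds[3])
})

test_that("zero-variance baseline gives fold exactly equal to the boost", {
  genes <- sprintf("G%04d", 1:200)
  cfg <- synthetic_config(seed = 7, expression = list(
    factor = 5, sdlog = 0, transcripts_per_gene = c(1L, 1L),
    n_samples = 2L))
  ex <- gen_expression(cfg, genes, boost_genes = genes[1:20])
  tp <- tissue_profile(ex$spectra, genes[1:20])
  expect_equal(hematopoietic_fold(tp, statistic = "mean"), 5)
})

test_that("delta-delta-CT follows the comparative threshold cycle formula", {
  r <- delta_delta_ct(25, 20, 3)
  expect_equal(r$delta, 5)
  expect_equal(r$ddct, 2)
  expect_equal(r$rq, 0.25)
  expect_equal(delta_delta_ct(20, 20, 0)$rq, 1)
  r1 <- delta_delta_ct(25, 20, 3)
  r2 <- delta_delta_ct(26, 20, 3)
  expect_equal(r2$rq, r1$rq / 2)
})
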