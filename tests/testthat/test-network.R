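toy_net <- function(...) {
  build_network(do.call(rbind, lapply(list(...), function(e)
    c(e[1], e[2]))))
}

test_that("network construction yields a simple undirected graph", {
  net <- toy_net(c("A", "B"), c("A", "C"))
  expect_equal(length(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)

  empty <- build_network(matrix(character(0), ncol = 2))
  expect_length(empty$nodes, 0L)

  set.seed(71)
  nodes <- sprintf("N%02d", 1:25)
  a <- sample(nodes, 600, replace = TRUE)
  b <- sample(nodes, 600, replace = TRUE)
  net <- build_network(cbind(a, b))
  expect_equal(nrow(net$edges), length(oracle_dedup_pairs(a, b)))
})

test_that("connectivity counts cross-set edges and enforces disjointness", {
  net <- toy_net(c("g1", "g3"), c("g2", "g4"))
  expect_equal(connectivity(net, c("g1", "g2"), "g3"), 1L)
  expect_error(connectivity(net, c("g1", "g2"), c("g2", "g3")), "disjoint")

  bip <- build_network(as.matrix(expand.grid(c("a1", "a2"),
                                             c("b1", "b2", "b3"))))
  expect_equal(connectivity(bip, c("a1", "a2"), c("b1", "b2", "b3")), 6L)

  set.seed(73)
  nodes <- sprintf("N%02d", 1:30)
  net <- build_network(rand_edges(73, nodes, 0.15))
  for (i in 1:120) {
    A <- sample(nodes, 5); B <- sample(setdiff(nodes, A), 7)
    expect_equal(connectivity(net, A, B),
                 oracle_connectivity(net$edges, A, B))
  }
})

test_that("permutation test is seed-reproducible and uses the add-one rule", {
  set.seed(79)
  nodes <- sprintf("N%03d", 1:100)
  net <- build_network(rand_edges(79, nodes, 0.05))
  A <- nodes[1:10]; B <- nodes[11:20]
  r1 <- permutation_test(net, A, B, nodes, n_perm = 300, seed = 5)
  r2 <- permutation_test(net, A, B, nodes, n_perm = 300, seed = 5)
  expect_identical(r1$null_values, r2$null_values)
  expect_equal(r1$empirical_p, (r1$r_ge + 1) / (r1$n_perm + 1))

  # a B with no connectivity at all: essentially every draw ties or beats it
  iso <- c("ZZ1", "ZZ2")
  net2 <- build_network(rbind(net$edges, c("ZZ1", "ZZ2")))
  r0 <- permutation_test(net2, A, iso, nodes, n_perm = 200, seed = 6)
  expect_equal(r0$observed, 0L)
  expect_gt(r0$empirical_p, 0.99)

  expect_error(permutation_test(net, A, B, nodes[1:5], n_perm = 10,
                                seed = 1),
               "background smaller")
  expect_error(permutation_test(net, A, B, nodes, n_perm = 10),
               "seed is required")
})

test_that("tiny-graph empirical tail matches exhaustive enumeration", {
  # 6 nodes; background for replacement = 4 genes; |B| = 2 -> C(4,2) = 6
  net <- toy_net(c("A1", "C1"), c("A1", "C2"), c("A2", "C3"),
                 c("C1", "C2"))
  A <- c("A1", "A2")
  bg <- c("C1", "C2", "C3", "C4")
  combos <- combn(bg, 2)
  exact_conn <- apply(combos, 2, function(B)
    oracle_connectivity(net$edges, A, B))
  for (obs_set in list(c("C1", "C2"), c("C3", "C4"))) {
    obs <- oracle_connectivity(net$edges, A, obs_set)
    r <- permutation_test(net, A, obs_set, bg, n_perm = 6000, seed = 11)
    exact_tail <- mean(exact_conn >= obs)
    expect_equal(r$r_ge / r$n_perm, exact_tail, tolerance = 0.05)
  }
})

test_that("Bonferroni reporting uses 1/n_perm when no null reaches observed", {
  # complete bipartite A x B against an isolated background: r_ge = 0 always
  A <- sprintf("a%d", 1:3); B <- sprintf("b%d", 1:4)
  net <- build_network(as.matrix(expand.grid(A, B)))
  bg <- sprintf("bg%03d", 1:100)
  r <- permutation_test(net, A, B, bg, n_perm = 1000, seed = 3,
                        n_tests = 8)
  expect_equal(r$r_ge, 0L)
  expect_equal(r$p_upper_bound, 1 / 1000)
  expect_equal(r$corrected_p, 8 / 1000)
})

test_that("adding a cross-set edge never decreases connectivity", {
  set.seed(83)
  nodes <- sprintf("N%02d", 1:30)
  edges <- rand_edges(83, nodes, 0.1)
  A <- nodes[1:5]; B <- nodes[6:12]
  base <- connectivity(build_network(edges), A, B)
  for (i in 1:20) {
    extra <- c(sample(A, 1), sample(B, 1))
    grown <- connectivity(build_network(rbind(edges, extra)), A, B)
    expect_gte(grown, base)
  }
})

test_that("candidate ranking counts adjacent seeds with deterministic ties", {
  net <- toy_net(c("S1", "X"), c("S2", "X"), c("S3", "X"),
                 c("S1", "Y"), c("Y", "Q"))
  r <- rank_by_seed_connectivity(net, c("S1", "S2", "S3", "S4"),
                                 c("X", "Y", "ZABSENT"))
  expect_equal(r$gene, c("X", "Y", "ZABSENT"))
  expect_equal(r$contributing_connectivity, c(3L, 1L, 0L))

  # tie-break: equal contributing connectivity -> higher degree first,
  # then lexicographic
  net2 <- toy_net(c("S", "P"), c("S", "Q"), c("Q", "W"))
  r2 <- rank_by_seed_connectivity(net2, "S", c("P", "Q"))
  expect_equal(r2$gene, c("Q", "P"))

  set.seed(87)
  nodes <- sprintf("N%02d", 1:40)
  net3 <- build_network(rand_edges(87, nodes, 0.1))
  seeds <- nodes[1:8]; cand <- nodes[9:40]
  r3 <- rank_by_seed_connectivity(net3, seeds, cand)
  for (g in cand) {
    manual <- sum(vapply(seeds, function(s)
      oracle_connectivity(net3$edges, s, g) > 0, FALSE))
    expect_equal(r3$contributing_connectivity[r3$gene == g], manual)
  }
})

test_that("cross-disease connectivity counts adjacent disease sets", {
  net <- toy_net(c("G", "d1a"), c("G", "d2a"), c("G", "d3a"),
                 c("G", "d4a"), c("G", "d5a"))
  catalog <- list(D1 = c("d1a", "x1"), D2 = "d2a", D3 = "d3a",
                  D4 = "d4a", D5 = "d5a", D6 = "zzz")
  expect_equal(cross_disease_connectivity(net, "G", catalog), 5L)
  expect_equal(cross_disease_connectivity(net, "LONELY", catalog), 0L)
  # membership of the gene itself does not block counting its own set
  catalog$D6 <- c("G", "d1a")
  expect_equal(cross_disease_connectivity(net, "G", catalog), 6L)

  set.seed(91)
  nodes <- sprintf("N%02d", 1:30)
  net2 <- build_network(rand_edges(91, nodes, 0.12))
  cat2 <- rand_catalog(91, n_diseases = 5, n_genes = 30)
  cat2 <- lapply(cat2, function(g) sub("R", "N", g))
  for (g in nodes[1:10]) {
    neigh <- unique(c(net2$edges[net2$edges[, 1] == g, 2],
                      net2$edges[net2$edges[, 2] == g, 1]))
    manual <- sum(vapply(cat2, function(set)
      length(intersect(neigh, setdiff(set, g))) > 0, FALSE))
    expect_equal(cross_disease_connectivity(net2, g, cat2), manual)
  }
})
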