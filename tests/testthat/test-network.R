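test_that("neighborhoods follow BFS distance and are monotone in order", {
  path_net <- ppi_network(tibble::tibble(from = c("A", "B", "C"),
                                         to = c("B", "C", "D")))
  expect_setequal(build_neighborhood(path_net, "A", 2), c("A", "B", "C"))
  expect_equal(build_neighborhood(path_net, "A", 0), "A")
  star <- ppi_network(tibble::tibble(from = "hub", to = paste0("n", 1:6)))
  expect_setequal(build_neighborhood(star, "hub", 2), star$nodes)
  expect_error(build_neighborhood(path_net, "ZZZ"), "absent")

  for (i in 1:50) {
    set.seed(200 + i)
    g <- igraph::sample_gnp(25, 0.12)
    igraph::V(g)$name <- paste0("v", 1:25)
    net <- ppi_network(igraph::as_data_frame(g))
    seed_node <- sample(net$nodes, 1)
    ord <- sample(0:3, 1)
    nb <- build_neighborhood(net, seed_node, ord)
    d <- igraph::distances(net$graph, v = seed_node)
    expect_setequal(nb, colnames(d)[d[1, ] <= ord])
    # monotone nesting
    expect_true(all(nb %in% build_neighborhood(net, seed_node, ord + 1)))
  }
})

test_that("self-loops and duplicate edges are cleaned at construction", {
  net <- ppi_network(tibble::tibble(from = c("A", "A", "B", "C"),
                                    to = c("B", "B", "A", "C")))
  expect_equal(nrow(net$edges), 1)
  expect_setequal(net$nodes, c("A", "B"))
})

test_that("perfectly correlated phospho edges survive the FDR filter, uncovered edges are listed", {
  set.seed(31)
  n <- 24
  sig <- rnorm(n)
  phospho <- rbind(
    A_pS1 = sig + rnorm(n, sd = 1e-6),
    B_pS1 = sig,
    C_pS1 = rnorm(n),
    D_pS1 = rnorm(n))
  colnames(phospho) <- sprintf("s%02d", 1:n)
  net <- ppi_network(tibble::tibble(from = c("A", "C", "E"),
                                    to = c("B", "D", "A")))
  out <- filter_edges_by_phospho(net, phospho, fdr = 0.10)
  tested <- attr(out, "tested")
  expect_true(tested$retained[tested$from == "A" & tested$to == "B"])
  expect_true(any(attr(out, "untestable")$from == "E"))
  # output edges are a subset of input edges; no new nodes
  expect_true(all(out$nodes %in% net$nodes))
  expect_lte(nrow(out$edges), nrow(net$edges))
  expect_error(filter_edges_by_phospho(net, phospho, fdr = 1.5), "\\(0, 1\\)")
})

test_that("the best |r| site pair represents a multi-site edge", {
  set.seed(32)
  n <- 20
  sig <- rnorm(n)
  phospho <- rbind(
    A_pS1 = rnorm(n),        # weak site
    A_pS2 = sig,             # strong site
    B_pS9 = sig + rnorm(n, sd = 0.01))
  colnames(phospho) <- sprintf("s%02d", 1:n)
  net <- ppi_network(tibble::tibble(from = "A", to = "B"))
  out <- filter_edges_by_phospho(net, phospho)
  expect_equal(attr(out, "tested")$site_from, "A_pS2")
})

test_that("cytokine TF sets are looked up per cytokine in input order", {
  tf_map <- list(T1 = c("CCL5"), T2 = c("CXCL10", "CCL5"), T3 = c("XYZ"))
  sets <- cytokine_tf_sets(tf_map, c("CCL5", "CXCL10"))
  expect_equal(names(sets), c("CCL5", "CXCL10"))
  expect_setequal(sets$CCL5, c("T1", "T2"))
  expect_equal(sets$CXCL10, "T2")
  expect_warning(cytokine_tf_sets(tf_map, "IL16"), "bound by no TF")
  expect_error(cytokine_tf_sets(tf_map, character()), "non-empty")
})

test_that("empirical enrichment follows the plus-one rule and validates inputs", {
  universe <- paste0("p", 1:30)
  tf_sets <- list(CCL5 = paste0("p", 1:10))
  nodes <- paste0("p", 1:8)  # all 8 nodes early -> observed count 8 is extreme
  enr <- empirical_enrichment(nodes, tf_sets, universe,
                              n_iterations = 999, seed = 3)
  nulls <- attr(enr, "null_counts")
  expect_equal(enr$empirical_p,
               (sum(nulls[1, ] >= enr$observed_count) + 1) / 1000)
  expect_error(empirical_enrichment(universe, tf_sets, universe), "larger")
  expect_error(empirical_enrichment(c(nodes, "zzz"), tf_sets, universe),
               "subset")
})

test_that("empirical p matches exhaustive enumeration on a small universe", {
  set.seed(41)
  universe <- paste0("u", 1:14)
  tf_set <- sample(universe, 6)
  nodes <- sample(universe, 5)
  enr <- empirical_enrichment(nodes, list(x = tf_set), universe,
                              n_iterations = 20000, seed = 42)
  exact <- oracle_enrichment_p(5, tf_set, universe, enr$observed_count)
  se <- sqrt(exact * (1 - exact) / 20000)
  expect_lt(abs(enr$empirical_p - exact), 3 * se + 1e-4)
})

test_that("empirical p is invariant to universe relabeling", {
  set.seed(51)
  universe <- paste0("u", 1:40)
  tf_sets <- list(a = sample(universe, 12))
  nodes <- sample(universe, 10)
  p1 <- empirical_enrichment(nodes, tf_sets, universe,
                             n_iterations = 20000, seed = 5)$empirical_p
  perm <- setNames(sample(universe), universe)
  p2 <- empirical_enrichment(unname(perm[nodes]),
                             list(a = unname(perm[tf_sets$a])),
                             unname(perm[universe]),
                             n_iterations = 20000, seed = 6)$empirical_p
  expect_lt(abs(p1 - p2), 0.02)
})
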