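test_that("graph_probability reproduces the worked 3-node computations", {
  G <- worked_graph()
  tri <- ibd_config_from_membership(c("1", "2", "3"), c(1, 1, 1))
  only23 <- ibd_config_from_edges(c("1", "2", "3"), list(c("2", "3")))
  empty <- ibd_config_from_edges(c("1", "2", "3"))
  expect_equal(graph_probability(tri, G), 0.081)
  expect_equal(graph_probability(only23, G), 0.001)
  expect_equal(graph_probability(empty, G), 0.009)

  half <- ibd_graph_from_probs(c("1", "2", "3"), rep(0.5, 3))
  expect_equal(graph_probability(tri, half), 0.125)
  expect_equal(graph_probability(empty, half), 0.125)
})

test_that("log-domain evaluation matches plain products on random graphs", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 8
    probs <- runif(n * (n - 1) / 2, 0.01, 0.99)
    G <- ibd_graph_from_probs(as.character(1:n), probs)
    mask <- sample.int(2^28, 1) - 1
    adj <- mask_to_adj(mask, n)
    dimnames(adj) <- list(as.character(1:n), as.character(1:n))
    g <- ibd_config(adj)
    direct <- mask_prob(mask, probs)
    expect_equal(graph_probability(g, G), direct, tolerance = 1e-12)
    expect_equal(exp(graph_probability(g, G, log = TRUE)), direct,
                 tolerance = 1e-12)
  }
})

test_that("probabilities over all configurations sum to one (h <= 4)", {
  set.seed(7)
  for (n in 2:4) {
    m <- n * (n - 1) / 2
    probs <- runif(m, 0.05, 0.95)
    total <- sum(vapply(0:(2^m - 1), mask_prob, numeric(1), probs = probs))
    expect_equal(total, 1, tolerance = 1e-10)
    # and through the package's own evaluator
    G <- ibd_graph_from_probs(as.character(1:n), probs)
    total_pkg <- sum(vapply(0:(2^m - 1), function(mask) {
      adj <- mask_to_adj(mask, n)
      dimnames(adj) <- list(as.character(1:n), as.character(1:n))
      graph_probability(ibd_config(adj), G)
    }, numeric(1)))
    expect_equal(total_pkg, 1, tolerance = 1e-10)
  }
})

test_that("graph_probability is invariant under node relabeling", {
  set.seed(11)
  probs <- runif(6, 0.1, 0.9)
  G1 <- ibd_graph_from_probs(c("a", "b", "c", "d"), probs)
  # relabel a->w, b->x, c->y, d->z (order preserved under sorting)
  G2 <- ibd_graph_from_probs(c("w", "x", "y", "z"), probs)
  g1 <- ibd_config_from_edges(c("a", "b", "c", "d"),
                              list(c("a", "b"), c("c", "d")))
  g2 <- ibd_config_from_edges(c("w", "x", "y", "z"),
                              list(c("w", "x"), c("y", "z")))
  expect_equal(graph_probability(g1, G1), graph_probability(g2, G2))
})

test_that("graph_probability enforces its contracts", {
  G <- worked_graph()
  g4 <- ibd_config_from_edges(c("1", "2", "3", "4"))
  expect_error(graph_probability(g4, G), "node set")
  Gp <- ibd_graph_from_probs(c("1", "2", "3"), c(1, 0.5, 0.5))
  empty <- ibd_config_from_edges(c("1", "2", "3"))
  expect_error(graph_probability(empty, Gp), "probability 1")
  full <- ibd_config_from_membership(c("1", "2", "3"), c(1, 1, 1))
  Gz <- ibd_graph_from_probs(c("1", "2", "3"), c(0, 0.5, 0.5))
  expect_error(graph_probability(full, Gz), "probability 0")
})

test_that("is_transitive agrees with the triple-rule oracle", {
  tri <- ibd_config_from_membership(c("1", "2", "3"), c(1, 1, 1))
  expect_true(is_transitive(tri))
  vee <- ibd_config_from_edges(c("1", "2", "3"),
                               list(c("1", "2"), c("1", "3")))
  expect_false(is_transitive(vee))
  empty <- ibd_config_from_edges(c("1", "2", "3"))
  expect_true(is_transitive(empty))

  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:5, 1)
    m <- n * (n - 1) / 2
    mask <- sample.int(2^m, 1) - 1
    adj <- mask_to_adj(mask, n)
    dimnames(adj) <- list(as.character(1:n), as.character(1:n))
    expect_identical(is_transitive(ibd_config(adj)),
                     adj_is_transitive(adj))
  }
})

test_that("connected components are found and deterministically ordered", {
  g <- ibd_config_from_edges(c("1", "2", "3"), list(c("1", "2")))
  expect_identical(connected_components(g), list(c("1", "2"), "3"))
  g0 <- ibd_config_from_edges(as.character(1:4))
  expect_identical(connected_components(g0),
                   list("1", "2", "3", "4"))
  chain <- ibd_config_from_edges(c("1", "2", "3"),
                                 list(c("1", "2"), c("2", "3")))
  expect_identical(connected_components(chain), list(c("1", "2", "3")))
})

test_that("clique closure completes components, is idempotent and minimal", {
  chain <- ibd_config_from_edges(c("1", "2", "3"),
                                 list(c("1", "2"), c("2", "3")))
  closed <- clique_close(chain)
  expect_true(closed$adj["1", "3"])
  expect_true(is_transitive(closed))
  expect_identical(clique_close(closed)$adj, closed$adj)

  # two components close independently, no cross edges appear
  g <- ibd_config_from_edges(as.character(1:5),
                             list(c("1", "2"), c("3", "4"), c("4", "5")))
  cc <- clique_close(g)
  expect_true(cc$adj["3", "5"])
  expect_false(any(cc$adj[c("1", "2"), c("3", "4", "5")]))

  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    m <- n * (n - 1) / 2
    adj <- mask_to_adj(sample.int(2^m, 1) - 1, n)
    dimnames(adj) <- list(as.character(1:n), as.character(1:n))
    expect_true(is_transitive(clique_close(ibd_config(adj))))
  }
})

test_that("haplotype ids round-trip and order canonically", {
  expect_identical(hap_id("NA12878", 1), "NA12878:1")
  parsed <- parse_hap_id(c("NA12878:1", "S001:2"))
  expect_identical(parsed$sample, c("NA12878", "S001"))
  expect_identical(parsed$hap_index, c(1L, 2L))
  expect_error(hap_id("a:b", 1), ":")
  expect_error(hap_id("a", 3), "hap_index")
})
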