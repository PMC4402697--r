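test_that("edge weights follow the mirrored normal CDF", {
  expect_equal(edge_weight(0.5), 0.5)
  expect_equal(edge_weight(0.9), 1 - pnorm((0.9 - 0.5) / 0.234),
               tolerance = 1e-12)
  expect_equal(edge_weight(0.9), edge_weight(0.1), tolerance = 1e-12)
  expect_true(all(edge_weight(seq(0.01, 0.99, by = 0.01)) > 0))
  # custom scale
  wp <- weight_params(sigma = 0.1)
  expect_equal(edge_weight(0.2, wp), pnorm(0.2, 0.5, 0.1))
  expect_error(weight_params(sigma = 0), "sigma")
})

test_that("initialization pins high edges and clique-closes", {
  G <- ibd_graph_from_probs(c("1", "2", "3"), c(0.995, 0.0046, 0.999))
  g0 <- initialize_configuration(G)
  expect_true(all(g0$adj[upper.tri(g0$adj)]))  # e13 forced by closure
  expect_true(is_transitive(g0))

  Glow <- ibd_graph_from_probs(c("1", "2", "3"), c(0.5, 0.7, 0.2))
  expect_false(any(initialize_configuration(Glow)$adj))

  Ghigh <- ibd_graph_from_probs(c("1", "2", "3"), c(0.995, 0.999, 0.991))
  expect_true(all(initialize_configuration(Ghigh)$adj[upper.tri(diag(3))]))
})

test_that("repair after adding an edge merges cliques", {
  g <- ibd_config_from_edges(as.character(1:4),
                             list(c("1", "2"), c("3", "4"), c("2", "3")))
  rep1 <- repair_after_add(g, c("2", "3"))
  expect_true(is_transitive(rep1))
  expect_true(all(rep1$adj[upper.tri(diag(4))]))  # one 4-clique

  clique <- ibd_config_from_membership(as.character(1:3), c(1, 1, 1))
  expect_identical(repair_after_add(clique, c("1", "2"))$adj, clique$adj)

  two <- ibd_config_from_edges(as.character(1:3), list(c("1", "3")))
  out <- repair_after_add(two, c("1", "3"))
  expect_identical(sum(out$adj), 2L)  # just the 2-clique
})

test_that("repair after removal splits by mean probability", {
  G <- worked_graph()  # p12 = 0.9, p13 = 0.9, p23 = 0.1
  tri <- ibd_config_from_membership(c("1", "2", "3"), c(1, 1, 1))
  # remove e13: node 2 joins side 1 because p12 = 0.9 > p23 = 0.1
  tri13 <- tri
  tri13$adj["1", "3"] <- tri13$adj["3", "1"] <- FALSE
  set.seed(1)
  out <- repair_after_remove(tri13, G, c("1", "3"))
  expect_identical(connected_components(out), list(c("1", "2"), "3"))
  expect_true(is_transitive(out))

  # removing the only edge of a 2-clique leaves singletons
  G2 <- ibd_graph_from_probs(c("a", "b"), 0.5)
  g2 <- ibd_config_from_edges(c("a", "b"))
  expect_identical(connected_components(repair_after_remove(
    ibd_config_from_edges(c("a", "b"), list(c("a", "b"))), G2,
    c("a", "b"))), list("a", "b"))

  expect_error(repair_after_remove(g2, G2, c("a", "b")), "component")
})

test_that("pinned sub-cliques survive removal repair as blocks", {
  # nodes 1..4: pinned clique {3,4}; removing e12 from the full clique
  # must keep {3,4} welded and assign it wholesale
  probs <- c(0.5, 0.2, 0.2, 0.9, 0.9, 0.995)
  # pairs: (1,2)=0.5 (1,3)=0.2 (1,4)=0.2 (2,3)=0.9 (2,4)=0.9 (3,4)=0.995
  G <- ibd_graph_from_probs(as.character(1:4), probs)
  full <- ibd_config_from_membership(as.character(1:4), rep(1, 4))
  full$adj["1", "2"] <- full$adj["2", "1"] <- FALSE
  set.seed(2)
  out <- repair_after_remove(full, G, c("1", "2"))
  expect_true(is_transitive(out))
  expect_true(out$adj["3", "4"])  # weld intact
  # {3,4} closer to 2 (0.9) than to 1 (0.2): joins side 2
  expect_identical(connected_components(out), list("1", c("2", "3", "4")))
})

test_that("welded endpoints cannot be split and the component survives", {
  # e13 and e23 pinned: removing e12 finds 1 and 2 welded through 3
  G <- ibd_graph_from_probs(as.character(1:3), c(0.5, 0.995, 0.999))
  full <- ibd_config_from_membership(as.character(1:3), rep(1, 3))
  full$adj["1", "2"] <- full$adj["2", "1"] <- FALSE
  out <- repair_after_remove(full, G, c("1", "2"))
  expect_identical(connected_components(out), list(c("1", "2", "3")))
})

test_that("sampler recovers exact conditionals on small graphs", {
  # with mid-range probabilities every transitive configuration is
  # visited quickly, so the distinct-mass estimate equals the
  # enumeration ratio almost exactly
  set.seed(5)
  for (n in 3:4) {
    probs <- runif(n * (n - 1) / 2, 0.25, 0.75)
    G <- ibd_graph_from_probs(as.character(1:n), probs)
    ex <- exact_conditionals(G)
    fit <- run_sampler(G, sampler_config(seed = 99, max_iterations = 5000))
    expect_equal(fit$state$distinct_configs, bell_number(n))
    up <- pair_index(n)
    expect_equal(fit$p_hat[up], ex[up], tolerance = 1e-9)
  }
})

test_that("the worked example estimate lands within 1% of 0.324", {
  G <- worked_graph()
  fit <- run_sampler(G, sampler_config(seed = 17, max_iterations = 5000))
  expect_lt(abs(fit$p_hat["2", "3"] - 0.3241107) / 0.3241107, 0.01)
})

test_that("fully pinned graphs return all-ones immediately", {
  G <- ibd_graph_from_probs(as.character(1:3), c(0.995, 0.999, 0.992))
  fit <- run_sampler(G)
  up <- pair_index(3)
  expect_true(all(fit$p_hat[up] == 1))
  expect_true(fit$state$converged)
  expect_identical(fit$state$iterations, 0L)
})

test_that("estimates stay in [0,1] and pinned edges report one", {
  set.seed(6)
  probs <- runif(10, 0.01, 0.98)
  probs[c(2, 7)] <- c(0.995, 0.999)
  G <- ibd_graph_from_probs(as.character(1:5), probs)
  fit <- run_sampler(G, sampler_config(seed = 3, max_iterations = 2000))
  up <- pair_index(5)
  vals <- fit$p_hat[up]
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(vals[c(2, 7)] == 1))
})

test_that("identical seed and config give identical trajectories", {
  G <- random_ibd_graph(6, seed = 8)
  cfg <- sampler_config(seed = 123, max_iterations = 3000)
  f1 <- run_sampler(G, cfg, record_iterations = c(1000, 3000))
  f2 <- run_sampler(G, cfg, record_iterations = c(1000, 3000))
  expect_identical(f1$p_hat, f2$p_hat)
  expect_identical(f1$snapshots, f2$snapshots)
  expect_identical(f1$state$log_n_g, f2$state$log_n_g)
})

test_that("the time limit stops long runs and flags the state", {
  G <- random_ibd_graph(8, seed = 9)
  fit <- run_sampler(G, sampler_config(max_seconds = 0.05, seed = 4))
  expect_true(fit$state$timed_out)
  expect_false(fit$state$converged)
})

test_that("the convergence window terminates exhausted small graphs", {
  # a 3-node graph has 5 configurations; once all are visited the
  # distinct-mass estimate stops changing and the run converges
  G <- ibd_graph_from_probs(as.character(1:3), c(0.4, 0.5, 0.6))
  fit <- run_sampler(G, sampler_config(seed = 10,
                                       convergence_window = 500))
  expect_true(fit$state$converged)
  expect_equal(fit$state$distinct_configs, 5)
})
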