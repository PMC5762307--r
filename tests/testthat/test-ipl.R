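test_that("pathway_graph validates structure", {
  nodes <- data.frame(id = c("a", "b"), type = "gene")
  expect_error(pathway_graph(nodes, data.frame(source = "a", target = "z",
                                               sign = 1L, kind = "other")),
               "endpoints", class = "iplscreen_input_error")
  expect_error(pathway_graph(nodes, data.frame(source = "a", target = "a",
                                               sign = 1L, kind = "other")),
               "self-loops", class = "iplscreen_input_error")
  expect_error(pathway_graph(rbind(nodes, nodes)), "duplicate",
               class = "iplscreen_input_error")
})

test_that("isolated node matches the closed form", {
  g <- make_graph("a")
  res <- infer_ipl(g, obs_for("a", z = 1),
                   ipl_params(beta_expr = 1, beta_cn = 0))
  expect_equal(res$ipl, 2 / log(10), tolerance = 1e-12)
  ## belief ratio up/down = exp(2)
  expect_equal(res$belief_up / res$belief_down, exp(2), tolerance = 1e-12)
  expect_equal(exact_ipl(g, obs_for("a", z = 1),
                         ipl_params(beta_expr = 1, beta_cn = 0))$ipl,
               2 / log(10), tolerance = 1e-12)
})

test_that("zero observations give zero scores and symmetric beliefs", {
  g <- make_graph(c("a", "b", "c"),
                  data.frame(source = c("a", "b"), target = c("b", "c"),
                             sign = c(1L, -1L)))
  res <- infer_ipl(g, obs_for(c("a", "b", "c"), z = 0))
  expect_equal(res$ipl, rep(0, 3), tolerance = 1e-9)
  ## couplings deplete the neutral state symmetrically: up/down beliefs
  ## stay equal (hence ipl 0) but are uniform only when lambda_edge = 0
  expect_equal(res$belief_down, res$belief_up, tolerance = 1e-9)
  expect_true(all(abs(res$belief_down + res$belief_neutral +
                        res$belief_up - 1) < 1e-9))
  dec <- infer_ipl(g, obs_for(c("a", "b", "c"), z = 0),
                   ipl_params(lambda_edge = 0))
  expect_equal(dec$belief_neutral, rep(1 / 3, 3), tolerance = 1e-9)
})

test_that("evidence propagates with the edge sign", {
  two_plus <- make_graph(c("a", "b"),
                         data.frame(source = "a", target = "b", sign = 1L))
  two_minus <- make_graph(c("a", "b"),
                          data.frame(source = "a", target = "b", sign = -1L))
  obs <- obs_for("a", z = 1)
  ep <- exact_ipl(two_plus, obs)
  em <- exact_ipl(two_minus, obs)
  expect_gt(ep$ipl[ep$node == "b"], 0)
  expect_lt(em$ipl[em$node == "b"], 0)
  ## BP is exact on trees
  expect_equal(infer_ipl(two_plus, obs)$ipl, ep$ipl, tolerance = 1e-7)
  expect_equal(infer_ipl(two_minus, obs)$ipl, em$ipl, tolerance = 1e-7)
})

test_that("lambda_edge = 0 decouples the graph to the closed form", {
  g <- with_seed(21, {
    ids <- sprintf("n%d", 1:6)
    make_graph(ids, data.frame(source = ids[c(1, 2, 3, 1)],
                               target = ids[c(2, 3, 4, 5)],
                               sign = c(1L, -1L, 1L, 1L)))
  })
  z <- with_seed(22, rnorm(6)); cc <- with_seed(23, rnorm(6, 0, 0.5))
  p <- ipl_params(beta_expr = 1.3, beta_cn = 0.7, lambda_edge = 0)
  res <- infer_ipl(g, obs_for(sprintf("n%d", 1:6), z, cc), p)
  expect_equal(res$ipl, 2 * (1.3 * z + 0.7 * cc) / log(10), tolerance = 1e-9)
})

test_that("negating all observations negates all scores", {
  for (s in 1:5) {
    cfg <- simulation_config(seed = s, graph_n_nodes = 12,
                             planted_subnetwork_size = 4)
    pw <- simulate_pathway(cfg)
    obs <- pw$observations
    neg <- obs; neg$z_expr <- -neg$z_expr; neg$c_cn <- -neg$c_cn
    r1 <- infer_ipl(pw$graph, obs)
    r2 <- infer_ipl(pw$graph, neg)
    expect_equal(r1$ipl, -r2$ipl, tolerance = 1e-7)
  }
})

test_that("increasing a node's evidence never decreases its score", {
  g <- make_graph(c("a", "b", "c"),
                  data.frame(source = c("a", "b"), target = c("b", "c"),
                             sign = c(1L, -1L)))
  ipls <- sapply(seq(-2, 2, by = 0.5), function(z)
    infer_ipl(g, obs_for(c("a", "b"), z = c(z, 0.3)))$ipl[1])
  expect_true(all(diff(ipls) > 0))
})

test_that("belief propagation matches enumeration on small graphs", {
  for (s in 1:6) {
    cfg <- simulation_config(seed = s, graph_n_nodes = 7,
                             planted_subnetwork_size = 2)
    pw <- simulate_pathway(cfg)
    ex <- exact_ipl(pw$graph, pw$observations)
    bp <- infer_ipl(pw$graph, pw$observations)
    is_tree <- nrow(pw$graph$edges) == nrow(pw$graph$nodes) - 1L
    tol <- if (is_tree) 1e-6 else 0.6   # loopy BP approximation error bound
    expect_lt(max(abs(ex$ipl - bp$ipl)), tol)
    expect_true(attr(bp, "converged"))
  }
  big <- make_graph(sprintf("n%02d", 1:13))
  expect_error(exact_ipl(big, NULL), class = "iplscreen_size_error")
})

test_that("build_observations standardizes by the robust scale", {
  de <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                   mean_a = c(10, 20, 30, 40), mean_b = c(10, 80, 15, 160),
                   log2fc = log2(c(11 / 11, 81 / 21, 16 / 31, 161 / 41)),
                   p_value = 0.5, q_value = 0.5, significant = FALSE)
  g <- make_graph(c("g1", "g2", "g3", "g4", "cx"),
                  types = c(rep("gene", 4), "complex"))
  obs <- build_observations(de, NULL, g)
  expect_identical(obs$node, c("g1", "g2", "g3", "g4"))
  expect_equal(obs$z_expr, de$log2fc / mad(de$log2fc))
  expect_identical(obs$z_expr[1], 0)       # mean_a == mean_b
  ## scaling all differentials leaves ranks unchanged
  de2 <- de; de2$log2fc <- de$log2fc * 3.7
  expect_equal(rank(build_observations(de2, NULL, g)$z_expr), rank(obs$z_expr))
  ## copy number passes through unstandardized
  cn <- data.frame(gene_id = c("g2", "g9"), log2_ratio = c(1.25, 3),
                   n_overlapping_segments = 1L)
  obs2 <- suppressMessages(build_observations(de, cn, g))
  expect_equal(obs2$c_cn[obs2$node == "g2"], 1.25)
  ## no overlap at all is an error
  g_none <- make_graph("zz", types = "gene")
  expect_error(build_observations(de, NULL, g_none),
               class = "iplscreen_input_error")
})

test_that("first-neighbour subnetworks are induced correctly", {
  g <- make_graph(c("a", "b", "c", "d"),
                  data.frame(source = c("a", "b", "c"),
                             target = c("b", "c", "d"), sign = 1L))
  sub <- first_neighbor_subnetwork(g, "a")
  expect_setequal(sub$nodes$id, c("a", "b"))
  expect_identical(nrow(sub$edges), 1L)
  ## seeds = all nodes reproduces the graph
  all_sub <- first_neighbor_subnetwork(g, g$nodes$id)
  expect_setequal(all_sub$nodes$id, g$nodes$id)
  expect_identical(nrow(all_sub$edges), nrow(g$edges))
  ## incoming neighbours count too
  sub_d <- first_neighbor_subnetwork(g, "d")
  expect_setequal(sub_d$nodes$id, c("c", "d"))
  ## isolated seed, unknown seed
  iso <- make_graph(c("x", "y"))
  expect_identical(first_neighbor_subnetwork(iso, "x")$nodes$id, "x")
  expect_error(first_neighbor_subnetwork(g, c("a", "nope")), "nope",
               class = "iplscreen_input_error")
})

test_that("planted subnetworks score above background", {
  wins <- sapply(1:10, function(s) {
    pw <- simulate_pathway(simulation_config(seed = s))
    res <- infer_ipl(pw$graph, pw$observations)
    planted <- res$node %in% pw$truth$active_nodes
    mean(res$ipl[planted]) > mean(res$ipl[!planted])
  })
  expect_true(all(wins))
})
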