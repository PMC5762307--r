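test_that("config validation names the offending field", {
  expect_error(simulation_config(de_fraction = 1.5), "de_fraction",
               class = "iplscreen_config_error")
  expect_error(simulation_config(n_genes = 0), "n_genes",
               class = "iplscreen_config_error")
  expect_error(simulation_config(planted_subnetwork_size = 99,
                                 graph_n_nodes = 10),
               "planted_subnetwork_size", class = "iplscreen_config_error")
  expect_error(simulation_config(cn_events = list(
    list(chrom = "chr1", start_probe = 10, end_probe = 30, log2_shift = 1),
    list(chrom = "chr1", start_probe = 20, end_probe = 40, log2_shift = -1))),
    "overlap", class = "iplscreen_config_error")
  expect_error(simulation_config(cn_events = list(
    list(chrom = "chr1", start_probe = 50, end_probe = 200, log2_shift = 1))),
    "n_probes", class = "iplscreen_config_error")
})

test_that("identical seed gives bit-identical outputs across modalities", {
  c1 <- simulation_config(seed = 42)
  c2 <- simulation_config(seed = 42)
  expect_identical(simulate_expression(c1), simulate_expression(c2))
  expect_identical(simulate_copy_number(c1), simulate_copy_number(c2))
  expect_identical(simulate_pathway(c1), simulate_pathway(c2))
  g <- sprintf("G%04d", 1:30)
  expect_identical(simulate_screen(c1, g), simulate_screen(c2, g))
})

test_that("RNG streams are isolated per modality", {
  base <- simulation_config(seed = 5)
  tweaked <- simulation_config(seed = 5, plate_rows = 4, plate_cols = 6,
                               gradient_amplitude = 0)
  expect_identical(simulate_expression(base), simulate_expression(tweaked))
  expect_identical(simulate_copy_number(base), simulate_copy_number(tweaked))
})

test_that("no planted effect and no noise give identical condition means", {
  sim <- simulate_expression(simulation_config(seed = 3, de_fraction = 0,
                                               expr_noise_sd = 0))
  m <- sim$matrix
  a <- rowMeans(m$values[, m$condition == "sensitive"])
  b <- rowMeans(m$values[, m$condition == "resistant"])
  expect_equal(a, b)
  expect_identical(nrow(sim$truth), 0L)
})

test_that("copy-number profiles are exact without noise", {
  flat <- simulate_copy_number(simulation_config(seed = 1, cn_events = list(),
                                                 probe_noise_sd = 0))
  expect_true(all(flat$probes$log2_ratio == 0))

  step <- simulate_copy_number(simulation_config(
    seed = 1, probe_noise_sd = 0,
    cn_events = list(list(chrom = "chr1", start_probe = 50, end_probe = 80,
                          log2_shift = 2))))
  expect_equal(step$probes$log2_ratio,
               rep(c(0, 2, 0), c(50, 30, 20)))
  expect_true(!is.unsorted(step$probes$start))
})

test_that("truth is consistent with the simulated universes", {
  cfg <- simulation_config(seed = 9)
  se <- simulate_expression(cfg)
  expect_true(all(se$truth$gene %in% se$matrix$gene_ids))
  pw <- simulate_pathway(cfg)
  expect_true(all(pw$truth$active_nodes %in% pw$graph$nodes$id))
  expect_length(pw$truth$active_nodes, cfg$planted_subnetwork_size)
  genes <- sprintf("G%04d", 1:40)
  sc <- simulate_screen(cfg, genes)
  expect_true(all(sc$truth$gene %in% genes))
})

test_that("pathway generator handles edge cases and stays connected", {
  single <- simulate_pathway(simulation_config(seed = 2, graph_n_nodes = 1,
                                               planted_subnetwork_size = 1))
  expect_identical(nrow(single$graph$nodes), 1L)
  expect_identical(nrow(single$graph$edges), 0L)

  pw <- simulate_pathway(simulation_config(seed = 8))
  g <- pw$graph
  ## connectivity via undirected reachability from node 1
  adj <- split(c(g$edges$target, g$edges$source),
               c(g$edges$source, g$edges$target))
  seen <- g$nodes$id[1]; queue <- seen
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    nb <- setdiff(adj[[v]], seen)
    seen <- c(seen, nb); queue <- c(queue, nb)
  }
  expect_setequal(seen, g$nodes$id)
})

test_that("screen wells reproduce the base value in the artifact-free world", {
  cfg <- simulation_config(seed = 4, gradient_amplitude = 0,
                           well_noise_cv = 0, n_kill_genes = 0)
  sim <- simulate_screen(cfg, sprintf("G%04d", 1:20))
  gene_wells <- !(sim$plates$content %in%
                    c("empty", "negative_control", "positive_control"))
  expect_true(all(sim$plates$raw_mts[gene_wells] == 1))
  neg <- sim$plates$content == "negative_control"
  expect_true(all(sim$plates$raw_mts[neg] == 1))   # zero kill on controls
  expect_identical(sum(neg), 4L * length(unique(sim$plates$plate_id)))
})

test_that("screen layout errors and multi-plate overflow behave", {
  cfg <- simulation_config(seed = 4)
  expect_error(simulate_screen(cfg, character()), "non-empty",
               class = "iplscreen_input_error")
  many <- sprintf("G%04d", 1:150)   # 90 gene wells per 96-well plate
  sim <- simulate_screen(cfg, many)
  expect_identical(length(unique(sim$plates$plate_id)), 12L)  # 2 per line/rep
  placed <- setdiff(unique(sim$plates$content),
                    c("empty", "negative_control", "positive_control"))
  expect_setequal(placed, many)
})
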