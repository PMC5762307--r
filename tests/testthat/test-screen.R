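test_that("plate_set validates well bookkeeping", {
  p <- make_plate(matrix(1, 4, 6))
  expect_s3_class(plate_set(p), "plate_set")
  dup <- rbind(p, p[1, ])
  expect_error(plate_set(dup), "duplicate", class = "iplscreen_input_error")
  bad <- p; bad$raw_mts[1] <- NA
  expect_error(plate_set(bad), class = "iplscreen_input_error")
})

test_that("surface fit reproduces constants and exact planes", {
  p <- make_plate(matrix(7.5, 8, 12))
  expect_equal(unname(fit_spatial_surface(p, span = 1)),
               rep(7.5, 96), tolerance = 1e-10)
  ## exactly linear plate: residuals vanish at any occupancy
  vals <- outer(1:8, 1:12, function(r, c) 2 + 0.3 * r - 0.1 * c)
  p2 <- make_plate(vals)
  expect_equal(unname(fit_spatial_surface(p2, span = 1)),
               p2$raw_mts[p2$content != "empty"], tolerance = 1e-8)
  p3 <- p2; p3$content[p3$row >= 7] <- "empty"; p3$raw_mts[p3$row >= 7] <- NA
  occ3 <- p3$content != "empty"
  expect_equal(unname(fit_spatial_surface(p3, span = 0.2)),
               p3$raw_mts[occ3], tolerance = 1e-8)
  expect_error(fit_spatial_surface(p, span = 0), class = "iplscreen_input_error")
  expect_error(fit_spatial_surface(p[1:4, ], span = 1),
               class = "iplscreen_input_error")
})

test_that("normalization yields 1 on uniform plates and is scale invariant", {
  p <- make_plate(matrix(3.2, 8, 12))
  nv <- normalize_plate(p)
  expect_equal(nv$viability, rep(1, nrow(nv)), tolerance = 1e-10)
  expect_identical(unique(nv$control_basis), "negative_control")
  ## doubling every raw value changes nothing
  noisy <- make_plate(matrix(with_seed(41, rlnorm(96, 0, 0.1)), 8, 12))
  n1 <- normalize_plate(noisy)
  doubled <- noisy; doubled$raw_mts <- doubled$raw_mts * 2
  n2 <- normalize_plate(doubled)
  expect_equal(n1$viability, n2$viability, tolerance = 1e-10)
})

test_that("plates without negative controls fall back to the plate median", {
  p <- make_plate(matrix(2, 8, 12), with_neg_control = FALSE)
  nv <- normalize_plate(p)
  expect_identical(unique(nv$control_basis), "plate_median")
  expect_equal(nv$viability, rep(1, nrow(nv)), tolerance = 1e-10)
})

test_that("exact Wilcoxon matches the enumeration oracle", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3)), 0.1)
  ## every distinct 3v3 rank configuration
  for (split in asplit(utils::combn(6, 3), 2)) {
    xs <- as.numeric(split); ys <- setdiff(1:6, xs)
    expect_equal(wilcoxon_rank_sum(xs, ys), wilcox_enum(xs, ys))
  }
  ## a few random tie-free 4v4 and 5v3 cases
  for (s in 1:5) {
    xy <- with_seed(s, sample(100, 8))
    expect_equal(wilcoxon_rank_sum(xy[1:4], xy[5:8]),
                 wilcox_enum(xy[1:4], xy[5:8]))
    expect_equal(wilcoxon_rank_sum(xy[1:5], xy[6:8]),
                 wilcox_enum(xy[1:5], xy[6:8]))
  }
  ## ties / large samples agree with wilcox.test's corrected approximation
  xs <- c(1, 2, 2, 3, 8, 9); ys <- c(2, 4, 4, 5, 6, 7)
  ref <- suppressWarnings(wilcox.test(xs, ys, exact = FALSE,
                                      correct = TRUE))$p.value
  expect_equal(wilcoxon_rank_sum(xs, ys), ref)
  expect_error(wilcoxon_rank_sum(1, c(1, 2)), class = "iplscreen_input_error")
})

test_that("hit calling applies all three gates with reasons", {
  mk <- function(gene, res, sen) {
    rbind(data.frame(gene = gene, cell_line = "MR49F", replicate = 1:3,
                     viability = res, plate_id = "p", control_basis = "negative_control"),
          data.frame(gene = gene, cell_line = "V16D", replicate = 1:3,
                     viability = sen, plate_id = "p", control_basis = "negative_control"))
  }
  ## 20 filler genes with overlapping values keep the BH denominator honest
  filler <- do.call(rbind, lapply(1:20, function(i)
    mk(sprintf("f%02d", i), c(1.00, 0.97, 1.03) + i * 1e-4,
       c(0.98, 1.01, 1.02) + i * 1e-4)))
  strong <- mk("strong", c(0.80, 0.78, 0.82), c(0.95, 0.96, 0.94))
  weak_kill <- mk("weak_kill", c(0.90, 0.91, 0.92), c(1.05, 1.06, 1.04))
  wrong_dir <- mk("wrong_dir", c(0.70, 0.71, 0.69), c(0.60, 0.61, 0.59))
  no_sig <- mk("no_sig", c(0.98, 1.01, 1.02), c(0.99, 1.00, 1.03))  # p = 1
  ## the 3v3 exact p floor is 0.1; with 24 genes and 3 at the floor the
  ## smallest q is 0.1 * 24 / 3 = 0.8, so 0.9 separates it from q = 1
  ht <- call_hits(rbind(filler, strong, weak_kill, wrong_dir, no_sig),
                  q_threshold = 0.9)
  expect_identical(ht$fail_reasons[ht$gene == "strong"], "")
  expect_true(ht$is_hit[ht$gene == "strong"])
  expect_identical(ht$fail_reasons[ht$gene == "weak_kill"], "kill_lt_15pct")
  expect_identical(ht$fail_reasons[ht$gene == "wrong_dir"], "not_greater_kill")
  expect_match(ht$fail_reasons[ht$gene == "no_sig"], "q_ge_threshold")
  expect_true(all(ht$is_hit == (ht$fail_reasons == "")))
  ## q from BH over all tested genes
  expect_equal(ht$q_value, bh_adjust(ht$p_value))
  expect_error(call_hits(strong, resistant = "HELA"),
               class = "iplscreen_input_error")
})

test_that("genes missing a cell line are excluded with a message", {
  nv <- data.frame(gene = rep(c("a", "b"), each = 6),
                   cell_line = rep(rep(c("MR49F", "V16D"), each = 3), 2),
                   replicate = rep(1:3, 4),
                   viability = with_seed(51, rlnorm(12, 0, 0.05)),
                   plate_id = "p", control_basis = "negative_control")
  lop <- nv[!(nv$gene == "b" & nv$cell_line == "V16D"), ]
  expect_message(ht <- call_hits(lop), "excluding")
  expect_identical(ht$gene, "a")
})

test_that("normalization removes a planted multiplicative gradient", {
  cfg <- simulation_config(seed = 61, n_kill_genes = 0, well_noise_cv = 0.05,
                           gradient_amplitude = 0.3, bump_amplitude = 0.15)
  sim <- simulate_screen(cfg, sprintf("G%04d", 1:64))
  nv <- normalize_screen(sim$plates)
  ps <- sim$plates
  rowof <- setNames(ps$row, paste(ps$plate_id, ps$content))
  r <- rowof[paste(nv$plate_id, nv$gene)]
  raw <- setNames(ps$raw_mts, paste(ps$plate_id, ps$content))[
    paste(nv$plate_id, nv$gene)]
  per_plate <- function(v) sapply(split(seq_len(nrow(nv)), nv$plate_id),
                                  function(i) cor(v[i], r[i], method = "spearman"))
  expect_gt(mean(abs(per_plate(raw))), 0.3)           # artifact present in raw
  ## reduced to near the n=64 Spearman noise floor (null SD ~ 0.126)
  expect_lt(mean(abs(per_plate(nv$viability))), 0.2)
})
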