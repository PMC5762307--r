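#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with validation.
#' Defaults describe the stated experimental world the pipeline targets:
#' biological triplicates per condition, planted 2-fold expression changes,
#' a single focal copy-number event on an exome-style probe grid, a signed
#' curated-pathway-like graph with a planted active subnetwork, and 96-well
#' viability plates with a smooth multiplicative spatial gradient and a
#' handful of planted differential-kill genes.
#'
#' @param seed master integer seed; one per-modality RNG stream is derived
#'   from it, so identical configs give bit-identical outputs and changing
#'   e.g. plate parameters never perturbs the expression draws.
#' @param n_genes number of simulated genes.
#' @param n_samples_per_condition replicates per condition (default 3,
#'   biological triplicate).
#' @param de_fraction fraction of genes with a planted expression shift.
#' @param de_log2fc planted absolute shift in log2 units (default 2, i.e.
#'   4-fold; sign alternates per planted gene).
#' @param expr_noise_sd Gaussian noise SD on the log2 scale.
#' @param n_probes copy-number probes per chromosome.
#' @param cn_events list of events, each `list(chrom, start_probe,
#'   end_probe, log2_shift)` with 0-based half-open probe index ranges;
#'   events on one chromosome must not overlap.
#' @param probe_noise_sd Gaussian SD of probe log2 ratios.
#' @param graph_n_nodes pathway graph size.
#' @param graph_edge_prob probability of each extra directed edge beyond
#'   the connectivity backbone.
#' @param planted_subnetwork_size size of the planted active subnetwork.
#' @param plate_rows,plate_cols plate geometry (default 8 x 12 = 96 wells).
#' @param gradient_amplitude amplitude of the multiplicative linear
#'   row/column gradient (fraction of signal; surface spans roughly
#'   `1 +/- gradient_amplitude`).
#' @param bump_amplitude amplitude of an optional centred smooth Gaussian
#'   bump added to the spatial surface (default 0 = off).
#' @param n_kill_genes number of planted differential-kill genes.
#' @param kill_effect_resistant,kill_effect_sensitive proportion of
#'   viability removed by knockdown of a planted gene in each cell line.
#' @param pos_control_kill kill fraction of the positive-control wells in
#'   both cell lines (default 0.8, a strong pan-lethal knockdown; set 0
#'   for a fully effect-free null plate).
#' @param well_noise_cv multiplicative well noise, as a coefficient of
#'   variation.
#' @return an object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 1000L,
                              n_samples_per_condition = 3L,
                              de_fraction = 0.05,
                              de_log2fc = 2,
                              expr_noise_sd = 0.25,
                              n_probes = 100L,
                              cn_events = list(list(chrom = "chr1",
                                                    start_probe = 50L,
                                                    end_probe = 80L,
                                                    log2_shift = 1)),
                              probe_noise_sd = 0.2,
                              graph_n_nodes = 60L,
                              graph_edge_prob = 0.05,
                              planted_subnetwork_size = 8L,
                              plate_rows = 8L,
                              plate_cols = 12L,
                              gradient_amplitude = 0.3,
                              bump_amplitude = 0,
                              n_kill_genes = 10L,
                              kill_effect_resistant = 0.4,
                              kill_effect_sensitive = 0.05,
                              pos_control_kill = 0.8,
                              well_noise_cv = 0.05) {
  cfg <- list(
    seed = check_count(seed, "seed", min = 0L),
    n_genes = check_count(n_genes, "n_genes"),
    n_samples_per_condition = check_count(n_samples_per_condition,
                                          "n_samples_per_condition", min = 2L),
    de_fraction = check_proportion(de_fraction, "de_fraction"),
    de_log2fc = check_nonneg(de_log2fc, "de_log2fc"),
    expr_noise_sd = check_nonneg(expr_noise_sd, "expr_noise_sd"),
    n_probes = check_count(n_probes, "n_probes"),
    cn_events = validate_cn_events(cn_events),
    probe_noise_sd = check_nonneg(probe_noise_sd, "probe_noise_sd"),
    graph_n_nodes = check_count(graph_n_nodes, "graph_n_nodes"),
    graph_edge_prob = check_proportion(graph_edge_prob, "graph_edge_prob"),
    planted_subnetwork_size = check_count(planted_subnetwork_size,
                                          "planted_subnetwork_size"),
    plate_rows = check_count(plate_rows, "plate_rows"),
    plate_cols = check_count(plate_cols, "plate_cols"),
    gradient_amplitude = check_proportion(gradient_amplitude,
                                          "gradient_amplitude"),
    bump_amplitude = check_nonneg(bump_amplitude, "bump_amplitude"),
    n_kill_genes = check_count(n_kill_genes, "n_kill_genes", min = 0L),
    kill_effect_resistant = check_proportion(kill_effect_resistant,
                                             "kill_effect_resistant"),
    kill_effect_sensitive = check_proportion(kill_effect_sensitive,
                                             "kill_effect_sensitive"),
    pos_control_kill = check_proportion(pos_control_kill, "pos_control_kill"),
    well_noise_cv = check_nonneg(well_noise_cv, "well_noise_cv")
  )
  if (cfg$planted_subnetwork_size > cfg$graph_n_nodes)
    config_error("'planted_subnetwork_size' exceeds 'graph_n_nodes'")
  for (ev in cfg$cn_events) {
    if (ev$end_probe > cfg$n_probes)
      config_error("'cn_events' refers to probes beyond 'n_probes'")
  }
  cfg$streams <- seed_streams(cfg$seed)
  structure(cfg, class = "simulation_config")
}

validate_cn_events <- function(events) {
  if (length(events) == 0L) return(list())
  for (ev in events) {
    need <- c("chrom", "start_probe", "end_probe", "log2_shift")
    if (!all(need %in% names(ev)))
      config_error("'cn_events' entries need chrom, start_probe, end_probe, log2_shift")
    if (ev$start_probe < 0 || ev$end_probe <= ev$start_probe)
      config_error("'cn_events' requires 0 <= start_probe < end_probe")
  }
  by_chrom <- split(events, vapply(events, `[[`, "", "chrom"))
  for (evs in by_chrom) {
    if (length(evs) < 2L) next
    o <- order(vapply(evs, `[[`, 0, "start_probe"))
    evs <- evs[o]
    for (i in seq_len(length(evs) - 1L)) {
      if (evs[[i + 1L]]$start_probe < evs[[i]]$end_probe)
        config_error("'cn_events' overlap on one chromosome")
    }
  }
  events
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config: seed", x$seed, "|", x$n_genes, "genes x",
      2L * x$n_samples_per_condition, "samples |", x$n_probes,
      "probes/chrom |", x$graph_n_nodes, "pathway nodes |",
      x$plate_rows, "x", x$plate_cols, "plates\n")
  invisible(x)
}

#' Simulate a two-condition expression matrix with planted fold changes
#'
#' Draws linear-scale abundances for two conditions ("sensitive", the
#' parental comparator, and "resistant") with
#' `n_samples_per_condition` replicates each. Noise is log-normal
#' (Gaussian on the log2 scale), so the downstream log2 t-test
#' assumptions hold approximately. A fraction `de_fraction` of genes
#' carries a shift of `+/- de_log2fc` log2 units in the resistant
#' condition (signs alternate).
#'
#' @param config a [simulation_config()].
#' @return list with `matrix` (an [expression_matrix()]) and `truth`
#'   (data frame of planted genes with signed `log2fc`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$streams[["expression"]])
  n <- config$n_genes
  k <- config$n_samples_per_condition
  gene_ids <- sprintf("G%04d", seq_len(n))
  ## Robustly expressed transcript range (~32-2048 FPKM-like units) so
  ## the pipeline's unit pseudocount is a minor regularizer, not an
  ## attenuator of planted fold changes.
  base_log2 <- runif(n, min = 5, max = 11)

  n_de <- round(config$de_fraction * n)
  de_idx <- if (n_de > 0) sort(sample.int(n, n_de)) else integer()
  de_sign <- rep_len(c(1, -1), n_de)
  shift <- numeric(n)
  shift[de_idx] <- de_sign * config$de_log2fc

  samples <- c(paste0("sensitive_", seq_len(k)), paste0("resistant_", seq_len(k)))
  condition <- setNames(rep(c("sensitive", "resistant"), each = k), samples)
  replicate <- setNames(rep(seq_len(k), times = 2L), samples)

  log2_means <- cbind(matrix(base_log2, n, k),
                      matrix(base_log2 + shift, n, k))
  noise <- matrix(rnorm(n * 2L * k, sd = config$expr_noise_sd), n, 2L * k)
  values <- 2^(log2_means + noise)
  dimnames(values) <- list(gene_ids, samples)

  truth <- data.frame(gene = gene_ids[de_idx],
                      log2fc = de_sign * config$de_log2fc,
                      stringsAsFactors = FALSE)
  list(matrix = expression_matrix(values, condition, replicate),
       truth = truth)
}

#' Simulate probe-level copy-number log2 ratios
#'
#' Probes tile each chromosome named in `cn_events` (or "chr1" when no
#' events are configured) as `n_probes` consecutive 1 kb windows, 0-based
#' half-open. The profile is 0 everywhere, plus each event's `log2_shift`
#' over its probe index range, plus Gaussian noise of SD `probe_noise_sd`.
#'
#' @param config a [simulation_config()].
#' @return list with `probes` (data frame: probe_id, chrom, start, end,
#'   log2_ratio, sorted by (chrom, start)) and `truth` (data frame of true
#'   segments in probe indices and genomic coordinates).
#' @export
simulate_copy_number <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$streams[["copynumber"]])
  chroms <- unique(vapply(config$cn_events, `[[`, "", "chrom"))
  if (length(chroms) == 0L) chroms <- "chr1"
  chroms <- sort(chroms)
  width <- 1000L

  probes <- do.call(rbind, lapply(chroms, function(ch) {
    idx <- seq_len(config$n_probes) - 1L
    data.frame(probe_id = sprintf("%s_p%04d", ch, idx + 1L),
               chrom = ch,
               start = idx * width,
               end = (idx + 1L) * width,
               log2_ratio = 0,
               stringsAsFactors = FALSE)
  }))
  for (ev in config$cn_events) {
    sel <- probes$chrom == ev$chrom &
      probes$start >= ev$start_probe * width &
      probes$start < ev$end_probe * width
    probes$log2_ratio[sel] <- probes$log2_ratio[sel] + ev$log2_shift
  }
  probes$log2_ratio <- probes$log2_ratio +
    rnorm(nrow(probes), sd = config$probe_noise_sd)

  truth <- do.call(rbind, lapply(config$cn_events, function(ev) {
    data.frame(chrom = ev$chrom,
               start_probe = ev$start_probe, end_probe = ev$end_probe,
               start = ev$start_probe * width, end = ev$end_probe * width,
               log2_shift = ev$log2_shift, stringsAsFactors = FALSE)
  }))
  list(probes = probes, truth = truth)
}

#' Simulate a signed pathway graph with a planted active subnetwork
#'
#' Builds a connected directed graph: a random attachment backbone (node i
#' links to a uniformly chosen earlier node, random orientation) keeps the
#' graph connected, then each further ordered pair gains an edge with
#' probability `graph_edge_prob`. About 75% of nodes are gene-type (ids
#' shared with the expression universe, "G0001", ...); the rest are
#' complex/family/abstract entities that carry no molecular observations.
#' Edges are 80% activating (+1) / 20% inhibitory (-1). A connected
#' subnetwork of `planted_subnetwork_size` nodes is selected by breadth-
#' first growth; its internal edges are forced activating so that
#' evidence reinforces, and its gene members receive expression z-scores
#' of +2 while background genes draw z ~ N(0, 0.5).
#'
#' @param config a [simulation_config()].
#' @return list with `graph` (a [pathway_graph()]), `observations` (data
#'   frame: node, z_expr, c_cn) and `truth` (character vector
#'   `active_nodes`).
#' @export
simulate_pathway <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$streams[["pathway"]])
  n <- config$graph_n_nodes
  types <- sample(c("gene", "complex", "family", "abstract"), n,
                  replace = TRUE, prob = c(0.75, 0.12, 0.08, 0.05))
  ids <- character(n)
  ids[types == "gene"] <- sprintf("G%04d", seq_len(sum(types == "gene")))
  for (tp in c("complex", "family", "abstract")) {
    sel <- types == tp
    ids[sel] <- sprintf("%s_%02d", tp, seq_len(sum(sel)))
  }
  nodes <- data.frame(id = ids, type = types, stringsAsFactors = FALSE)

  edges <- NULL
  if (n > 1L) {
    src <- integer(0); dst <- integer(0)
    for (i in 2:n) {                       # connectivity backbone
      j <- sample.int(i - 1L, 1L)
      if (runif(1) < 0.5) { src <- c(src, j); dst <- c(dst, i) }
      else { src <- c(src, i); dst <- c(dst, j) }
    }
    extra <- which(upper.tri(matrix(0L, n, n)) | lower.tri(matrix(0L, n, n)))
    keep <- extra[runif(length(extra)) < config$graph_edge_prob]
    src <- c(src, ((keep - 1L) %% n) + 1L)
    dst <- c(dst, ((keep - 1L) %/% n) + 1L)
    dup <- duplicated(paste(src, dst)) | src == dst
    src <- src[!dup]; dst <- dst[!dup]
    sign <- sample(c(1L, -1L), length(src), replace = TRUE, prob = c(0.8, 0.2))
    kind <- ifelse(types[dst] %in% c("complex", "family"),
                   ifelse(types[dst] == "complex", "component", "member"),
                   sample(c("transcriptional", "other"), length(src),
                          replace = TRUE, prob = c(0.7, 0.3)))
    edges <- data.frame(source = ids[src], target = ids[dst],
                        sign = sign, kind = kind, stringsAsFactors = FALSE)
  }
  graph <- pathway_graph(nodes, edges)

  ## planted connected subnetwork by BFS growth over the undirected graph
  planted <- bfs_connected_set(graph, config$planted_subnetwork_size)
  if (length(planted) < config$planted_subnetwork_size)
    config_error("graph too small/disconnected for 'planted_subnetwork_size'")
  if (!is.null(graph$edges) && nrow(graph$edges) > 0L) {
    internal <- graph$edges$source %in% planted & graph$edges$target %in% planted
    graph$edges$sign[internal] <- 1L
  }

  gene_nodes <- nodes$id[nodes$type == "gene"]
  z <- setNames(rnorm(length(gene_nodes), sd = 0.5), gene_nodes)
  z[intersect(planted, gene_nodes)] <- 2
  observations <- data.frame(node = gene_nodes, z_expr = unname(z),
                             c_cn = 0, stringsAsFactors = FALSE)
  list(graph = graph, observations = observations,
       truth = list(active_nodes = planted))
}

bfs_connected_set <- function(graph, size) {
  ids <- graph$nodes$id
  if (size == 1L || is.null(graph$edges) || nrow(graph$edges) == 0L)
    return(ids[seq_len(min(size, length(ids)))])
  adj <- split(c(graph$edges$target, graph$edges$source),
               c(graph$edges$source, graph$edges$target))
  start <- sample(ids, 1L)
  seen <- start; queue <- start
  while (length(queue) > 0L && length(seen) < size) {
    v <- queue[[1L]]; queue <- queue[-1L]
    nb <- setdiff(adj[[v]] %||% character(), seen)
    take <- head(nb, size - length(seen))
    seen <- c(seen, take); queue <- c(queue, take)
  }
  seen
}

#' Simulate an RNAi viability screen as raw plate readings
#'
#' Lays the screened genes out on 96-well (by default) plates for two cell
#' lines ("MR49F", resistant; "V16D", sensitive) in biological triplicate.
#' Each plate reserves 4 negative-control (non-targeted) wells at the
#' corners and 2 positive-control wells on the top/bottom edges; remaining
#' wells are filled row-major with genes and overflow onto further plates.
#' The raw MTS absorbance of an occupied well is
#' `base * (1 - kill) * surface(row, col) * noise`, where `surface` is a
#' multiplicative linear row/column gradient of amplitude
#' `gradient_amplitude` (plus an optional centred Gaussian bump), `noise`
#' is log-normal with CV `well_noise_cv`, and `kill` is the planted
#' effect: `kill_effect_resistant`/`kill_effect_sensitive` for the
#' `n_kill_genes` planted genes, `pos_control_kill` in both lines for the
#' positive control, 0 otherwise. Note that a strongly killed positive-
#' control well is a genuine outlier for the downstream local surface
#' fit on partially occupied plates (small span), just as it would be in
#' a real screen.
#'
#' @param config a [simulation_config()].
#' @param genes character vector of screened gene ids.
#' @return list with `plates` (a [plate_set()] data frame) and `truth`
#'   (data frame of planted genes with per-line effects).
#' @export
simulate_screen <- function(config, genes) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(genes) == 0L) input_error("'genes' must be non-empty")
  if (anyDuplicated(genes)) input_error("'genes' contains duplicates")
  set.seed(config$streams[["screen"]])
  nr <- config$plate_rows; nc <- config$plate_cols
  ctrl <- control_layout(nr, nc)
  capacity <- nr * nc - nrow(ctrl)
  if (capacity < 1L)
    layout_error("plate has no free wells after control placement")
  n_plates <- ceiling(length(genes) / capacity)

  n_kill <- min(config$n_kill_genes, length(genes))
  kill_genes <- if (n_kill > 0) sort(sample(genes, n_kill)) else character()
  eff_res <- setNames(rep(0, length(genes)), genes)
  eff_sen <- eff_res
  eff_res[kill_genes] <- config$kill_effect_resistant
  eff_sen[kill_genes] <- config$kill_effect_sensitive

  grid <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  grid <- grid[order(grid$row, grid$col), ]
  free <- !(paste(grid$row, grid$col) %in% paste(ctrl$row, ctrl$col))

  base <- 1.0
  lines <- c(MR49F = "resistant", V16D = "sensitive")
  out <- vector("list", 0L)
  for (line in names(lines)) {
    for (rep_i in seq_len(3L)) {
      for (p in seq_len(n_plates)) {
        gset <- genes[((p - 1L) * capacity + 1L):min(p * capacity, length(genes))]
        content <- rep("empty", nr * nc)
        content[match(paste(ctrl$row, ctrl$col),
                      paste(grid$row, grid$col))] <- ctrl$content
        content[which(free)[seq_along(gset)]] <- gset
        kill <- numeric(nr * nc)
        is_gene <- !content %in% c("empty", "negative_control", "positive_control")
        kill[is_gene] <- if (lines[[line]] == "resistant")
          eff_res[content[is_gene]] else eff_sen[content[is_gene]]
        kill[content == "positive_control"] <- config$pos_control_kill
        surf <- spatial_surface(grid$row, grid$col, nr, nc,
                                config$gradient_amplitude, config$bump_amplitude)
        raw <- base * (1 - kill) * surf *
          cv_noise_factors(nr * nc, config$well_noise_cv)
        raw[content == "empty"] <- NA_real_
        out[[length(out) + 1L]] <- data.frame(
          plate_id = sprintf("P%02d_%s_R%d", p, line, rep_i),
          cell_line = line, replicate = rep_i,
          row = grid$row, col = grid$col,
          content = content, raw_mts = raw, stringsAsFactors = FALSE)
      }
    }
  }
  plates <- plate_set(do.call(rbind, out))
  truth <- data.frame(gene = kill_genes,
                      effect_resistant = rep(config$kill_effect_resistant, n_kill),
                      effect_sensitive = rep(config$kill_effect_sensitive, n_kill),
                      stringsAsFactors = FALSE)
  list(plates = plates, truth = truth)
}

## Fixed control wells: negative controls at the 4 corners, positive
## controls mid top/bottom edge. Counts/positions are a design choice of
## the generator, recorded in the layout itself.
control_layout <- function(nr, nc) {
  lay <- data.frame(
    row = c(1L, 1L, nr, nr, 1L, nr),
    col = c(1L, nc, 1L, nc, ceiling(nc / 2), ceiling(nc / 2) + 1L),
    content = c(rep("negative_control", 4L), rep("positive_control", 2L)),
    stringsAsFactors = FALSE)
  lay[!duplicated(paste(lay$row, lay$col)) & lay$col <= nc, , drop = FALSE]
}

spatial_surface <- function(row, col, nr, nc, amplitude, bump = 0) {
  gr <- if (nr > 1L) (row - 1) / (nr - 1) - 0.5 else 0
  gc <- if (nc > 1L) (col - 1) / (nc - 1) - 0.5 else 0
  s <- 1 + amplitude * (gr + gc)
  if (bump > 0) {
    rc <- (nr + 1) / 2; cc <- (nc + 1) / 2
    sig2 <- 2 * (min(nr, nc) / 4)^2
    s <- s + bump * exp(-((row - rc)^2 + (col - cc)^2) / sig2)
  }
  s
}
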