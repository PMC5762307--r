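## Stage orchestration: simulate -> diffexpr -> segment -> ipl ->
## nominate -> screen -> hits -> subnetwork. All intermediates are
## plain-text tables under config$outdir; every stage writes a JSON
## manifest (parameters, seed, input checksums, package version) and
## outputs are written atomically (tmp file + rename).

#' Pipeline configuration
#'
#' @param outdir output directory (created if needed).
#' @param seed master seed; fanned out deterministically to stage seeds.
#' @param simulation,diffexpr,segment,ipl,nominate,screen,hits named
#'   lists overriding the corresponding module defaults (see
#'   [simulation_config()], [differential_expression()],
#'   [segment_profile()], [ipl_params()], [nominate_candidates()],
#'   [normalize_screen()], [call_hits()]).
#' @param log_level "info" or "quiet".
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, simulation = list(),
                            diffexpr = list(), segment = list(),
                            ipl = list(), nominate = list(),
                            screen = list(), hits = list(),
                            log_level = "info") {
  structure(list(outdir = outdir, seed = check_count(seed, "seed", 0L),
                 simulation = simulation, diffexpr = diffexpr,
                 segment = segment, ipl = ipl, nominate = nominate,
                 screen = screen, hits = hits, log_level = log_level),
            class = "pipeline_config")
}

pipeline_paths <- function(config) {
  o <- config$outdir
  list(expression = file.path(o, "expression.tsv"),
       expression_samples = file.path(o, "expression.samples.tsv"),
       probes = file.path(o, "probes.tsv"),
       gene_models = file.path(o, "genes.bed"),
       pathway = file.path(o, "pathway.tab"),
       truth = file.path(o, "truth.json"),
       diffexpr = file.path(o, "diffexpr.tsv"),
       seg = file.path(o, "segments.seg"),
       gene_cn = file.path(o, "gene_cn.tsv"),
       ipl = file.path(o, "ipl.tsv"),
       candidates = file.path(o, "candidates.tsv"),
       plates = file.path(o, "plates.csv"),
       screen_truth = file.path(o, "screen_truth.json"),
       viability = file.path(o, "viability.tsv"),
       hits = file.path(o, "hits.tsv"),
       subnetwork = file.path(o, "subnetwork.sif"))
}

## which stage produces which file (for actionable missing-input errors)
producing_stage <- c(expression = "simulate", expression_samples = "simulate",
                     probes = "simulate", gene_models = "simulate",
                     pathway = "simulate", truth = "simulate",
                     diffexpr = "diffexpr", seg = "segment",
                     gene_cn = "segment", ipl = "ipl",
                     candidates = "nominate", plates = "screen",
                     screen_truth = "screen", viability = "screen",
                     hits = "hits", subnetwork = "subnetwork")

require_inputs <- function(config, keys) {
  paths <- pipeline_paths(config)
  for (k in keys) {
    if (!file.exists(paths[[k]]))
      input_error(sprintf(
        "missing input '%s' (produced by stage '%s'); run that stage first",
        paths[[k]], producing_stage[[k]]))
  }
  paths
}

atomic_write <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

write_manifest <- function(config, stage, params, inputs, outputs) {
  manifest <- list(stage = stage,
                   package_version = as.character(packageVersion("iplscreen")),
                   seed = config$seed,
                   parameters = params,
                   inputs = as.list(tools::md5sum(inputs)),
                   outputs = outputs)
  atomic_write(function(p) jsonlite::write_json(
    manifest, p, auto_unbox = TRUE, pretty = TRUE, digits = NA),
    file.path(config$outdir, paste0(stage, ".manifest.json")))
}

log_info <- function(config, ...) {
  if (!identical(config$log_level, "quiet"))
    message("[iplscreen] ", ...)
}

sim_config_for <- function(config) {
  do.call(simulation_config,
          modifyList(list(seed = config$seed), config$simulation))
}

#' Run one pipeline stage
#'
#' Stages: `simulate`, `diffexpr`, `segment`, `ipl`, `nominate`,
#' `screen`, `hits`, `subnetwork`. Each reads its inputs from and writes
#' its outputs under `config$outdir`; a missing input raises an error
#' naming the file and the stage that produces it.
#'
#' @param name stage name.
#' @param config a [pipeline_config()].
#' @return stage-specific summary (counts), invisibly.
#' @export
run_stage <- function(name, config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- c("simulate", "diffexpr", "segment", "ipl", "nominate",
              "screen", "hits", "subnetwork")
  if (!name %in% stages)
    input_error(paste0("unknown stage '", name, "'"))
  log_info(config, "stage ", name)
  switch(name,
         simulate = stage_simulate(config),
         diffexpr = stage_diffexpr(config),
         segment = stage_segment(config),
         ipl = stage_ipl(config),
         nominate = stage_nominate(config),
         screen = stage_screen(config),
         hits = stage_hits(config),
         subnetwork = stage_subnetwork(config))
}

stage_simulate <- function(config) {
  paths <- pipeline_paths(config)
  sc <- sim_config_for(config)
  expr <- simulate_expression(sc)
  cn <- simulate_copy_number(sc)
  pw <- simulate_pathway(sc)
  genes <- simulate_gene_models(sc, expr$matrix$gene_ids)

  atomic_write(function(p) write_expression(expr$matrix, p,
    annot_path = paths$expression_samples), paths$expression)
  atomic_write(function(p) write_probes(cn$probes, p), paths$probes)
  atomic_write(function(p) write_gene_models(genes, p), paths$gene_models)
  atomic_write(function(p) write_pathway(pw$graph, p), paths$pathway)
  truth <- list(de_genes = expr$truth, cn_segments = cn$truth,
                active_nodes = pw$truth$active_nodes)
  atomic_write(function(p) jsonlite::write_json(truth, p, auto_unbox = TRUE,
                                                digits = NA), paths$truth)
  write_manifest(config, "simulate", unclass(sc)[setdiff(names(sc), "streams")],
                 character(), unlist(paths[c("expression", "probes",
                                             "gene_models", "pathway", "truth")]))
  invisible(list(n_genes = sc$n_genes, n_de_planted = nrow(expr$truth),
                 n_probes = nrow(cn$probes),
                 n_nodes = nrow(pw$graph$nodes)))
}

stage_diffexpr <- function(config) {
  paths <- require_inputs(config, c("expression", "expression_samples"))
  mat <- read_expression(paths$expression, paths$expression_samples)
  params <- modifyList(list(cond_a = "sensitive", cond_b = "resistant",
                            q_threshold = 0.05, fc_threshold = 2,
                            pseudocount = 1), config$diffexpr)
  de <- do.call(differential_expression, c(list(matrix = mat), params))
  atomic_write(function(p) write.table(de, p, sep = "\t", quote = FALSE,
                                       row.names = FALSE), paths$diffexpr)
  write_manifest(config, "diffexpr", params,
                 c(paths$expression, paths$expression_samples), paths$diffexpr)
  invisible(list(n_tested = nrow(de), n_significant = sum(de$significant)))
}

stage_segment <- function(config) {
  paths <- require_inputs(config, c("probes", "gene_models"))
  probes <- read_probes(paths$probes)
  params <- modifyList(list(alpha = 0.01, n_perm = 1000L, min_width = 3L),
                       config$segment)
  seg_seed <- unname(seed_streams(config$seed)[["segmentation"]])
  segs <- segment_profile(probes, alpha = params$alpha,
                          n_perm = params$n_perm,
                          min_width = params$min_width, seed = seg_seed)
  genes <- read_gene_models(paths$gene_models)
  gcn <- suppressMessages(gene_level_log_ratio(segs, genes))
  atomic_write(function(p) write_seg(segs, p), paths$seg)
  atomic_write(function(p) write.table(gcn, p, sep = "\t", quote = FALSE,
                                       row.names = FALSE), paths$gene_cn)
  write_manifest(config, "segment", c(params, seed = seg_seed),
                 c(paths$probes, paths$gene_models),
                 unlist(paths[c("seg", "gene_cn")]))
  invisible(list(n_segments = nrow(segs), n_genes_with_cn = nrow(gcn)))
}

stage_ipl <- function(config) {
  paths <- require_inputs(config, c("pathway", "diffexpr", "gene_cn"))
  graph <- read_pathway(paths$pathway)
  de <- read.delim(paths$diffexpr, stringsAsFactors = FALSE)
  gcn <- read.delim(paths$gene_cn, stringsAsFactors = FALSE)
  params <- do.call(ipl_params, config$ipl)
  obs <- suppressMessages(build_observations(de, gcn, graph))
  res <- infer_ipl(graph, obs, params)
  out <- data.frame(node = res$node, type = res$type, ipl = res$ipl,
                    belief_down = res$belief_down,
                    belief_neutral = res$belief_neutral,
                    belief_up = res$belief_up)
  atomic_write(function(p) write.table(out, p, sep = "\t", quote = FALSE,
                                       row.names = FALSE), paths$ipl)
  write_manifest(config, "ipl", unclass(params),
                 c(paths$pathway, paths$diffexpr, paths$gene_cn), paths$ipl)
  invisible(list(n_nodes = nrow(res),
                 converged = attr(res, "converged")))
}

stage_nominate <- function(config) {
  paths <- require_inputs(config, c("ipl", "expression", "expression_samples"))
  ipl <- read.delim(paths$ipl, stringsAsFactors = FALSE)
  class(ipl) <- c("ipl_result", "data.frame")
  mat <- read_expression(paths$expression, paths$expression_samples)
  params <- modifyList(list(k_sd = 2, cv_min = 10, cv_max = 200,
                            min_nonzero_samples = 2L), config$nominate)
  cs <- do.call(nominate_candidates, c(list(ipl = ipl, matrix = mat), params))
  cs <- add_controls(cs)
  tab <- cs$table
  tab$role <- "candidate"
  ctrl <- data.frame(gene = cs$controls$gene, cv = NA_real_,
                     n_nonzero = NA_integer_, passed_cv = NA,
                     passed_nonzero = NA, passed_ipl = NA, ipl = NA_real_,
                     role = cs$controls$role, stringsAsFactors = FALSE)
  out <- rbind(tab[tab$gene %in% cs$candidates, names(ctrl)], ctrl)
  atomic_write(function(p) write.table(out, p, sep = "\t", quote = FALSE,
                                       row.names = FALSE), paths$candidates)
  write_manifest(config, "nominate", params,
                 c(paths$ipl, paths$expression), paths$candidates)
  invisible(list(n_outlier_nodes = length(cs$nominated_nodes),
                 n_gene_nodes = length(cs$gene_nodes),
                 n_candidates = length(cs$candidates)))
}

stage_screen <- function(config) {
  paths <- require_inputs(config, "candidates")
  cand <- read.delim(paths$candidates, stringsAsFactors = FALSE)
  genes <- cand$gene[cand$role %in% c("candidate", "biological")]
  if (!file.exists(paths$plates)) {
    sc <- sim_config_for(config)
    sim <- simulate_screen(sc, genes)
    atomic_write(function(p) write_plates(sim$plates, p), paths$plates)
    atomic_write(function(p) jsonlite::write_json(sim$truth, p,
      auto_unbox = TRUE, digits = NA), paths$screen_truth)
  }
  plates <- read_plates(paths$plates)
  params <- modifyList(list(full_span = 1.0, partial_span = 0.2),
                       config$screen)
  nv <- suppressMessages(do.call(normalize_screen,
                                 c(list(plates = plates), params)))
  atomic_write(function(p) write.table(nv, p, sep = "\t", quote = FALSE,
                                       row.names = FALSE), paths$viability)
  write_manifest(config, "screen", params,
                 c(paths$candidates, paths$plates), paths$viability)
  invisible(list(n_plates = length(unique(plates$plate_id)),
                 n_screened_genes = length(unique(nv$gene))))
}

stage_hits <- function(config) {
  paths <- require_inputs(config, "viability")
  nv <- read.delim(paths$viability, stringsAsFactors = FALSE)
  params <- modifyList(list(resistant = "MR49F", sensitive = "V16D",
                            q_threshold = 0.2, kill_threshold = 0.15),
                       config$hits)
  ht <- suppressMessages(do.call(call_hits, c(list(nv = nv), params)))
  atomic_write(function(p) write.table(ht, p, sep = "\t", quote = FALSE,
                                       row.names = FALSE), paths$hits)
  write_manifest(config, "hits", params, paths$viability, paths$hits)
  invisible(list(n_tested = nrow(ht), n_hits = sum(ht$is_hit)))
}

stage_subnetwork <- function(config) {
  paths <- require_inputs(config, c("hits", "pathway", "ipl"))
  ht <- read.delim(paths$hits, stringsAsFactors = FALSE)
  graph <- read_pathway(paths$pathway)
  ipl <- read.delim(paths$ipl, stringsAsFactors = FALSE)
  class(ipl) <- c("ipl_result", "data.frame")
  seeds <- intersect(ht$gene[ht$is_hit], graph$nodes$id)
  sub <- if (length(seeds) > 0L) first_neighbor_subnetwork(graph, seeds)
         else pathway_graph(graph$nodes[0, , drop = FALSE])
  atomic_write(function(p) write_sif(sub, p, ipl = ipl,
    attr_path = paste0(paths$subnetwork, ".attrs.tsv")), paths$subnetwork)
  write_manifest(config, "subnetwork", list(),
                 c(paths$hits, paths$pathway, paths$ipl), paths$subnetwork)
  invisible(list(n_seed_hits = length(seeds),
                 n_subnetwork_nodes = nrow(sub$nodes)))
}

#' Run the full pipeline
#'
#' Executes all stages in dependency order and returns a summary of the
#' counts at each stage (planted/significant genes, segments, IPL-outlier
#' nodes, candidates, hits), mirroring the structure of a resistance-
#' network analysis report.
#'
#' @param config a [pipeline_config()].
#' @return named list of stage summaries, class `pipeline_summary`.
#' @export
run_all <- function(config) {
  stages <- c("simulate", "diffexpr", "segment", "ipl", "nominate",
              "screen", "hits", "subnetwork")
  summary <- lapply(stages, function(s) run_stage(s, config))
  names(summary) <- stages
  structure(summary, class = "pipeline_summary")
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat("iplscreen pipeline summary\n")
  cat("  simulated genes:      ", x$simulate$n_genes,
      " (planted DE: ", x$simulate$n_de_planted, ")\n", sep = "")
  cat("  significant DE genes: ", x$diffexpr$n_significant, "\n", sep = "")
  cat("  copy-number segments: ", x$segment$n_segments, "\n", sep = "")
  cat("  IPL-outlier nodes:    ", x$nominate$n_outlier_nodes,
      " (gene nodes: ", x$nominate$n_gene_nodes, ")\n", sep = "")
  cat("  candidates screened:  ", x$nominate$n_candidates, "\n", sep = "")
  cat("  hits:                 ", x$hits$n_hits, "\n", sep = "")
  invisible(x)
}

#' Simulated gene models along the probed genome
#'
#' Deterministically tiles the simulated genes across the probed extent
#' of each simulated chromosome (0-based half-open, alternating strand)
#' so that gene-level copy-number summarization has genuine overlaps.
#'
#' @param config a [simulation_config()].
#' @param gene_ids character vector of gene ids to place.
#' @return data frame: gene_id, chrom, start, end, strand.
#' @export
simulate_gene_models <- function(config, gene_ids) {
  stopifnot(inherits(config, "simulation_config"))
  chroms <- unique(vapply(config$cn_events, `[[`, "", "chrom"))
  if (length(chroms) == 0L) chroms <- "chr1"
  chroms <- sort(chroms)
  total <- config$n_probes * 1000L
  n <- length(gene_ids)
  chrom_of <- chroms[(seq_len(n) - 1L) %% length(chroms) + 1L]
  idx <- stats::ave(seq_len(n), chrom_of, FUN = seq_along)
  per_chrom <- table(chrom_of)[chrom_of]
  step <- total / as.numeric(per_chrom)
  start <- floor((idx - 1L) * step)
  end <- pmin(total, floor(start + pmax(1, 0.8 * step)))
  data.frame(gene_id = gene_ids, chrom = chrom_of,
             start = as.integer(start), end = as.integer(end),
             strand = rep_len(c("+", "-"), n), stringsAsFactors = FALSE)
}

#' Command-line entry point
#'
#' Subcommands: the stage names of [run_stage()] plus `run-all`. Options:
#' `--config FILE` (JSON with the fields of [pipeline_config()]),
#' `--outdir DIR` and `--seed N` overrides.
#'
#' @param args character vector (default: command-line arguments).
#' @return exit status, invisibly.
#' @export
iplscreen_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0("usage: iplscreen <",
                  "simulate|diffexpr|segment|ipl|nominate|screen|hits|",
                  "subnetwork|run-all> [--config FILE] [--outdir DIR] ",
                  "[--seed N]")
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[[1L]]; args <- args[-1L]
  opt <- list(outdir = "iplscreen_out", seed = NULL, config = NULL)
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[[i]])
    if (!key %in% names(opt) || i == length(args)) {
      message(usage); return(invisible(1L))
    }
    opt[[key]] <- args[[i + 1L]]; i <- i + 2L
  }
  cfg_args <- list(outdir = opt$outdir, seed = 1L)
  if (!is.null(opt$config))
    cfg_args <- modifyList(cfg_args, jsonlite::read_json(opt$config,
                                                         simplifyVector = TRUE))
  if (!is.null(opt$seed)) cfg_args$seed <- as.integer(opt$seed)
  if (!is.null(opt$outdir)) cfg_args$outdir <- opt$outdir
  config <- do.call(pipeline_config, cfg_args)
  if (cmd == "run-all") print(run_all(config))
  else str(run_stage(cmd, config))
  invisible(0L)
}
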