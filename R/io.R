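## File-format glue. Everything the pipeline writes is plain text with a
## header row; coordinates on disk follow the same 0-based half-open
## convention used in memory (BED-style).

#' Write / read an expression matrix as TSV plus sample annotations
#'
#' The matrix file has a `gene` first column and one column per sample;
#' the annotation file has columns sample, condition, replicate.
#'
#' @param matrix an [expression_matrix()].
#' @param path matrix TSV path.
#' @param annot_path annotation TSV path (default: `path` with
#'   `.samples.tsv` appended to its base name).
#' @return `path`, invisibly.
#' @export
write_expression <- function(matrix, path,
                             annot_path = default_annot_path(path)) {
  stopifnot(inherits(matrix, "expression_matrix"))
  df <- data.frame(gene = matrix$gene_ids, matrix$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- data.frame(sample = matrix$sample_ids,
                    condition = unname(matrix$condition),
                    replicate = unname(matrix$replicate))
  write.table(ann, annot_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

default_annot_path <- function(path)
  paste0(sub("\\.tsv$", "", path), ".samples.tsv")

#' @rdname write_expression
#' @export
read_expression <- function(path, annot_path = default_annot_path(path)) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1L, drop = FALSE])
  rownames(values) <- df[[1L]]
  ann <- read.delim(annot_path, stringsAsFactors = FALSE)
  expression_matrix(values,
                    condition = setNames(ann$condition, ann$sample),
                    replicate = setNames(ann$replicate, ann$sample))
}

#' Write / read probe-level copy-number log2 ratios
#'
#' TSV with columns probe_id, chrom, start, end, log2_ratio.
#'
#' @param probes probe data frame.
#' @param path file path.
#' @export
write_probes <- function(probes, path) {
  write.table(probes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probes
#' @export
read_probes <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write segments in SEG convention
#'
#' Columns: sample, chrom, start, end, n_probes, mean_log2.
#'
#' @param segments a `segment_table`.
#' @param path file path.
#' @param sample sample label for the first column.
#' @export
write_seg <- function(segments, path, sample = "derived_vs_parental") {
  df <- data.frame(sample = sample, segments[, c("chrom", "start", "end",
                                                 "n_probes", "mean_log2")])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read gene models as BED6
#'
#' 0-based half-open, columns chrom/start/end/name/score/strand; scores
#' are written as 0.
#'
#' @param genes data frame (gene_id, chrom, start, end, strand).
#' @param path file path.
#' @export
write_gene_models <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand %||% "*")
  names(gr) <- genes$gene_id
  gr$score <- 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(gene_id = gr$name,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,   # back to 0-based
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write / read a pathway graph as a tab-delimited interaction file
#'
#' Node lines have two fields (`type`, `id`); edge lines have four
#' (`source`, `target`, `kind`, `sign`).
#'
#' @param graph a [pathway_graph()].
#' @param path file path.
#' @export
write_pathway <- function(graph, path) {
  stopifnot(inherits(graph, "pathway_graph"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(graph$nodes$type, graph$nodes$id, sep = "\t"), con)
  if (nrow(graph$edges) > 0L)
    writeLines(paste(graph$edges$source, graph$edges$target,
                     graph$edges$kind, graph$edges$sign, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_pathway
#' @export
read_pathway <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  len <- lengths(parts)
  if (!all(len %in% c(2L, 4L)))
    input_error("pathway file lines must have 2 (node) or 4 (edge) fields")
  nodes <- do.call(rbind, lapply(parts[len == 2L], function(p)
    data.frame(id = p[2L], type = p[1L], stringsAsFactors = FALSE)))
  edges <- if (any(len == 4L)) {
    do.call(rbind, lapply(parts[len == 4L], function(p)
      data.frame(source = p[1L], target = p[2L], kind = p[3L],
                 sign = as.integer(p[4L]), stringsAsFactors = FALSE)))
  } else NULL
  pathway_graph(nodes, edges)
}

#' Export a graph as SIF plus a node-attribute table
#'
#' The SIF relation encodes kind and sign (e.g. `transcriptional+`).
#' Isolated nodes are written as single-field SIF lines. The attribute
#' TSV has columns id, ipl.
#'
#' @param graph a [pathway_graph()].
#' @param path SIF path.
#' @param ipl optional `ipl_result` for the attribute file.
#' @param attr_path attribute TSV path (default `path` + `.attrs.tsv`).
#' @export
write_sif <- function(graph, path, ipl = NULL,
                      attr_path = paste0(path, ".attrs.tsv")) {
  stopifnot(inherits(graph, "pathway_graph"))
  E <- graph$edges
  rel <- paste0(E$kind, ifelse(E$sign > 0, "+", "-"))
  lines <- paste(E$source, rel, E$target, sep = "\t")
  isolated <- setdiff(graph$nodes$id, c(E$source, E$target))
  writeLines(c(lines, isolated), path)
  if (!is.null(ipl)) {
    keep <- ipl$node %in% graph$nodes$id
    write.table(data.frame(id = ipl$node[keep], ipl = ipl$ipl[keep]),
                attr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write / read plate readings as CSV
#'
#' Columns: plate_id, cell_line, replicate, row, col, content, raw_mts.
#'
#' @param plates a [plate_set()].
#' @param path file path.
#' @export
write_plates <- function(plates, path) {
  write.csv(plates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plates
#' @export
read_plates <- function(path) {
  plate_set(read.csv(path, stringsAsFactors = FALSE))
}
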