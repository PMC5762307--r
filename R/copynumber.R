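#' Segment a probe-level log2 copy-number profile
#'
#' Recursive circular binary segmentation (CBS). Within each current
#' segment the arc `(i, j]` maximizing the unit-variance two-sample
#' statistic between in-arc and out-of-arc probe means is located
#' (ties: smallest left boundary, then smallest arc length); the split is
#' accepted when its permutation p-value — `n_perm` shuffles of the probe
#' values within the segment, `(count + 1) / (n_perm + 1)` — is below
#' `alpha` and both resulting parts have at least `min_width` probes.
#' Accepted arcs cut the segment into up to three pieces, each segmented
#' recursively. Chromosomes are processed independently; a chromosome
#' with fewer than `2 * min_width` probes is returned as a single
#' segment. The pruning/undo heuristics of classic CBS implementations
#' are intentionally not reproduced.
#'
#' Output segments tile the probed extent of each chromosome exactly:
#' the first starts at the first probe's start, each subsequent segment
#' starts where its first probe starts, and interior ends are the next
#' segment's start (0-based half-open throughout).
#'
#' @param probes data frame (probe_id, chrom, start, end, log2_ratio)
#'   sorted by (chrom, start).
#' @param alpha permutation significance level for accepting a split.
#' @param n_perm number of within-segment permutations.
#' @param min_width minimum probes per segment.
#' @param seed integer seed for the permutation stream.
#' @return data frame of class `segment_table`: chrom, start, end,
#'   mean_log2, n_probes.
#' @export
segment_profile <- function(probes, alpha = 0.01, n_perm = 1000L,
                            min_width = 3L, seed = 1L) {
  need <- c("chrom", "start", "end", "log2_ratio")
  if (!is.data.frame(probes) || !all(need %in% names(probes)))
    input_error("'probes' needs columns chrom, start, end, log2_ratio")
  o <- order(probes$chrom, probes$start)
  if (!identical(o, seq_len(nrow(probes))))
    input_error("'probes' must be sorted by (chrom, start)")
  if (any(!is.finite(probes$log2_ratio)))
    input_error("'log2_ratio' must be finite")
  min_width <- check_count(min_width, "min_width")
  n_perm <- check_count(n_perm, "n_perm")

  set.seed(seed)
  out <- lapply(split(probes, probes$chrom), function(pp) {
    x <- pp$log2_ratio
    bounds <- cbs_recurse(x, alpha, n_perm, min_width)
    starts <- pp$start[bounds$first]
    ends <- c(pp$start[bounds$first[-1L]], pp$end[nrow(pp)])
    data.frame(chrom = pp$chrom[1L], start = starts, end = ends,
               mean_log2 = bounds$mean, n_probes = bounds$n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out[order(names(out))])
  rownames(res) <- NULL
  class(res) <- c("segment_table", "data.frame")
  res
}

## Returns, for one chromosome's ordered values, the first probe index,
## mean and size of each segment (in order).
cbs_recurse <- function(x, alpha, n_perm, min_width) {
  n <- length(x)
  if (n < 2L * min_width || all(x == x[1L]))
    return(list(first = 1L, mean = mean(x), n = n))
  arc <- .cbs_max_arc(x, min_width)
  if (arc$i < 0)
    return(list(first = 1L, mean = mean(x), n = n))
  count <- .cbs_perm_count(x, min_width, n_perm, arc$stat)
  p <- (count + 1) / (n_perm + 1)
  if (p >= alpha)
    return(list(first = 1L, mean = mean(x), n = n))
  cuts <- unique(c(0L, arc$i, arc$j, n))     # arc (i, j], 0-based bounds
  first <- integer(); mn <- numeric(); sz <- integer()
  for (k in seq_len(length(cuts) - 1L)) {
    lo <- cuts[k] + 1L; hi <- cuts[k + 1L]
    sub <- cbs_recurse(x[lo:hi], alpha, n_perm, min_width)
    first <- c(first, sub$first + lo - 1L)
    mn <- c(mn, sub$mean); sz <- c(sz, sub$n)
  }
  list(first = first, mean = mn, n = sz)
}

#' Gene-level copy-number log2 ratios from segments
#'
#' Per gene, the overlap-length-weighted mean of the means of all
#' overlapping segments. Genes overlapping no segment are omitted (ids in
#' the `"unmatched"` attribute and a message). Strand is carried but
#' ignored; all coordinates are 0-based half-open.
#'
#' @param segments a `segment_table` from [segment_profile()].
#' @param genes data frame of gene models (gene_id, chrom, start, end,
#'   strand).
#' @return data frame of class `gene_cn`: gene_id, log2_ratio,
#'   n_overlapping_segments.
#' @export
gene_level_log_ratio <- function(segments, genes) {
  if (!all(c("chrom", "start", "end", "mean_log2") %in% names(segments)))
    input_error("'segments' needs chrom, start, end, mean_log2")
  if (!all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
    input_error("'genes' needs gene_id, chrom, start, end")
  if (any(genes$start >= genes$end))
    input_error("gene models need start < end")

  ## 0-based half-open -> 1-based closed for GRanges
  seg_gr <- GenomicRanges::GRanges(
    segments$chrom, IRanges::IRanges(segments$start + 1L, segments$end))
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  ov <- GenomicRanges::findOverlaps(gene_gr, seg_gr)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  w <- GenomicRanges::width(IRanges::pintersect(gene_gr[qh], seg_gr[sh]))

  unmatched <- setdiff(seq_len(nrow(genes)), unique(qh))
  if (length(unmatched) > 0L)
    message("gene_level_log_ratio: ", length(unmatched),
            " gene(s) overlap no segment and were omitted")

  num <- tapply(w * segments$mean_log2[sh], qh, sum)
  den <- tapply(w, qh, sum)
  nseg <- tapply(sh, qh, length)
  idx <- as.integer(names(den))
  res <- data.frame(gene_id = genes$gene_id[idx],
                    log2_ratio = as.numeric(num / den),
                    n_overlapping_segments = as.integer(nseg),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "unmatched") <- genes$gene_id[unmatched]
  class(res) <- c("gene_cn", "data.frame")
  res
}
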