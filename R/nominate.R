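#' Nodes with outlying integrated pathway levels
#'
#' Returns the nodes whose IPL lies more than `k_sd` sample standard
#' deviations (n-1 denominator) from the median of all finite node
#' scores — the "2 SD from the median" cut, read literally with the
#' median as centre and the SD as spread.
#'
#' @param ipl an `ipl_result` from [infer_ipl()].
#' @param k_sd multiplier on the standard deviation (default 2).
#' @return character vector of node ids (empty, with a warning, when all
#'   scores are identical).
#' @export
ipl_outlier_nodes <- function(ipl, k_sd = 2) {
  scores <- ipl$ipl[is.finite(ipl$ipl)]
  if (length(scores) < 2L) input_error("need at least 2 finite IPL scores")
  s <- sd(scores)
  if (s == 0) {
    warning("ipl_outlier_nodes: all IPL scores identical; returning none")
    return(character())
  }
  med <- median(scores)
  ok <- is.finite(ipl$ipl) & abs(ipl$ipl - med) > k_sd * s
  ipl$node[ok]
}

#' Expression-variability filters for candidate genes
#'
#' Keeps a gene iff its coefficient of variation over all samples (linear
#' scale, percent) lies within `[cv_min, cv_max]` and it has non-zero
#' expression in at least `min_nonzero_samples` samples. Genes absent
#' from the matrix are dropped with a message. Genes with zero mean have
#' an undefined CV and fail the CV filter (they also fail the non-zero
#' filter).
#'
#' @param genes character vector of candidate gene ids.
#' @param matrix an [expression_matrix()].
#' @param cv_min,cv_max CV band in percent (defaults 10 and 200).
#' @param min_nonzero_samples minimum samples with value > 0 (default 2).
#' @return object of class `candidate_set`: list with `table` (gene, cv,
#'   n_nonzero, passed_cv, passed_nonzero), `candidates` (genes passing
#'   all filters) and an empty `controls` slot.
#' @export
expression_filters <- function(genes, matrix, cv_min = 10, cv_max = 200,
                               min_nonzero_samples = 2L) {
  stopifnot(inherits(matrix, "expression_matrix"))
  missing <- setdiff(genes, matrix$gene_ids)
  if (length(missing) > 0L)
    message("expression_filters: dropping ", length(missing),
            " gene(s) absent from the expression matrix")
  genes <- intersect(genes, matrix$gene_ids)
  vals <- matrix$values[genes, , drop = FALSE]
  cv <- vapply(seq_along(genes), function(i) {
    x <- vals[i, ]
    if (mean(x) <= 0) NA_real_ else coefficient_of_variation(x)
  }, numeric(1))
  n_nonzero <- rowSums(vals > 0)
  passed_cv <- !is.na(cv) & cv >= cv_min & cv <= cv_max
  passed_nonzero <- n_nonzero >= min_nonzero_samples
  tab <- data.frame(gene = genes, cv = cv, n_nonzero = as.integer(n_nonzero),
                    passed_cv = passed_cv, passed_nonzero = passed_nonzero,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab,
                 candidates = genes[passed_cv & passed_nonzero],
                 controls = data.frame(gene = character(), role = character(),
                                       stringsAsFactors = FALSE)),
            class = "candidate_set")
}

#' Nominate candidate genes from IPL scores and expression filters
#'
#' The full three-filter chain: (1) IPL-outlier nodes via
#' [ipl_outlier_nodes()]; (2) restriction to gene-type nodes; (3) the
#' CV-band and non-zero-expression filters of [expression_filters()].
#' The filters are independent predicates, so their order cannot change
#' the result.
#'
#' @param ipl an `ipl_result`.
#' @param matrix an [expression_matrix()].
#' @param k_sd IPL outlier multiplier.
#' @inheritParams expression_filters
#' @return a `candidate_set`; its `table` additionally records
#'   `passed_ipl`, and slots `nominated_nodes` / `gene_nodes` hold the
#'   intermediate node sets.
#' @export
nominate_candidates <- function(ipl, matrix, k_sd = 2, cv_min = 10,
                                cv_max = 200, min_nonzero_samples = 2L) {
  nominated <- ipl_outlier_nodes(ipl, k_sd)
  gene_nodes <- nominated[nominated %in% ipl$node[ipl$type == "gene"]]
  cs <- expression_filters(gene_nodes, matrix, cv_min, cv_max,
                           min_nonzero_samples)
  cs$table$passed_ipl <- TRUE                # by construction of the chain
  cs$table$ipl <- ipl$ipl[match(cs$table$gene, ipl$node)]
  cs$nominated_nodes <- nominated
  cs$gene_nodes <- gene_nodes
  cs
}

#' Append screening controls to a candidate set
#'
#' Adds the non-targeted negative control, viability positive control(s)
#' and biological control genes with their roles. The candidate list is
#' unchanged; a control that is also a nominated candidate is kept once
#' and dual-flagged via the `also_candidate` column.
#'
#' @param candidates a `candidate_set`.
#' @param negative single negative-control id (e.g. "scramble").
#' @param positive positive viability control ids (e.g. "KIF11").
#' @param biological biological control ids (e.g. "MYC", "AR").
#' @return the augmented `candidate_set`.
#' @export
add_controls <- function(candidates, negative = "scramble",
                         positive = "KIF11", biological = c("MYC", "AR")) {
  stopifnot(inherits(candidates, "candidate_set"))
  if (length(negative) == 0L || length(c(negative, positive, biological)) == 0L)
    input_error("control ids must be non-empty")
  ctrl <- data.frame(
    gene = c(negative, positive, biological),
    role = c(rep("negative", length(negative)),
             rep("positive_viability", length(positive)),
             rep("biological", length(biological))),
    stringsAsFactors = FALSE)
  dup <- ctrl$gene[duplicated(ctrl$gene)]
  if (length(dup) > 0L) {
    conflicting <- unique(ctrl$gene[ctrl$gene %in% dup &
      ave(ctrl$role, ctrl$gene, FUN = function(r) length(unique(r))) > 1])
    if (length(conflicting) > 0L)
      input_error(paste0("conflicting roles for control(s): ",
                         paste(conflicting, collapse = ", ")))
    ctrl <- ctrl[!duplicated(ctrl$gene), , drop = FALSE]
  }
  ctrl$also_candidate <- ctrl$gene %in% candidates$candidates
  candidates$controls <- ctrl
  candidates
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("candidate_set:", length(x$candidates), "candidates")
  if (!is.null(x$nominated_nodes))
    cat(" from", length(x$nominated_nodes), "IPL-outlier nodes (",
        length(x$gene_nodes), "gene nodes )")
  cat(";", nrow(x$controls), "controls\n")
  invisible(x)
}
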