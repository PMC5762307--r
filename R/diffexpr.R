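#' Expression matrix container
#'
#' A validated gene-by-sample matrix of linear-scale abundances with
#' condition and replicate annotations per sample.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids); finite and non-negative.
#' @param condition named character vector mapping sample id to condition
#'   label.
#' @param replicate named integer vector mapping sample id to replicate
#'   index (defaults to 1..k within each condition).
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, condition, replicate = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    input_error("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    input_error("'values' needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    input_error("duplicate gene ids in 'values'")
  if (anyDuplicated(colnames(values)))
    input_error("duplicate sample ids in 'values'")
  if (any(!is.finite(values)) || any(values < 0))
    input_error("'values' must be finite and >= 0")
  samples <- colnames(values)
  if (!all(samples %in% names(condition)))
    input_error("every sample needs a condition annotation")
  condition <- condition[samples]
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(samples), condition, FUN = seq_along)
    names(replicate) <- samples
  }
  replicate <- as.integer(replicate[samples])
  names(replicate) <- samples
  structure(list(values = values,
                 gene_ids = rownames(values),
                 sample_ids = samples,
                 condition = condition,
                 replicate = replicate),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", length(x$gene_ids), "genes x",
      length(x$sample_ids), "samples;",
      paste(sprintf("%s (n=%d)", names(table(x$condition)),
                    table(x$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' Per-gene differential expression between two conditions
#'
#' Two-sided t-test on `log2(value + pseudocount)`, Benjamini-Hochberg
#' correction across genes, and a fold-change gate on the ratio of
#' linear-scale condition means (with the same pseudocount). A gene is
#' significant iff `q < q_threshold` and `max(FC, 1/FC) > fc_threshold`.
#'
#' By default the pooled-variance (Student) test is used: with tiny
#' group sizes (3 vs 3) the Welch approximation collapses to ~2 degrees
#' of freedom whenever the two sample variances differ by chance, and
#' the resulting heavy tails destroy power that the design actually has;
#' on the log2 scale the group variances of abundance data are
#' comparable, which is exactly the pooled test's assumption. Set
#' `var_equal = FALSE` for Welch.
#'
#' Genes with zero variance in both groups get `p = 1` when the group
#' means are equal (no evidence either way, by convention) and `p = 0`
#' when they differ (an exact, noise-free shift). Genes with missing
#' values are excluded and listed in the `"excluded"` attribute.
#'
#' @param matrix an [expression_matrix()].
#' @param cond_a,cond_b condition labels; fold changes are B over A (A is
#'   the comparator, e.g. the parental line).
#' @param q_threshold BH q-value cutoff (default 0.05).
#' @param fc_threshold minimum fold change, either direction (default 2).
#' @param pseudocount added before log2 and to the linear means.
#' @param var_equal pooled-variance Student t (default) or Welch.
#' @return data frame of class `diffexpr_result`: gene, mean_a, mean_b,
#'   log2fc, p_value, q_value, significant.
#' @export
differential_expression <- function(matrix, cond_a = "sensitive",
                                    cond_b = "resistant",
                                    q_threshold = 0.05, fc_threshold = 2,
                                    pseudocount = 1, var_equal = TRUE) {
  stopifnot(inherits(matrix, "expression_matrix"))
  for (cc in c(cond_a, cond_b)) {
    if (sum(matrix$condition == cc) < 2L)
      input_error(sprintf("condition '%s' absent or has < 2 samples", cc))
  }
  a <- matrix$values[, matrix$condition == cond_a, drop = FALSE]
  b <- matrix$values[, matrix$condition == cond_b, drop = FALSE]
  keep <- complete.cases(a) & complete.cases(b)
  excluded <- matrix$gene_ids[!keep]
  if (length(excluded) > 0L) {
    message("differential_expression: excluding ", length(excluded),
            " gene(s) with missing values")
    a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
  }

  la <- log2(a + pseudocount); lb <- log2(b + pseudocount)
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- rowSums((la - ma)^2) / (na - 1L)
  vb <- rowSums((lb - mb)^2) / (nb - 1L)
  if (var_equal) {
    sp2 <- ((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L)
    se2 <- sp2 * (1 / na + 1 / nb)
  } else {
    se2 <- va / na + vb / nb
  }
  diff <- mb - ma
  p <- ifelse(diff == 0, 1, 0)              # zero-variance convention
  pos <- se2 > 0
  tt <- diff[pos] / sqrt(se2[pos])
  df <- if (var_equal) rep(na + nb - 2L, sum(pos)) else
    se2[pos]^2 / (va[pos]^2 / (na^2 * (na - 1L)) +
                  vb[pos]^2 / (nb^2 * (nb - 1L)))
  p[pos] <- 2 * pt(-abs(tt), df)
  q <- bh_adjust(p)

  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  fc <- (mean_b + pseudocount) / (mean_a + pseudocount)
  res <- data.frame(gene = matrix$gene_ids[keep],
                    mean_a = mean_a, mean_b = mean_b,
                    log2fc = log2(fc),
                    p_value = p, q_value = q,
                    significant = q < q_threshold &
                      pmax(fc, 1 / fc) > fc_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "excluded") <- excluded
  attr(res, "conditions") <- c(a = cond_a, b = cond_b)
  class(res) <- c("diffexpr_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i}(p_(j) * n / j)`, capped at 1 and mapped back to
#' the input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    input_error("p-values must lie in [0, 1]")
  n <- length(p_values)
  o <- order(p_values)
  q <- p_values[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Coefficient of variation, in percent
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation, on
#' linear-scale values.
#'
#' @param values numeric vector, length >= 2, positive mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L)
    input_error("CV needs at least 2 values")
  m <- mean(values)
  if (!is.finite(m) || m <= 0)
    abort("CV undefined: mean is not positive", "cv_error")
  100 * sd(values) / m
}
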