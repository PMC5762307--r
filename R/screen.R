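#' Plate-set container for raw screen readings
#'
#' One row per well over all plates, cell lines and replicates. Required
#' columns: plate_id, cell_line, replicate, row, col, content (a gene id,
#' "negative_control", "positive_control" or "empty") and raw_mts
#' (absorbance; NA iff the well is empty).
#'
#' @param wells data frame as above.
#' @return data frame of class `plate_set`.
#' @export
plate_set <- function(wells) {
  need <- c("plate_id", "cell_line", "replicate", "row", "col",
            "content", "raw_mts")
  if (!is.data.frame(wells) || !all(need %in% names(wells)))
    input_error(paste0("'wells' needs columns ",
                       paste(need, collapse = ", ")))
  key <- paste(wells$plate_id, wells$row, wells$col)
  if (anyDuplicated(key)) input_error("duplicate well positions on a plate")
  occ <- wells$content != "empty"
  if (any(is.na(wells$raw_mts[occ])))
    input_error("occupied wells must have raw_mts")
  if (any(wells$raw_mts[occ] <= 0))
    input_error("raw_mts must be > 0")
  if (any(!is.na(wells$raw_mts[!occ])))
    input_error("empty wells must have raw_mts = NA")
  structure(as.data.frame(wells, stringsAsFactors = FALSE),
            class = c("plate_set", "data.frame"))
}

#' Local-regression spatial surface over one plate
#'
#' Loess-style fit of the raw readings on the numeric (row, col)
#' predictors: for each occupied well, a degree-1 weighted least-squares
#' plane over its `ceiling(span * n_occupied)` nearest occupied wells
#' (Euclidean distance in row/col units; neighbour ties broken by well
#' order) with tricube weights `(1 - (d/d_max)^3)^3`. All occupied
#' wells, including controls, participate. If the local design is
#' rank-deficient (e.g. collinear wells) the fit falls back to a global
#' least-squares plane with a warning.
#'
#' @param plate data frame of one plate's wells (see [plate_set()]).
#' @param span neighbourhood fraction in (0, 1].
#' @return numeric vector of fitted values for the occupied wells, in
#'   plate row order, named by `row,col`.
#' @export
fit_spatial_surface <- function(plate, span) {
  if (span <= 0 || span > 1) input_error("'span' must be in (0, 1]")
  occ <- which(plate$content != "empty" & !is.na(plate$raw_mts))
  n <- length(occ)
  if (n < 6L) input_error("need at least 6 occupied wells")
  r <- plate$row[occ]; cc <- plate$col[occ]; y <- plate$raw_mts[occ]
  k <- ceiling(span * n)
  X <- cbind(1, r, cc)

  if (qr(X)$rank < 3L) {
    warning("fit_spatial_surface: degenerate well layout; global linear fit")
    fit <- stats::lm.fit(X, y)
    fitted <- X %*% ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    return(setNames(as.numeric(fitted), paste(r, cc, sep = ",")))
  }

  fitted <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt((r - r[i])^2 + (cc - cc[i])^2)
    nb <- order(d)[seq_len(k)]
    dmax <- max(d[nb])
    w <- if (dmax > 0) (1 - pmin(d[nb] / dmax, 1)^3)^3 else rep(1, k)
    w[nb == i] <- 1                          # the well itself always counts
    Xi <- X[nb, , drop = FALSE]
    if (qr(Xi * sqrt(w))$rank < 3L) {
      fit <- stats::lm.wfit(Xi, y[nb], w)
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    } else {
      beta <- solve(crossprod(Xi, w * Xi), crossprod(Xi, w * y[nb]))
    }
    fitted[i] <- sum(X[i, ] * beta)
  }
  setNames(fitted, paste(r, cc, sep = ","))
}

#' Normalize one plate's readings to control-relative viabilities
#'
#' Two-step normalization: (1) divide each occupied well's raw reading by
#' its fitted spatial-surface value ([fit_spatial_surface()] with
#' `full_span` when every well on the plate is occupied, `partial_span`
#' otherwise), removing smooth row/column artifacts; (2) divide by the
#' median of the plate's negative-control step-1 values — or, when the
#' plate carries no negative-control well, by the plate median of step-1
#' values (`control_basis = "plate_median"`). Wells whose fitted value is
#' not positive are dropped with a message.
#'
#' @param plate one plate's wells (all positions, including empty rows).
#' @param full_span span when all wells are occupied (default 1).
#' @param partial_span span for partially occupied plates (default 0.2).
#' @return data frame: gene, cell_line, replicate, viability, plate_id,
#'   control_basis; one row per gene well.
#' @export
normalize_plate <- function(plate, full_span = 1.0, partial_span = 0.2) {
  span <- if (all(plate$content != "empty")) full_span else partial_span
  fitted <- fit_spatial_surface(plate, span)
  occ <- which(plate$content != "empty" & !is.na(plate$raw_mts))
  bad <- fitted <= 0
  if (any(bad)) {
    message("normalize_plate: dropping ", sum(bad),
            " well(s) with non-positive fitted value on ",
            plate$plate_id[1L])
    occ <- occ[!bad]; fitted <- fitted[!bad]
  }
  step1 <- plate$raw_mts[occ] / fitted
  content <- plate$content[occ]

  neg <- step1[content == "negative_control"]
  if (length(neg) > 0L) {
    basis_value <- median(neg); basis <- "negative_control"
  } else {
    basis_value <- median(step1); basis <- "plate_median"
  }
  is_gene <- !content %in% c("negative_control", "positive_control")
  data.frame(gene = content[is_gene],
             cell_line = plate$cell_line[occ][is_gene],
             replicate = plate$replicate[occ][is_gene],
             viability = step1[is_gene] / basis_value,
             plate_id = plate$plate_id[occ][is_gene],
             control_basis = basis,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Normalize every plate of a screen
#'
#' Applies [normalize_plate()] per plate_id and binds the results.
#'
#' @param plates a [plate_set()].
#' @inheritParams normalize_plate
#' @return data frame of class `normalized_viability`.
#' @export
normalize_screen <- function(plates, full_span = 1.0, partial_span = 0.2) {
  stopifnot(inherits(plates, "plate_set"))
  out <- lapply(split(plates, plates$plate_id), normalize_plate,
                full_span = full_span, partial_span = partial_span)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("normalized_viability", "data.frame")
  res
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact p-value from the null distribution of the rank-sum statistic
#' when the pooled sample size is at most 10 and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction. With 3 vs 3 tie-free observations the smallest achievable
#' two-sided exact p is 0.1 (= 2/choose(6,3)).
#'
#' @param xs,ys numeric vectors, each of length >= 2.
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(xs, ys) {
  if (length(xs) < 2L || length(ys) < 2L)
    input_error("each group needs at least 2 values")
  nx <- length(xs); ny <- length(ys); n <- nx + ny
  pooled <- c(xs, ys)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (n <= 10L && !ties) {
    p <- 2 * min(pwilcox(U, nx, ny), 1 - pwilcox(U - 1, nx, ny))
    return(min(1, p))
  }
  mu <- nx * ny / 2
  tie_tab <- table(pooled)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 == 0) return(1)                 # all values identical
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Call resistance-specific hits from normalized viabilities
#'
#' Per gene, the resistant-line replicate viabilities are compared to the
#' sensitive-line ones with the two-sided Wilcoxon rank-sum test;
#' q-values come from [bh_adjust()] over all tested genes. A gene is a
#' hit iff `q < q_threshold`, its mean resistant viability is at most
#' `1 - kill_threshold` (at least that much cell kill), and the
#' resistant mean is below the sensitive mean (greater kill in the
#' resistant line). Failing genes carry the reasons in `fail_reasons`
#' (semicolon-separated among `q_ge_threshold`, `kill_lt_15pct`,
#' `not_greater_kill`). Genes lacking replicates in either line are
#' excluded with a message.
#'
#' @param nv a `normalized_viability` data frame.
#' @param resistant,sensitive cell-line labels.
#' @param q_threshold BH q cutoff (default 0.2).
#' @param kill_threshold minimum kill fraction in the resistant line
#'   (default 0.15).
#' @return data frame of class `hit_table`: gene,
#'   mean_viability_resistant, mean_viability_sensitive, p_value,
#'   q_value, is_hit, fail_reasons.
#' @export
call_hits <- function(nv, resistant = "MR49F", sensitive = "V16D",
                      q_threshold = 0.2, kill_threshold = 0.15) {
  for (line in c(resistant, sensitive)) {
    if (!line %in% nv$cell_line)
      input_error(sprintf("cell line '%s' absent from viabilities", line))
  }
  genes <- sort(unique(nv$gene))
  ok <- vapply(genes, function(g) {
    sum(nv$gene == g & nv$cell_line == resistant) >= 2L &&
      sum(nv$gene == g & nv$cell_line == sensitive) >= 2L
  }, logical(1))
  if (any(!ok))
    message("call_hits: excluding ", sum(!ok),
            " gene(s) without replicates in both cell lines")
  genes <- genes[ok]

  stats_ <- t(vapply(genes, function(g) {
    xs <- nv$viability[nv$gene == g & nv$cell_line == resistant]
    ys <- nv$viability[nv$gene == g & nv$cell_line == sensitive]
    c(mean(xs), mean(ys), wilcoxon_rank_sum(xs, ys))
  }, numeric(3)))
  q <- bh_adjust(stats_[, 3L])

  reasons <- vapply(seq_along(genes), function(i) {
    r <- character()
    if (q[i] >= q_threshold) r <- c(r, "q_ge_threshold")
    if (stats_[i, 1L] > 1 - kill_threshold) r <- c(r, "kill_lt_15pct")
    if (stats_[i, 1L] >= stats_[i, 2L]) r <- c(r, "not_greater_kill")
    paste(r, collapse = ";")
  }, character(1))

  res <- data.frame(gene = genes,
                    mean_viability_resistant = stats_[, 1L],
                    mean_viability_sensitive = stats_[, 2L],
                    p_value = stats_[, 3L], q_value = q,
                    is_hit = reasons == "",
                    fail_reasons = reasons,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("hit_table", "data.frame")
  res
}
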