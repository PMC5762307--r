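## Shared fixture builders and independent oracles.

## quick expression_matrix: one row per gene, columns a1..ak, b1..bk
make_matrix <- function(a, b, gene_ids = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%02d", seq_len(n))
  values <- cbind(a, b)
  rownames(values) <- gene_ids
  colnames(values) <- c(paste0("A", seq_len(ncol(a))), paste0("B", seq_len(ncol(b))))
  cond <- setNames(rep(c("condA", "condB"), c(ncol(a), ncol(b))), colnames(values))
  expression_matrix(values, cond)
}

## small graphs by explicit edge list: edges as data.frame(source, target, sign)
make_graph <- function(ids, edges = NULL, types = NULL) {
  nodes <- data.frame(id = ids,
                      type = types %||% rep("gene", length(ids)),
                      stringsAsFactors = FALSE)
  if (!is.null(edges)) edges$kind <- edges$kind %||% "other"
  pathway_graph(nodes, edges)
}

obs_for <- function(ids, z, c_cn = NA_real_) {
  data.frame(node = ids, z_expr = z, c_cn = c_cn, stringsAsFactors = FALSE)
}

## one fully-occupied plate with given well values (matrix rows x cols);
## controls placed like the generator's layout
make_plate <- function(values, cell_line = "MR49F", replicate = 1L,
                       plate_id = "P1", with_neg_control = TRUE) {
  nr <- nrow(values); nc <- ncol(values)
  grid <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  grid <- grid[order(grid$row, grid$col), ]
  content <- sprintf("G%03d", seq_len(nr * nc))
  if (with_neg_control) {
    content[grid$row == 1 & grid$col == 1] <- "negative_control"
    content[grid$row == nr & grid$col == nc] <- "negative_control"
  }
  data.frame(plate_id = plate_id, cell_line = cell_line,
             replicate = replicate, row = grid$row, col = grid$col,
             content = content,
             raw_mts = values[cbind(grid$row, grid$col)],
             stringsAsFactors = FALSE)
}

## independent exact Wilcoxon oracle: enumerate every assignment of the
## pooled ranks to group x
wilcox_enum <- function(xs, ys) {
  nx <- length(xs); n <- nx + length(ys)
  rk <- rank(c(xs, ys))
  w_obs <- sum(rk[seq_len(nx)])
  splits <- utils::combn(n, nx)
  ws <- apply(splits, 2, function(i) sum(seq_len(n)[i]))
  mu <- nx * (n + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu))
}

## deterministic per-test seeds
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
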