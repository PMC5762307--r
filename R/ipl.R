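#' Signed pathway graph container
#'
#' Typed nodes (`gene`, `complex`, `family`, `abstract`) and signed,
#' typed directed edges, as exported from curated interaction files.
#'
#' @param nodes data frame with columns `id`, `type`.
#' @param edges data frame with columns `source`, `target`, `sign`
#'   (+1/-1), `kind` (`transcriptional`, `component`, `member`, `other`),
#'   or NULL for an edgeless graph.
#' @return object of class `pathway_graph`.
#' @export
pathway_graph <- function(nodes, edges = NULL) {
  if (!is.data.frame(nodes) || !all(c("id", "type") %in% names(nodes)))
    input_error("'nodes' needs columns id, type")
  if (anyDuplicated(nodes$id)) input_error("duplicate node ids")
  if (!is.null(edges) && nrow(edges) > 0L) {
    if (!all(c("source", "target", "sign", "kind") %in% names(edges)))
      input_error("'edges' needs columns source, target, sign, kind")
    missing <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(missing) > 0L)
      input_error(paste0("edge endpoints not in node set: ",
                         paste(head(missing, 5L), collapse = ", ")))
    if (any(edges$source == edges$target))
      input_error("self-loops are not allowed")
    if (!all(edges$sign %in% c(-1L, 1L)))
      input_error("edge sign must be +1 or -1")
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    edges <- edges[, c("source", "target", "sign", "kind")]
    edges$sign <- as.integer(edges$sign)
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(source = character(), target = character(),
                        sign = integer(), kind = character(),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = as.data.frame(nodes, stringsAsFactors = FALSE),
                 edges = edges),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("pathway_graph:", nrow(x$nodes), "nodes (",
      sum(x$nodes$type == "gene"), "gene ),", nrow(x$edges), "edges (",
      sum(x$edges$sign < 0), "inhibitory )\n")
  invisible(x)
}

#' IPL model parameters
#'
#' @param beta_expr coupling weight of the expression z-score evidence.
#' @param beta_cn coupling weight of the copy-number evidence.
#' @param lambda_edge neighbour-coupling strength; 0 decouples the graph.
#' @param max_iter maximum sweeps of message passing.
#' @param damping message damping in \[0, 1); new message =
#'   `(1 - damping) * computed + damping * old`.
#' @param tol convergence tolerance on the max message change.
#' @return object of class `ipl_params`.
#' @export
ipl_params <- function(beta_expr = 1, beta_cn = 1, lambda_edge = 0.5,
                       max_iter = 500L, damping = 0.5, tol = 1e-8) {
  if (beta_expr < 0 || beta_cn < 0 || lambda_edge < 0)
    config_error("coupling weights must be >= 0")
  if (damping < 0 || damping >= 1) config_error("'damping' must be in [0, 1)")
  if (tol <= 0) config_error("'tol' must be > 0")
  structure(list(beta_expr = beta_expr, beta_cn = beta_cn,
                 lambda_edge = lambda_edge,
                 max_iter = check_count(max_iter, "max_iter"),
                 damping = damping, tol = tol),
            class = "ipl_params")
}

#' Build node observations from expression and copy-number results
#'
#' The per-gene expression differential `log2(mean_b + pc) - log2(mean_a
#' + pc)` (i.e. the `log2fc` of [differential_expression()]) is
#' standardized by its robust scale — the median absolute deviation
#' scaled by 1.4826 — across all genes matched to gene-type graph nodes,
#' giving `z_expr`. Gene-level copy-number log2 ratios pass through
#' unstandardized as `c_cn`. Non-gene nodes and genes absent from the
#' data carry no observation.
#'
#' @param de a `diffexpr_result` from [differential_expression()].
#' @param cn optional `gene_cn` from [gene_level_log_ratio()].
#' @param graph a [pathway_graph()].
#' @return data frame: node, z_expr, c_cn (NA where absent).
#' @export
build_observations <- function(de, cn = NULL, graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  gene_nodes <- graph$nodes$id[graph$nodes$type == "gene"]
  matched <- intersect(gene_nodes, de$gene)
  if (length(matched) == 0L)
    input_error("no overlap between graph gene nodes and expression genes")
  unmatched <- setdiff(de$gene, gene_nodes)
  if (length(unmatched) > 0L)
    message("build_observations: ", length(unmatched),
            " expression gene(s) not in the graph")
  d <- de$log2fc[match(matched, de$gene)]
  scale <- mad(d)                            # 1.4826 * MAD, centred at median
  z <- if (scale > 0) d / scale else d
  obs <- data.frame(node = matched, z_expr = z, c_cn = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(cn) && nrow(cn) > 0L) {
    hit <- match(obs$node, cn$gene_id)
    obs$c_cn <- cn$log2_ratio[hit]
    extra <- setdiff(intersect(cn$gene_id, gene_nodes), obs$node)
    if (length(extra) > 0L)
      obs <- rbind(obs, data.frame(node = extra, z_expr = NA_real_,
                                   c_cn = cn$log2_ratio[match(extra, cn$gene_id)],
                                   stringsAsFactors = FALSE))
  }
  obs
}

## Node evidence fields h_n = beta_expr * z + beta_cn * c (missing -> 0),
## in graph node order.
node_fields <- function(graph, obs, params) {
  h <- setNames(numeric(nrow(graph$nodes)), graph$nodes$id)
  if (!is.null(obs) && nrow(obs) > 0L) {
    bad <- setdiff(obs$node, graph$nodes$id)
    if (length(bad) > 0L)
      input_error(paste0("observations for unknown nodes: ",
                         paste(head(bad, 5L), collapse = ", ")))
    z <- ifelse(is.na(obs$z_expr), 0, obs$z_expr)
    cc <- ifelse(is.na(obs$c_cn), 0, obs$c_cn)
    h[obs$node] <- params$beta_expr * z + params$beta_cn * cc
  }
  h
}

#' Integrated pathway level scores by sum-product message passing
#'
#' Defines a pairwise factor model over ternary node states
#' `S in {-1, 0, +1}` (down, neutral, up): node evidence factor
#' `phi(S) = exp(S * (beta_expr * z + beta_cn * c))` (missing evidence
#' contributes 0, i.e. a uniform factor), and for every edge the coupling
#' `psi(S_u, S_v) = exp(lambda_edge * sign * S_u * S_v)`. Marginal
#' beliefs are computed by damped sum-product (loopy) belief propagation;
#' messages are swept in a fixed order (edges sorted by source then
#' target id, forward then reverse direction) until the largest message
#' change falls below `tol` or `max_iter` sweeps elapse. Exact on trees;
#' the usual loopy approximation elsewhere. The integrated pathway level
#' is `ipl = log10(belief(+1) / belief(-1))`, so a node's score reflects
#' both its own data and its neighbours' states.
#'
#' @param graph a [pathway_graph()].
#' @param obs observations from [build_observations()] (or NULL).
#' @param params an [ipl_params()].
#' @return data frame of class `ipl_result`: node, type, ipl, belief_down,
#'   belief_neutral, belief_up; attributes `converged`, `n_iter`.
#' @export
infer_ipl <- function(graph, obs = NULL, params = ipl_params()) {
  stopifnot(inherits(graph, "pathway_graph"), inherits(params, "ipl_params"))
  if (nrow(graph$nodes) == 0L) input_error("empty graph")
  states <- c(-1, 0, 1)
  h <- node_fields(graph, obs, params)
  n <- length(h)
  phi <- exp(outer(h, states))               # n x 3
  ids <- graph$nodes$id

  E <- graph$edges
  if (nrow(E) == 0L) {
    bel <- phi / rowSums(phi)
    return(ipl_result(graph, bel, TRUE, 0L))
  }
  eo <- order(E$source, E$target)
  E <- E[eo, ]
  u <- match(E$source, ids); v <- match(E$target, ids)
  m <- nrow(E)
  ## psi[s_u, s_v] per edge
  psi <- lapply(seq_len(m), function(e)
    exp(params$lambda_edge * E$sign[e] * outer(states, states)))

  ## directed messages: 1..m are u->v, m+1..2m are v->u; msg[d, ] over states
  msg <- matrix(1 / 3, 2L * m, 3L)
  from <- c(u, v); to <- c(v, u)
  rev_dir <- c(m + seq_len(m), seq_len(m))   # opposite direction of each
  inc <- split(seq_len(2L * m), to)          # incoming message dirs per node

  converged <- FALSE; it <- 0L
  for (it in seq_len(params$max_iter)) {
    delta <- 0
    for (d in seq_len(2L * m)) {
      e <- if (d <= m) d else d - m
      src <- from[d]
      ## product of phi(src) and messages into src except the reverse one
      prod_in <- phi[src, ]
      for (dd in inc[[as.character(src)]] %||% integer()) {
        if (dd != rev_dir[d]) prod_in <- prod_in * msg[dd, ]
      }
      P <- if (d <= m) psi[[e]] else t(psi[[e]])
      new <- as.numeric(prod_in %*% P)
      new <- new / sum(new)
      new <- (1 - params$damping) * new + params$damping * msg[d, ]
      delta <- max(delta, max(abs(new - msg[d, ])))
      msg[d, ] <- new
    }
    if (delta < params$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("infer_ipl: message passing did not converge in ",
            params$max_iter, " iterations")

  bel <- phi
  for (node in seq_len(n)) {
    for (dd in inc[[as.character(node)]] %||% integer())
      bel[node, ] <- bel[node, ] * msg[dd, ]
    bel[node, ] <- bel[node, ] / sum(bel[node, ])
  }
  ipl_result(graph, bel, converged, it)
}

ipl_result <- function(graph, beliefs, converged, n_iter) {
  res <- data.frame(node = graph$nodes$id, type = graph$nodes$type,
                    ipl = log10(beliefs[, 3L] / beliefs[, 1L]),
                    belief_down = beliefs[, 1L],
                    belief_neutral = beliefs[, 2L],
                    belief_up = beliefs[, 3L],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "converged") <- converged
  attr(res, "n_iter") <- n_iter
  class(res) <- c("ipl_result", "data.frame")
  res
}

#' Exact IPL scores by exhaustive enumeration
#'
#' Sums the unnormalized joint `exp(sum_n h_n S_n + sum_e lambda * sign_e
#' * S_u S_v)` over all `3^n` joint states to obtain exact marginals;
#' same score definition as [infer_ipl()]. Test oracle for small graphs.
#'
#' @inheritParams infer_ipl
#' @return an `ipl_result` data frame.
#' @export
exact_ipl <- function(graph, obs = NULL, params = ipl_params()) {
  stopifnot(inherits(graph, "pathway_graph"))
  n <- nrow(graph$nodes)
  if (n == 0L) input_error("empty graph")
  if (n > 12L) size_error("exact_ipl supports at most 12 nodes")
  states <- c(-1, 0, 1)
  h <- node_fields(graph, obs, params)
  ids <- graph$nodes$id

  S <- as.matrix(expand.grid(rep(list(states), n)))  # 3^n x n
  logw <- as.numeric(S %*% h)
  if (nrow(graph$edges) > 0L) {
    u <- match(graph$edges$source, ids); v <- match(graph$edges$target, ids)
    for (e in seq_along(u))
      logw <- logw + params$lambda_edge * graph$edges$sign[e] * S[, u[e]] * S[, v[e]]
  }
  w <- exp(logw - max(logw))
  bel <- sapply(seq_len(3L), function(s)
    colSums(w * (S == states[s])))           # n x 3 (column per state)
  bel <- matrix(bel, nrow = n)
  bel <- bel / rowSums(bel)
  ipl_result(graph, bel, TRUE, 0L)
}

#' First-neighbour subnetwork around seed nodes
#'
#' Induced subgraph on the seeds plus every node adjacent to a seed in
#' either direction; node and edge attributes are preserved.
#'
#' @param graph a [pathway_graph()].
#' @param seeds character vector of node ids.
#' @return a [pathway_graph()].
#' @export
first_neighbor_subnetwork <- function(graph, seeds) {
  stopifnot(inherits(graph, "pathway_graph"))
  unknown <- setdiff(seeds, graph$nodes$id)
  if (length(unknown) > 0L)
    input_error(paste0("unknown seed node(s): ",
                       paste(unknown, collapse = ", ")))
  E <- graph$edges
  nb <- c(E$target[E$source %in% seeds], E$source[E$target %in% seeds])
  keep <- union(seeds, nb)
  nodes <- graph$nodes[graph$nodes$id %in% keep, , drop = FALSE]
  edges <- E[E$source %in% keep & E$target %in% keep, , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  pathway_graph(nodes, edges)
}
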