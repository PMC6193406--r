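#' Weighted PageRank on a connected component
#'
#' Power iteration with uniform teleportation: `v <- (1 - d)/n + d * M v`,
#' where `M` is the column-stochastic transition matrix of the weighted walk
#' on the component's induced subgraph. Used to label modules by their most
#' central gene; the map-equation codelength itself uses the teleport-free
#' stationary distribution ([visit_rates()]).
#'
#' @param net A [gene_network()].
#' @param component Character vector: one connected component.
#' @param damping Damping factor in (0,1); default 0.85.
#' @param tol L1 convergence tolerance; default 1e-10.
#' @return Named numeric vector of scores summing to 1.
#' @export
pagerank <- function(net, component, damping = 0.85, tol = 1e-10) {
  if (!(damping > 0 && damping < 1)) stop("damping must be in (0,1)")
  nodes <- sort(component)
  n <- length(nodes)
  if (n == 1) return(setNames(1, nodes))
  e <- induced_edges(net, nodes)
  if (!is_connected_set(e, nodes)) stop("component is not connected")
  ia <- match(e$gene_a, nodes)
  ib <- match(e$gene_b, nodes)
  s <- numeric(n)
  for (k in seq_along(ia)) {
    s[ia[k]] <- s[ia[k]] + e$mi[k]
    s[ib[k]] <- s[ib[k]] + e$mi[k]
  }
  v <- rep(1 / n, n)
  for (iter in seq_len(10000)) {
    out <- v / s
    v2 <- numeric(n)
    for (k in seq_along(ia)) {
      v2[ib[k]] <- v2[ib[k]] + e$mi[k] * out[ia[k]]
      v2[ia[k]] <- v2[ia[k]] + e$mi[k] * out[ib[k]]
    }
    v2 <- (1 - damping) / n + damping * v2
    if (sum(abs(v2 - v)) < tol) {
      return(setNames(v2 / sum(v2), nodes))
    }
    v <- v2
  }
  stop("PageRank did not converge in 10000 iterations")
}

#' Label every module of a tree by its highest-PageRank gene
#'
#' @param tree A `module_tree`.
#' @param scores Named scores covering all tree genes (see [pagerank()]).
#'   Ties are broken lexicographically.
#' @return The tree with `$label` set on every node (including the root).
#' @export
label_modules <- function(tree, scores) {
  missing <- setdiff(tree$genes, names(scores))
  if (length(missing)) {
    stop("no score for gene(s): ", paste(head(missing), collapse = ", "))
  }
  walk <- function(node) {
    g <- node$genes
    node$label <- g[order(-scores[g], g)][1]
    if (!is.null(node$children)) node$children <- lapply(node$children, walk)
    node
  }
  walk(tree)
}
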