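#' Undirected weighted gene network
#'
#' A thin container around an edge list: nodes are genes, edge weights are MI
#' values. Symmetric by construction, self-loops are rejected.
#'
#' @param edges `data.frame` with columns `gene_a`, `gene_b`, `mi` (weights
#'   `> 0`).
#' @param nodes Optional character vector of node ids (defaults to all genes
#'   appearing in `edges`; extra isolated nodes are allowed).
#' @return Object of class `gene_network` with elements `nodes` and `edges`.
#' @export
gene_network <- function(edges, nodes = NULL) {
  stopifnot(all(c("gene_a", "gene_b", "mi") %in% names(edges)))
  if (any(edges$gene_a == edges$gene_b)) stop("self-loops are not allowed")
  if (any(edges$mi <= 0)) stop("edge weights must be > 0")
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  if (anyDuplicated(paste0(a, "\r", b))) stop("duplicate edges")
  edges <- data.frame(gene_a = a, gene_b = b, mi = edges$mi,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(nodes, edges$gene_a, edges$gene_b)))
  structure(list(nodes = nodes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Connected components of a gene network
#'
#' The first level of modularity: components are returned sorted by size
#' (descending), ties broken by smallest member id; members are sorted.
#'
#' @param net A [gene_network()].
#' @return List of character vectors (class `component_list`), disjoint and
#'   covering all network nodes.
#' @export
connected_components <- function(net) {
  if (nrow(net$edges) == 0) {
    comps <- as.list(sort(net$nodes))
  } else {
    g <- igraph::graph_from_data_frame(
      net$edges[, c("gene_a", "gene_b")], directed = FALSE,
      vertices = data.frame(name = net$nodes)
    )
    mem <- igraph::components(g)$membership
    comps <- split(names(mem), mem)
    comps <- lapply(comps, function(v) sort(unname(v)))
  }
  first <- vapply(comps, `[`, "", 1L)
  ord <- order(-lengths(comps), first)
  structure(unname(comps[ord]), class = "component_list")
}

# Induced-subgraph edge set for a node set.
induced_edges <- function(net, nodes) {
  e <- net$edges
  e[e$gene_a %in% nodes & e$gene_b %in% nodes, , drop = FALSE]
}

#' Stationary visit rates of the random walk on a component
#'
#' On an undirected network the walker's stationary distribution is
#' strength-proportional: `p_i = s_i / (2W)` with `s_i` the sum of incident
#' edge weights and `W` the total edge weight of the component's induced
#' subgraph.
#'
#' @param net A [gene_network()].
#' @param component Character vector of node ids forming one connected
#'   component.
#' @return Named numeric vector summing to 1.
#' @export
visit_rates <- function(net, component) {
  e <- induced_edges(net, component)
  if (length(component) == 1) {
    return(setNames(1, component))
  }
  s <- setNames(numeric(length(component)), sort(component))
  for (col in c("gene_a", "gene_b")) {
    agg <- tapply(e$mi, e[[col]], sum)
    s[names(agg)] <- s[names(agg)] + agg
  }
  if (any(s == 0)) stop("component is not connected (isolated node)")
  p <- s / (2 * sum(e$mi))
  if (!isTRUE(all.equal(unname(sum(p)), 1, tolerance = 1e-12))) {
    stop("visit rates do not sum to 1")   # defensive; algebraically impossible
  }
  # connectivity check (strength > 0 is necessary, not sufficient)
  if (!is_connected_set(e, names(s))) stop("component is not connected")
  p
}

is_connected_set <- function(edges, nodes) {
  if (length(nodes) <= 1) return(TRUE)
  if (nrow(edges) == 0) return(FALSE)
  idx <- setNames(seq_along(nodes), nodes)
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(edges))) {
    a <- find(idx[[edges$gene_a[r]]]); b <- find(idx[[edges$gene_b[r]]])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_along(nodes), find, 0L))) == 1
}
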