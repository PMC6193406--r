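# ---------------------------------------------------------------------------
# Map-equation machinery.
#
# All flows are expressed relative to the component's total weight: an edge of
# weight w carries flow w / 2W in each direction, a node's visit rate is
# s_i / 2W, and a module's exit rate q_m is its boundary weight / 2W. The
# two-level codelength then decomposes as
#
#   L(M) = plogp(q) - 2 sum_m plogp(q_m) + sum_m plogp(q_m + P_m)
#          - sum_i plogp(p_i),                       q = sum_m q_m,
#
# with plogp(x) = x log2 x. The last term does not depend on the partition,
# so the optimizer works on the first three ("structural") terms; this also
# makes the objective exact on aggregated graphs, where node "visit rates" P
# and node external flows x diverge. The hierarchical codelength replaces a
# leaf module's codebook by an index codebook over its children's enter rates
# plus the children's own codebooks, recursively.
# ---------------------------------------------------------------------------

# Internal flow graph: nodes 1..n with rate mass P, external flow x, and an
# undirected edge list (i, j, f) in flow units. At the base level P == x ==
# visit rates; after aggregation P is the contained rate mass and x the
# module exit rate.
me_graph <- function(P, x, ei, ej, f) {
  n <- length(P)
  adj_n <- vector("list", n)
  if (length(ei)) {
    ii <- c(ei, ej); jj <- c(ej, ei); ff <- c(f, f)
    o <- order(ii)
    ii <- ii[o]; jj <- jj[o]; ff <- ff[o]
    breaks <- c(which(diff(ii) > 0), length(ii))
    start <- c(1L, head(breaks, -1L) + 1L)
    for (b in seq_along(breaks)) {
      node <- ii[start[b]]
      idx <- start[b]:breaks[b]
      adj_n[[node]] <- list(nbr = jj[idx], f = ff[idx])
    }
  }
  list(n = n, P = P, x = x, ei = ei, ej = ej, f = f, adj = adj_n)
}

# Base-level flow graph of one connected component; nodes are the sorted
# component genes.
me_base_graph <- function(net, component) {
  nodes <- sort(component)
  e <- induced_edges(net, nodes)
  n <- length(nodes)
  if (n > 1 && !is_connected_set(e, nodes)) stop("component is not connected")
  W2 <- 2 * sum(e$mi)
  ei <- match(e$gene_a, nodes)
  ej <- match(e$gene_b, nodes)
  f <- if (n == 1) numeric(0) else e$mi / W2
  s <- numeric(n)
  for (k in seq_along(ei)) {
    s[ei[k]] <- s[ei[k]] + f[k]
    s[ej[k]] <- s[ej[k]] + f[k]
  }
  p <- if (n == 1) 1 else s
  g <- me_graph(P = p, x = p, ei = ei, ej = ej, f = f)
  g$nodes <- nodes
  g
}

# Structural two-level codelength of a membership vector (full codelength
# minus the partition-independent -sum plogp(p_i) term).
me_Lstruct <- function(g, m) {
  mc <- match(m, sort(unique(m)))
  k <- max(mc)
  Pm <- as.numeric(rowsum(g$P, mc))
  Xm <- as.numeric(rowsum(g$x, mc))
  intm <- numeric(k)
  if (length(g$ei)) {
    same <- mc[g$ei] == mc[g$ej]
    if (any(same)) {
      agg <- rowsum(g$f[same], mc[g$ei][same])
      intm[as.integer(rownames(agg))] <- agg
    }
  }
  q <- pmax(0, Xm - 2 * intm)
  sum(plogp(sum(q))) - 2 * sum(plogp(q)) + sum(plogp(q + Pm))
}

# One round of greedy node moves (repeated sweeps in random order until no
# move lowers the codelength). Returns the improved membership.
me_local_move <- function(g, m, seed) {
  n <- g$n
  mc <- match(m, unique(m))
  Pm <- numeric(n); Xm <- numeric(n); intm <- numeric(n); sizes <- integer(n)
  for (i in seq_len(n)) {
    Pm[mc[i]] <- Pm[mc[i]] + g$P[i]
    Xm[mc[i]] <- Xm[mc[i]] + g$x[i]
    sizes[mc[i]] <- sizes[mc[i]] + 1L
  }
  if (length(g$ei)) {
    same <- mc[g$ei] == mc[g$ej]
    for (k in which(same)) intm[mc[g$ei][k]] <- intm[mc[g$ei][k]] + g$f[k]
  }
  q <- pmax(0, Xm - 2 * intm)
  qtot <- sum(q)

  with_seed(seed, {
    repeat {
      moved <- FALSE
      for (i in sample.int(n)) {
        a <- mc[i]
        nb <- g$adj[[i]]
        if (is.null(nb)) next
        nbr_mods <- mc[nb$nbr]
        fm <- rowsum(nb$f, nbr_mods)
        mods <- as.integer(rownames(fm))
        f_ia <- if (a %in% mods) fm[match(a, mods), 1L] else 0
        cand <- sort(mods[mods != a])
        if (sizes[a] > 1L) {
          free <- which(sizes == 0L)[1L]        # leaving into a new module
          if (!is.na(free)) cand <- c(cand, free)
        }
        if (length(cand) == 0) next
        qa2 <- max(0, q[a] - g$x[i] + 2 * f_ia)
        base_a <- -2 * plogp(q[a]) + plogp(q[a] + Pm[a])
        best_d <- -1e-13; best_b <- 0L; best_fib <- 0; best_qb2 <- 0
        for (b in cand) {
          f_ib <- if (b %in% mods) fm[match(b, mods), 1L] else 0
          qb2 <- max(0, q[b] + g$x[i] - 2 * f_ib)
          qtot2 <- qtot + (qa2 - q[a]) + (qb2 - q[b])
          d <- (plogp(qtot2) - plogp(qtot)) +
            (-2 * plogp(qa2) + plogp(qa2 + Pm[a] - g$P[i])) - base_a +
            (-2 * plogp(qb2) + plogp(qb2 + Pm[b] + g$P[i])) -
            (-2 * plogp(q[b]) + plogp(q[b] + Pm[b]))
          if (d < best_d) {
            best_d <- d; best_b <- b; best_fib <- f_ib; best_qb2 <- qb2
          }
        }
        if (best_b > 0L) {
          b <- best_b
          qtot <- qtot + (qa2 - q[a]) + (best_qb2 - q[b])
          q[a] <- qa2; q[b] <- best_qb2
          Pm[a] <- Pm[a] - g$P[i]; Pm[b] <- Pm[b] + g$P[i]
          Xm[a] <- Xm[a] - g$x[i]; Xm[b] <- Xm[b] + g$x[i]
          sizes[a] <- sizes[a] - 1L; sizes[b] <- sizes[b] + 1L
          mc[i] <- b
          moved <- TRUE
        }
      }
      if (!moved) break
    }
  })
  mc
}

# Aggregate a membership into a module-level flow graph.
me_aggregate <- function(g, mc) {
  mc <- match(mc, sort(unique(mc)))
  k <- max(mc)
  P2 <- as.numeric(rowsum(g$P, mc))
  X2 <- as.numeric(rowsum(g$x, mc))
  int2 <- numeric(k)
  ei2 <- integer(0); ej2 <- integer(0); f2 <- numeric(0)
  if (length(g$ei)) {
    a <- mc[g$ei]; b <- mc[g$ej]
    same <- a == b
    if (any(same)) {
      agg <- rowsum(g$f[same], a[same])
      int2[as.integer(rownames(agg))] <- agg
    }
    if (any(!same)) {
      lo <- pmin(a[!same], b[!same]); hi <- pmax(a[!same], b[!same])
      key <- (lo - 1) * k + hi
      agg <- rowsum(g$f[!same], key)
      key2 <- as.numeric(rownames(agg))
      ei2 <- as.integer((key2 - 1) %/% k + 1)
      ej2 <- as.integer((key2 - 1) %% k + 1)
      f2 <- as.numeric(agg)
    }
  }
  g2 <- me_graph(P = P2, x = pmax(0, X2 - 2 * int2), ei = ei2, ej = ej2, f = f2)
  g2
}

# Full two-level search: seeded restarts of (local move, aggregate, local
# move, ...) Louvain-style cycles; returns the best membership found and its
# structural codelength. Never returns a partition worse than one module.
me_optimize <- function(g, trials = 10, seed = 1) {
  best_m <- rep(1L, g$n)
  best_L <- 0          # structural codelength of the one-module partition
  if (g$n == 1) return(list(membership = best_m, Lstruct = 0))
  for (t in seq_len(trials)) {
    m <- seq_len(g$n)
    sweep_seed <- derive_seed(seed, 100 + t)
    m <- me_local_move(g, m, sweep_seed)
    repeat {
      mc <- match(m, unique(m))
      if (max(mc) == 1L) break
      g2 <- me_aggregate(g, mc)
      m2 <- me_local_move(g2, seq_len(g2$n), derive_seed(sweep_seed, 7))
      if (length(unique(m2)) == g2$n) break
      m <- match(m2, unique(m2))[mc]
      m <- me_local_move(g, m, derive_seed(sweep_seed, 13))
    }
    L <- me_Lstruct(g, m)
    if (L < best_L - 1e-12) {
      best_L <- L
      best_m <- match(m, unique(m))
    }
  }
  list(membership = best_m, Lstruct = best_L)
}

# External flow (exit rate) and rate mass of a gene-index set in a base graph.
me_set_q <- function(g, idx) {
  inset <- logical(g$n); inset[idx] <- TRUE
  x <- sum(g$x[idx])
  if (length(g$ei)) {
    internal <- inset[g$ei] & inset[g$ej]
    x <- x - 2 * sum(g$f[internal])
  }
  max(0, x)
}

#' Hierarchical map-equation codelength of a module tree
#'
#' Evaluates the (hierarchical) map equation for an arbitrary nested
#' partition of one connected component, in bits. A depth-1 tree reproduces
#' the two-level codelength. The root index codebook covers its children's
#' enter rates; an internal module's codebook covers its own exit rate plus
#' its children's enter rates; a leaf module's codebook covers its exit rate
#' plus its member genes' visit rates.
#'
#' @param net A [gene_network()].
#' @param tree A `module_tree` partitioning one connected component of `net`.
#' @return Codelength in bits (`>= 0`).
#' @examples
#' net <- gene_network(data.frame(gene_a = c("a", "b", "c", "d"),
#'                                gene_b = c("b", "c", "d", "a"), mi = 1))
#' tr <- optimize_two_level(net, net$nodes)
#' codelength(net, tr)   # 2 bits: a 4-cycle in one module
#' @export
codelength <- function(net, tree) {
  validate_module_tree(tree)
  g <- me_base_graph(net, tree$genes)
  idx_of <- setNames(seq_along(g$nodes), g$nodes)
  total <- 0
  walk <- function(node, is_root) {
    idx <- idx_of[node$genes]
    q_m <- if (is_root) 0 else me_set_q(g, idx)
    if (is.null(node$children)) {
      P_m <- sum(g$P[idx])
      total <<- total + plogp(q_m + P_m) - plogp(q_m) - sum(plogp(g$P[idx]))
    } else {
      q_kids <- vapply(node$children, function(ch) me_set_q(g, idx_of[ch$genes]), 0)
      tot <- q_m + sum(q_kids)
      total <<- total + plogp(tot) - plogp(q_m) - sum(plogp(q_kids))
      for (ch in node$children) walk(ch, FALSE)
    }
  }
  walk(tree, TRUE)
  total
}

# Build a depth-1 module_tree from a membership vector over g$nodes; children
# ordered by decreasing rate mass (ties: smallest gene id).
tree_from_membership <- function(g, mc) {
  mods <- split(seq_len(g$n), mc)
  mass <- vapply(mods, function(idx) sum(g$P[idx]), 0)
  first <- vapply(mods, function(idx) min(g$nodes[idx]), "")
  mods <- mods[order(-mass, first)]
  kids <- lapply(mods, function(idx) new_module_node(g$nodes[idx]))
  root <- new_module_node(g$nodes, children = unname(kids), path = "root")
  class(root) <- c("module_tree", class(root))
  assign_paths(root)
}

#' Two-level map-equation partition of a connected component
#'
#' Greedy node-aggregation search (Louvain-style: repeated sweeps of
#' single-node moves interleaved with module aggregation) for the partition
#' minimizing the two-level map equation, restarted `trials` times with
#' seeded random sweep orders. The best trial is returned; the result is
#' never worse than the one-module partition.
#'
#' @param net A [gene_network()].
#' @param component Character vector: one connected component of `net`.
#' @param trials Number of seeded restarts (>= 1).
#' @param seed Integer seed; identical inputs give identical trees.
#' @return A depth-1 `module_tree` with the total codelength (bits) in
#'   `$codelength`.
#' @export
optimize_two_level <- function(net, component, trials = 10, seed = 1) {
  if (length(component) == 0) stop("empty component")
  stopifnot(trials >= 1)
  g <- me_base_graph(net, component)
  opt <- me_optimize(g, trials = trials, seed = seed)
  tree <- tree_from_membership(g, opt$membership)
  tree$codelength <- opt$Lstruct - sum(plogp(g$P))
  store_node_codelengths(tree, g)
}

# Per-node codebook contributions (bits), stored on each node; the root keeps
# the tree's total codelength (its own index contribution goes to
# `codelength_index`).
store_node_codelengths <- function(tree, g) {
  idx_of <- setNames(seq_along(g$nodes), g$nodes)
  walk <- function(node, is_root) {
    idx <- idx_of[node$genes]
    q_m <- if (is_root) 0 else me_set_q(g, idx)
    if (is.null(node$children)) {
      node$codelength <-
        plogp(q_m + sum(g$P[idx])) - plogp(q_m) - sum(plogp(g$P[idx]))
    } else {
      q_kids <- vapply(node$children, function(ch) me_set_q(g, idx_of[ch$genes]), 0)
      contrib <- plogp(q_m + sum(q_kids)) - plogp(q_m) - sum(plogp(q_kids))
      if (is_root) node$codelength_index <- contrib
      else node$codelength <- contrib
      node$children <- lapply(node$children, walk, is_root = FALSE)
    }
    node
  }
  total <- tree$codelength
  tree <- walk(tree, TRUE)
  tree$codelength <- total
  tree
}

#' Hierarchical map-equation decomposition of a connected component
#'
#' Finds the minimum-codelength nested partition: a two-level partition is
#' searched first; top-level modules are then (a) grouped into supermodules
#' whenever that strictly lowers the hierarchical codelength (coarsening, as
#' in Infomap's super-module search) and (b) recursively re-partitioned into
#' submodules, a sub-partition being kept only when it strictly lowers the
#' hierarchical codelength (tolerance 1e-10 bits). Recursion stops at
#' `max_depth`, at modules smaller than `min_split`, or when no split helps.
#'
#' @inheritParams optimize_two_level
#' @param max_depth Maximum number of module levels (>= 1).
#' @param min_split Smallest module size eligible for splitting (>= 2).
#' @return A `module_tree` whose `$codelength` (bits) never exceeds the
#'   two-level codelength of its top level.
#' @export
build_hierarchy <- function(net, component, trials = 10, seed = 1,
                            max_depth = 5, min_split = 3) {
  if (length(component) == 0) stop("empty component")
  stopifnot(trials >= 1, max_depth >= 1, min_split >= 2)
  g <- me_base_graph(net, component)
  opt <- me_optimize(g, trials = trials, seed = seed)
  mc <- opt$membership

  # units: list of gene-index sets at the current top level
  units <- unname(split(seq_len(g$n), mc))
  # each unit starts as a leaf subtree (gene indices only)
  subtrees <- lapply(units, function(idx) list(idx = idx, children = NULL))

  # --- coarsening: group top-level units into supermodules while it pays ---
  # The grouping candidate is searched on the module-level flow graph (node
  # rate mass = node external flow = the unit's exit rate), then accepted on
  # the exact hierarchical codelength of the resulting tree. Singleton groups
  # are not wrapped: a lone unit stays at the root level.
  depth_used <- 1L
  round_i <- 0L
  while (length(subtrees) > 2 && depth_used < max_depth) {
    round_i <- round_i + 1L
    k <- length(subtrees)
    unit_of <- integer(g$n)
    for (u in seq_len(k)) unit_of[subtrees[[u]]$idx] <- u
    q_u <- vapply(subtrees, function(st) me_set_q(g, st$idx), 0)
    ei <- integer(0); ej <- integer(0); f <- numeric(0)
    if (length(g$ei)) {
      a <- unit_of[g$ei]; b <- unit_of[g$ej]
      cross <- a != b
      if (any(cross)) {
        lo <- pmin(a[cross], b[cross]); hi <- pmax(a[cross], b[cross])
        agg <- rowsum(g$f[cross], (lo - 1) * k + hi)
        key <- as.numeric(rownames(agg))
        ei <- as.integer((key - 1) %/% k + 1)
        ej <- as.integer((key - 1) %% k + 1)
        f <- as.numeric(agg)
      }
    }
    gm <- me_graph(P = q_u, x = q_u, ei = ei, ej = ej, f = f)
    grp <- me_optimize(gm, trials = trials, seed = derive_seed(seed, 31L + round_i))
    ng <- length(unique(grp$membership))
    if (ng <= 1 || ng >= k) break
    groups <- unname(split(seq_len(k), grp$membership))
    candidate <- lapply(groups, function(us) {
      if (length(us) == 1) return(subtrees[[us]])
      list(idx = sort(unlist(lapply(subtrees[us], `[[`, "idx"))),
           children = subtrees[us])
    })
    gain <- subtree_codelength(candidate, g) - subtree_codelength(subtrees, g)
    if (gain >= -1e-10) break
    subtrees <- candidate
    depth_used <- depth_used + 1L
  }

  # --- recursive splitting of leaf units ---
  counter <- new.env(parent = emptyenv()); counter$k <- 0L
  split_leaf <- function(idx, depth) {
    if (depth >= max_depth || length(idx) < min_split) return(NULL)
    counter$k <- counter$k + 1L
    sub <- me_subgraph_optimize(g, idx, trials,
                                derive_seed(seed, 1000L + counter$k))
    if (is.null(sub) || length(sub) < 2) return(NULL)
    q_m <- me_set_q(g, idx)
    q_c <- vapply(sub, function(cidx) me_set_q(g, cidx), 0)
    P_c <- vapply(sub, function(cidx) sum(g$P[cidx]), 0)
    gain <- plogp(q_m + sum(q_c)) - 2 * sum(plogp(q_c)) +
      sum(plogp(q_c + P_c)) - plogp(q_m + sum(g$P[idx]))
    if (gain >= -1e-10) return(NULL)
    sub
  }
  grow <- function(st, depth) {
    if (!is.null(st$children)) {
      kids <- lapply(st$children, grow, depth = depth + 1L)
      return(new_module_node(g$nodes[st$idx], children = kids))
    }
    sub <- split_leaf(st$idx, depth)
    if (is.null(sub)) return(new_module_node(g$nodes[st$idx]))
    kids <- lapply(sub, function(cidx) grow(list(idx = cidx, children = NULL),
                                            depth + 1L))
    new_module_node(g$nodes[st$idx], children = kids)
  }
  kids <- lapply(subtrees, grow, depth = 1L)
  kids <- order_children(kids, g)
  root <- new_module_node(g$nodes, children = kids, path = "root")
  class(root) <- c("module_tree", class(root))
  root <- assign_paths(root)
  root$codelength <- codelength_from_graph(root, g)
  store_node_codelengths(root, g)
}

order_children <- function(kids, g) {
  idx_of <- setNames(seq_along(g$nodes), g$nodes)
  order_rec <- function(nodes) {
    mass <- vapply(nodes, function(nd) sum(g$P[idx_of[nd$genes]]), 0)
    first <- vapply(nodes, function(nd) nd$genes[1], "")
    nodes <- nodes[order(-mass, first)]
    lapply(nodes, function(nd) {
      if (!is.null(nd$children)) nd$children <- order_rec(nd$children)
      nd
    })
  }
  order_rec(kids)
}

# Hierarchical codelength of a list of root-level subtree structures
# (lists with $idx gene-index sets and optional $children), used while the
# hierarchy is under construction.
subtree_codelength <- function(subtrees, g) {
  total <- 0
  walk <- function(st) {
    q_m <- me_set_q(g, st$idx)
    if (is.null(st$children)) {
      total <<- total + plogp(q_m + sum(g$P[st$idx])) - plogp(q_m) -
        sum(plogp(g$P[st$idx]))
    } else {
      q_kids <- vapply(st$children, function(ch) me_set_q(g, ch$idx), 0)
      total <<- total + plogp(q_m + sum(q_kids)) - plogp(q_m) -
        sum(plogp(q_kids))
      for (ch in st$children) walk(ch)
    }
  }
  q_tops <- vapply(subtrees, function(st) me_set_q(g, st$idx), 0)
  total <- plogp(sum(q_tops)) - sum(plogp(q_tops))
  for (st in subtrees) walk(st)
  total
}

# codelength() against a prebuilt base graph (avoids rebuilding).
codelength_from_graph <- function(tree, g) {
  idx_of <- setNames(seq_along(g$nodes), g$nodes)
  total <- 0
  walk <- function(node, is_root) {
    idx <- idx_of[node$genes]
    q_m <- if (is_root) 0 else me_set_q(g, idx)
    if (is.null(node$children)) {
      total <<- total + plogp(q_m + sum(g$P[idx])) - plogp(q_m) -
        sum(plogp(g$P[idx]))
    } else {
      q_kids <- vapply(node$children, function(ch) me_set_q(g, idx_of[ch$genes]), 0)
      total <<- total + plogp(q_m + sum(q_kids)) - plogp(q_m) -
        sum(plogp(q_kids))
      for (ch in node$children) walk(ch, FALSE)
    }
  }
  walk(tree, TRUE)
  total
}

# Optimize the induced subgraph of a gene-index set as a standalone network,
# handling disconnected induced subgraphs piecewise. Returns a list of
# gene-index sets (the candidate children), or NULL when trivial.
me_subgraph_optimize <- function(g, idx, trials, seed) {
  inset <- logical(g$n); inset[idx] <- TRUE
  sel <- which(inset[g$ei] & inset[g$ej])
  if (length(sel) == 0) {
    if (length(idx) == 1) return(NULL)
    return(as.list(idx))          # no internal edges: isolated members
  }
  local <- setNames(seq_along(idx), idx)
  ei <- local[as.character(g$ei[sel])]
  ej <- local[as.character(g$ej[sel])]
  # connected pieces of the induced subgraph (union-find)
  parent <- seq_along(idx)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_along(ei)) {
    a <- find(ei[k]); b <- find(ej[k])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_along(idx), find, 0L)
  pieces <- unname(split(seq_along(idx), roots))
  out <- list()
  piece_i <- 0L
  for (pc in pieces) {
    piece_i <- piece_i + 1L
    if (length(pc) == 1) { out[[length(out) + 1L]] <- idx[pc]; next }
    inpc <- logical(length(idx)); inpc[pc] <- TRUE
    psel <- sel[inpc[ei] & inpc[ej]]
    lmap <- setNames(seq_along(pc), pc)
    w <- g$f[psel]
    W2 <- 2 * sum(w)
    s <- numeric(length(pc))
    pei <- lmap[as.character(local[as.character(g$ei[psel])])]
    pej <- lmap[as.character(local[as.character(g$ej[psel])])]
    fr <- w / W2
    for (k in seq_along(psel)) {
      s[pei[k]] <- s[pei[k]] + fr[k]
      s[pej[k]] <- s[pej[k]] + fr[k]
    }
    gp <- me_graph(P = s, x = s, ei = pei, ej = pej, f = fr)
    opt <- me_optimize(gp, trials = trials, seed = derive_seed(seed, piece_i))
    for (mod in unname(split(pc, opt$membership))) {
      out[[length(out) + 1L]] <- sort(idx[mod])
    }
  }
  if (length(out) < 2) return(NULL)
  out
}
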