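# Fixture builders -----------------------------------------------------------

mk_clique <- function(pref, n, w = 1) {
  g <- sprintf("%s%02d", pref, seq_len(n))
  cmb <- t(combn(g, 2))
  data.frame(gene_a = cmb[, 1], gene_b = cmb[, 2], mi = w,
             stringsAsFactors = FALSE)
}

# perfect matching a_i -- b_i between two 8-node name groups
mk_matching <- function(p1, p2, n = 8, w = 1) {
  data.frame(gene_a = sprintf("%s%02d", p1, seq_len(n)),
             gene_b = sprintf("%s%02d", p2, seq_len(n)), mi = w,
             stringsAsFactors = FALSE)
}

barbell_net <- function() {
  gene_network(rbind(mk_clique("a", 3), mk_clique("b", 3),
                     data.frame(gene_a = "a01", gene_b = "b01", mi = 1)))
}

two_clique_net <- function(n = 8) {
  gene_network(rbind(mk_clique("x", n), mk_clique("y", n),
                     data.frame(gene_a = "x01", gene_b = "y01", mi = 1)))
}

# two super-groups, each two 8-cliques joined by a perfect matching; a single
# edge between the super-groups
nested_net <- function() {
  gene_network(rbind(
    mk_clique("a", 8), mk_clique("b", 8), mk_clique("c", 8), mk_clique("d", 8),
    mk_matching("a", "b"), mk_matching("c", "d"),
    data.frame(gene_a = "a01", gene_b = "c01", mi = 1)
  ))
}

nested_truth <- function() {
  genes <- c(sprintf("a%02d", 1:8), sprintf("b%02d", 1:8),
             sprintf("c%02d", 1:8), sprintf("d%02d", 1:8))
  list(level1 = setNames(rep(c("AB", "AB", "CD", "CD"), each = 8), genes),
       level2 = setNames(rep(c("a", "b", "c", "d"), each = 8), genes))
}

# seeded random connected graph on n nodes with random weights
random_connected_net <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    adj <- matrix(runif(n * n) < p, n, n)
    adj[lower.tri(adj, diag = TRUE)] <- FALSE
    idx <- which(adj, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    genes <- sprintf("n%02d", seq_len(n))
    edges <- data.frame(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                        mi = round(runif(nrow(idx), 0.2, 1), 3),
                        stringsAsFactors = FALSE)
    net <- gene_network(edges)
    if (length(net$nodes) == n &&
        length(connected_components(net)) == 1) return(net)
  }
}

small_sim <- function(seed = 1, ...) {
  args <- modifyList(list(
    n_background_genes = 20,
    super_blocks = list(c(8L, 6L), c(6L, 5L)),
    amplicon_size = 3, n_tumor = 60, n_normal = 40,
    de_fraction = 0.1, de_shift = 2, seed = seed), list(...))
  do.call(sim_config, args)
}

# Oracles ---------------------------------------------------------------------

# Direct entropy-form evaluation of the two-level map equation, written from
# the definition (module exit rates + per-module codebook entropies);
# independent of the package's plogp expansion.
oracle_two_level <- function(net, membership) {
  membership <- setNames(as.character(membership), names(membership))
  nodes <- names(membership)
  e <- net$edges[net$edges$gene_a %in% nodes & net$edges$gene_b %in% nodes, ]
  W2 <- 2 * sum(e$mi)
  s <- setNames(numeric(length(nodes)), nodes)
  for (col in c("gene_a", "gene_b")) {
    agg <- tapply(e$mi, e[[col]], sum)
    s[names(agg)] <- s[names(agg)] + agg
  }
  p <- s / W2
  H <- function(x) { x <- x[x > 0]; x <- x / sum(x); -sum(x * log2(x)) }
  mods <- unique(membership)
  q <- setNames(numeric(length(mods)), mods)
  for (m in mods) {
    inm <- membership[e$gene_a] == m
    jnm <- membership[e$gene_b] == m
    q[m] <- sum(e$mi[xor(inm, jnm)]) / W2
  }
  qtot <- sum(q)
  L_index <- if (qtot > 0) qtot * H(q) else 0
  L_mod <- 0
  for (m in mods) {
    rates <- c(q[m], p[membership == m])
    L_mod <- L_mod + sum(rates) * H(rates)
  }
  L_index + L_mod
}

# All set partitions of 1..n as membership vectors (restricted growth strings)
oracle_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxm) {
    i <- length(prefix) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- prefix; return(invisible()) }
    for (m in seq_len(maxm + 1L)) rec(c(prefix, m), max(maxm, m))
  }
  rec(integer(0), 0L)
  out
}

# Exhaustive minimum two-level codelength over all partitions
oracle_min_codelength <- function(net) {
  nodes <- sort(net$nodes)
  parts <- oracle_partitions(length(nodes))
  best <- Inf
  for (m in parts) {
    L <- oracle_two_level(net, setNames(m, nodes))
    if (L < best) best <- L
  }
  best
}

# Dense linear-system PageRank: v = (1-d)/n * (I - d M)^{-1} 1
oracle_pagerank <- function(net, component, damping = 0.85) {
  nodes <- sort(component)
  n <- length(nodes)
  e <- net$edges[net$edges$gene_a %in% nodes & net$edges$gene_b %in% nodes, ]
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  A[cbind(e$gene_a, e$gene_b)] <- e$mi
  A <- A + t(A)
  M <- t(A / rowSums(A))              # column-stochastic
  v <- solve(diag(n) - damping * M, rep((1 - damping) / n, n))
  setNames(v / sum(v), nodes)
}

# Exact hypergeometric upper tail by direct binomial-coefficient summation
oracle_hyper_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

expect_valid_tree <- function(tree, component = NULL) {
  expect_true(coexmap:::validate_module_tree(tree, component))
}
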