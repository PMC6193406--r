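test_that("visit rates are strength-proportional and sum to one", {
  # path A-B-C: degrees (1,2,1), 2W = 4
  path_net <- gene_network(data.frame(gene_a = c("A", "B"),
                                      gene_b = c("B", "C"), mi = 1))
  expect_equal(visit_rates(path_net, path_net$nodes),
               c(A = 0.25, B = 0.5, C = 0.25), tolerance = 1e-14)
  # k-regular graph (cycle): uniform
  cyc <- gene_network(data.frame(gene_a = c("a", "b", "c", "d", "e"),
                                 gene_b = c("b", "c", "d", "e", "a"), mi = 2))
  expect_equal(unname(visit_rates(cyc, cyc$nodes)), rep(0.2, 5),
               tolerance = 1e-14)
  expect_equal(sum(visit_rates(cyc, cyc$nodes)), 1, tolerance = 1e-12)
  expect_error(visit_rates(cyc, c("a", "b", "z")))
})

test_that("connected components are found and deterministically ordered", {
  net <- gene_network(rbind(mk_clique("a", 4), mk_clique("b", 3),
                            data.frame(gene_a = "z1", gene_b = "z2", mi = 0.5)),
                      nodes = c("iso1", "iso2"))
  comps <- connected_components(net)
  expect_identical(lengths(comps), c(4L, 3L, 2L, 1L, 1L))
  expect_identical(comps[[1]], sprintf("a%02d", 1:4))
  expect_identical(comps[[4]], "iso1")                # ties by smallest member
  expect_identical(sort(unlist(comps)), sort(net$nodes))
  # single clique: one component
  expect_length(connected_components(gene_network(mk_clique("q", 5))), 1L)
})

test_that("codelength matches hand values and the independent entropy oracle", {
  # 4-cycle in one module: exactly 2 bits
  cyc4 <- gene_network(data.frame(gene_a = c("a", "b", "c", "d"),
                                  gene_b = c("b", "c", "d", "a"), mi = 1))
  one_mod <- optimize_two_level(cyc4, cyc4$nodes, trials = 3, seed = 1)
  expect_length(one_mod$children, 1L)
  expect_identical(codelength(cyc4, one_mod), 2)

  # barbell: package value == oracle value, and two modules beat one
  bb <- barbell_net()
  truth_m <- setNames(rep(c(1, 2), each = 3), sort(bb$nodes))
  tr <- optimize_two_level(bb, bb$nodes, trials = 10, seed = 1)
  expect_length(tr$children, 2L)
  expect_equal(tr$codelength, oracle_two_level(bb, truth_m), tolerance = 1e-12)
  expect_equal(codelength(bb, tr), tr$codelength, tolerance = 1e-12)
  one <- oracle_two_level(bb, setNames(rep(1, 6), sort(bb$nodes)))
  expect_lt(tr$codelength, one)

  # exhaustive enumeration: the two-triangle split is the global optimum
  expect_equal(oracle_min_codelength(bb), tr$codelength, tolerance = 1e-12)
  expect_error(codelength(bb, local({
    t2 <- tr; t2$children[[1]]$genes <- t2$children[[1]]$genes[-1]; t2
  })), "partition")
})

test_that("codelength is invariant to module relabeling and node order", {
  net <- random_connected_net(8, seed = 5)
  nodes <- sort(net$nodes)
  m <- setNames(c(1, 1, 2, 2, 2, 3, 3, 1), nodes)
  relab <- setNames(c(9, 9, 4, 4, 4, 7, 7, 9), nodes)
  expect_equal(oracle_two_level(net, m), oracle_two_level(net, relab),
               tolerance = 1e-12)
  shuf <- m[sample(names(m))]
  expect_equal(oracle_two_level(net, m), oracle_two_level(net, shuf),
               tolerance = 1e-12)
})

test_that("the optimizer recovers planted partitions and never beats the oracle", {
  # single clique: no split helps
  cl <- gene_network(mk_clique("c", 7))
  expect_length(optimize_two_level(cl, cl$nodes, trials = 5, seed = 2)$children, 1L)

  # two 8-cliques joined by one edge: exact recovery
  net2 <- two_clique_net(8)
  tr2 <- optimize_two_level(net2, net2$nodes, trials = 10, seed = 1)
  rec <- tree_partition(tr2, 1)
  truth <- setNames(rep(c("x", "y"), each = 8), sort(net2$nodes))
  expect_identical(partition_nmi(rec, truth), 1)

  # random 7-node graphs: optimizer equals the exhaustive minimum
  hits <- 0
  for (s in 1:8) {
    net <- random_connected_net(7, p = 0.45, seed = 400 + s)
    tr <- optimize_two_level(net, net$nodes, trials = 10, seed = s)
    best <- oracle_min_codelength(net)
    expect_gte(tr$codelength, best - 1e-9)            # never below the oracle
    if (abs(tr$codelength - best) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 7)
})

test_that("optimizer and hierarchy are deterministic given (net, trials, seed)", {
  net <- random_connected_net(12, p = 0.3, seed = 77)
  a <- optimize_two_level(net, net$nodes, trials = 5, seed = 9)
  b <- optimize_two_level(net, net$nodes, trials = 5, seed = 9)
  expect_identical(a, b)
  ha <- build_hierarchy(net, net$nodes, trials = 5, seed = 9)
  hb <- build_hierarchy(net, net$nodes, trials = 5, seed = 9)
  expect_identical(ha, hb)
})

test_that("build_hierarchy recovers nested structure and respects its guards", {
  # single clique: depth-1 tree
  cl <- gene_network(mk_clique("c", 8))
  hcl <- build_hierarchy(cl, cl$nodes, trials = 5, seed = 1)
  expect_identical(tree_depth(hcl), 1L)
  expect_valid_tree(hcl, cl$nodes)

  # nested benchmark: both levels exact
  net <- nested_net()
  tru <- nested_truth()
  h <- build_hierarchy(net, net$nodes, trials = 10, seed = 1)
  expect_valid_tree(h, net$nodes)
  expect_identical(tree_depth(h), 2L)
  expect_identical(partition_nmi(tree_partition(h, 1), tru$level1), 1)
  expect_identical(partition_nmi(tree_leaf_partition(h), tru$level2), 1)

  # hierarchical codelength never exceeds the flat two-level codelength
  flat <- optimize_two_level(net, net$nodes, trials = 10, seed = 1)
  expect_lte(h$codelength, flat$codelength + 1e-10)
  # and codelength() agrees with the stored value
  expect_equal(codelength(net, h), h$codelength, tolerance = 1e-12)

  expect_error(build_hierarchy(net, character(0)), "empty")
  expect_error(build_hierarchy(net, net$nodes, max_depth = 0), "max_depth")
})

test_that("tree partitions, paths, and .tree/JSON output are consistent", {
  net <- nested_net()
  h <- build_hierarchy(net, net$nodes, trials = 10, seed = 1)
  nodes <- tree_nodes(h)
  paths <- vapply(nodes, `[[`, "", "path")
  expect_false(anyDuplicated(paths) > 0)
  expect_true(all(grepl("^[0-9]+(:[0-9]+)*$", paths)))
  # every level-2 path extends its parent's path
  for (nd in nodes) {
    if (attr(nd, "depth") == 2L) {
      expect_true(any(paths == sub(":[0-9]+$", "", nd$path)))
    }
  }
  d <- withr::local_tempdir()
  rates <- visit_rates(net, net$nodes)
  write_tree_file(h, rates, file.path(d, "t.tree"))
  back <- read_tree_file(file.path(d, "t.tree"))
  expect_setequal(back$gene, net$nodes)
  expect_equal(sum(back$flow), 1, tolerance = 1e-5)
  leaf <- tree_leaf_partition(h)
  expect_identical(unname(sub(":[0-9]+$", "", back$path[match(net$nodes, back$gene)])),
                   unname(leaf[net$nodes]))
  write_tree_json(h, file.path(d, "t.json"))
  tj <- jsonlite::read_json(file.path(d, "t.json"))
  expect_identical(tj$path, "root")
  expect_length(tj$children, length(h$children))
})
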