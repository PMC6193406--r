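test_that("estimate_mi is symmetric, rank-invariant, and handles degenerate input", {
  set.seed(1)
  x <- rnorm(100); y <- rnorm(100)
  expect_identical(estimate_mi(x, y), estimate_mi(y, x))
  # invariance under strictly monotone transforms (rank-based binning)
  expect_identical(estimate_mi(x, y), estimate_mi(exp(x), y))
  expect_identical(estimate_mi(x, y), estimate_mi(x, y^3 + 5 * y))
  expect_error(estimate_mi(x, y[-1]), "length")
  expect_error(estimate_mi(x[1:10], y[1:10]), "20")
  expect_error(estimate_mi(c(x[-1], NA), y), "finite")
  expect_warning(mi0 <- estimate_mi(rep(1, 50), rnorm(50)), "constant")
  expect_identical(mi0, 0)
})

test_that("estimate_mi tracks the Gaussian closed form and vanishes under independence", {
  set.seed(101)
  z <- rnorm(2000)
  y <- 0.8 * z + sqrt(1 - 0.64) * rnorm(2000)
  expect_equal(estimate_mi(z, y), -0.5 * log(1 - 0.8^2), tolerance = 0.08 / 0.51)
  # independent permutation of the same values
  set.seed(202)
  expect_lte(estimate_mi(z, sample(z)), 0.02)
})

test_that("build_mi_table enumerates pairs consistently", {
  sim <- simulate_expression(small_sim(seed = 9, n_tumor = 80, n_normal = 20,
                                       de_fraction = 0))
  sub <- c("B1S1G001", "B1S1G002", "BG0001")
  tab3 <- build_mi_table(sim$data, subset = sub)
  expect_identical(nrow(tab3), 3L)                     # C(3,2)
  expect_true(all(tab3$gene_a < tab3$gene_b))
  expect_true(all(tab3$mi >= 0))

  # restriction consistency: subset table == full table filtered
  sub6 <- sort(c(sim$truth$block_tree$B1$S1[1:3], "BG0001", "BG0002", "AMP01"))
  full <- build_mi_table(sim$data)
  tab6 <- build_mi_table(sim$data, subset = sub6)
  filt <- full[full$gene_a %in% sub6 & full$gene_b %in% sub6, ]
  rownames(filt) <- NULL
  expect_equal(tab6$mi, filt$mi, tolerance = 1e-12)
  expect_identical(tab6$gene_a, filt$gene_a)

  # planted sub-block pairs score above background pairs
  mem <- setNames(sim$truth$membership$sub, sim$truth$membership$gene)
  in_a <- full$gene_a %in% names(mem); in_b <- full$gene_b %in% names(mem)
  same_sub <- in_a & in_b & mem[full$gene_a] == mem[full$gene_b]
  bg <- startsWith(full$gene_a, "BG") & startsWith(full$gene_b, "BG")
  expect_gt(median(full$mi[same_sub]), median(full$mi[bg]))

  expect_error(build_mi_table(sim$data, subset = "NOPE"), "unknown")
})

test_that("dpi_prune applies the triangle rule simultaneously", {
  tri <- structure(data.frame(gene_a = c("A", "A", "B"),
                              gene_b = c("B", "C", "C"),
                              mi = c(0.9, 0.3, 0.8)),
                   class = c("mi_table", "data.frame"))
  pruned <- dpi_prune(tri, epsilon = 0)
  expect_setequal(paste(pruned$gene_a, pruned$gene_b),
                  c("A B", "B C"))                     # weakest edge removed
  expect_identical(nrow(dpi_prune(tri, epsilon = 1)), 3L)  # epsilon 1: no-op
  expect_error(dpi_prune(tri, epsilon = -0.1), "epsilon")

  # oracle: brute-force scan over all triangles, simultaneous removal
  dpi_oracle <- function(tab, eps) {
    key <- paste(tab$gene_a, tab$gene_b)
    drop <- logical(nrow(tab))
    genes <- unique(c(tab$gene_a, tab$gene_b))
    for (tri in combn(genes, 3, simplify = FALSE)) {
      tri <- sort(tri)
      e <- c(which(key == paste(tri[1], tri[2])),
             which(key == paste(tri[1], tri[3])),
             which(key == paste(tri[2], tri[3])))
      if (length(e) < 3) next                        # not a triangle
      for (i in 1:3) {
        if (tab$mi[e[i]] < min(tab$mi[e[-i]]) * (1 - eps)) drop[e[i]] <- TRUE
      }
    }
    tab[!drop, ]
  }
  set.seed(8)
  for (rep in 1:5) {
    genes <- sprintf("g%02d", 1:8)
    cmb <- t(combn(genes, 2))
    tab <- structure(data.frame(gene_a = cmb[, 1], gene_b = cmb[, 2],
                                mi = runif(nrow(cmb), 0.01, 1)),
                     class = c("mi_table", "data.frame"))
    # sparsify so triangles and non-triangles both occur
    tab <- tab[runif(nrow(tab)) < 0.7, ]
    for (eps in c(0, 0.1)) {
      kept <- dpi_prune(tab, epsilon = eps)
      orc <- dpi_oracle(tab, eps)
      expect_identical(paste(kept$gene_a, kept$gene_b),
                       paste(orc$gene_a, orc$gene_b))
    }
    # within any single triangle considered alone, the strongest edge survives
    for (tri in combn(genes[1:5], 3, simplify = FALSE)) {
      sub <- tab[tab$gene_a %in% tri & tab$gene_b %in% tri, ]
      if (nrow(sub) < 3) next
      kept_tri <- dpi_prune(sub, epsilon = 0)
      expect_true(paste(sub$gene_a, sub$gene_b)[which.max(sub$mi)] %in%
                    paste(kept_tri$gene_a, kept_tri$gene_b))
    }
  }
})

test_that("dpi_prune removes the indirect edge of a Gaussian Markov chain", {
  removed <- 0
  for (s in 1:20) {
    set.seed(300 + s)
    n <- 2000
    x <- rnorm(n)
    y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(n)
    z <- 0.9 * y + sqrt(1 - 0.81) * rnorm(n)
    tab <- structure(data.frame(
      gene_a = c("X", "X", "Y"), gene_b = c("Y", "Z", "Z"),
      mi = c(estimate_mi(x, y), estimate_mi(x, z), estimate_mi(y, z))),
      class = c("mi_table", "data.frame"))
    kept <- dpi_prune(tab, epsilon = 0.05)
    if (!any(kept$gene_a == "X" & kept$gene_b == "Z")) removed <- removed + 1
  }
  expect_gte(removed, 18)
})

test_that("prune_top_edges keeps exactly the k best pairs with lexicographic ties", {
  set.seed(12)
  genes <- sprintf("g%d", 1:5)
  cmb <- t(combn(genes, 2))
  tab <- structure(data.frame(gene_a = cmb[, 1], gene_b = cmb[, 2],
                              mi = sample(seq(0.1, 1, length.out = 10))),
                   class = c("mi_table", "data.frame"))
  net <- prune_top_edges(tab, k = 3)
  ord <- tab[order(-tab$mi), ][1:3, ]                   # full-sort oracle
  expect_setequal(paste(net$edges$gene_a, net$edges$gene_b),
                  paste(ord$gene_a, ord$gene_b))
  expect_identical(nrow(net$edges), 3L)

  # k >= number of pairs: everything kept
  expect_identical(nrow(prune_top_edges(tab, k = 99)$edges), nrow(tab))
  expect_identical(formals(prune_top_edges)$k, 10000)   # conventional default

  # exact ties at the cutoff resolved lexicographically
  tie <- structure(data.frame(gene_a = c("a", "a", "b"),
                              gene_b = c("b", "c", "c"),
                              mi = c(0.5, 0.5, 0.5)),
                   class = c("mi_table", "data.frame"))
  kept <- prune_top_edges(tie, k = 2)$edges
  expect_identical(paste(kept$gene_a, kept$gene_b), c("a b", "a c"))
  expect_error(prune_top_edges(tie[0, ], k = 1), "empty")

  # invariant: edge count is min(k, pairs)
  for (k in c(1, 4, 10, 25)) {
    expect_identical(nrow(prune_top_edges(tab, k)$edges),
                     as.integer(min(k, nrow(tab))))
  }
})

test_that("edge lists round-trip through TSV and SIF", {
  net <- two_clique_net(4)
  d <- withr::local_tempdir()
  write_edge_list(net, file.path(d, "edges.tsv"))
  back <- read_edge_list(file.path(d, "edges.tsv"))
  expect_identical(back$gene_a, net$edges$gene_a)
  expect_equal(back$mi, net$edges$mi, tolerance = 1e-6)
  write_sif(net, file.path(d, "net.sif"))
  sif <- readLines(file.path(d, "net.sif"))
  expect_length(sif, nrow(net$edges))
  expect_match(sif[1], "^x01\t[0-9.]+\tx02$")
})
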