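test_that("generator is deterministic and structurally sound", {
  cfg <- small_sim(seed = 11)
  s1 <- simulate_expression(cfg)
  s2 <- simulate_expression(cfg)
  expect_identical(s1$data$matrix, s2$data$matrix)
  expect_identical(s1$truth$de_genes, s2$truth$de_genes)

  # a different seed changes the data
  s3 <- simulate_expression(cfg, seed = 12)
  expect_false(identical(s1$data$matrix, s3$data$matrix))

  truth <- s1$truth
  blocks <- unlist(truth$block_tree, use.names = FALSE)
  expect_false(anyDuplicated(blocks) > 0)                 # blocks disjoint
  expect_length(intersect(blocks, truth$amplicon_genes), 0)
  expect_true(all(c(blocks, truth$amplicon_genes) %in% s1$data$gene_ids))
  expect_identical(dim(s1$data$matrix),
                   c(length(s1$data$gene_ids), length(s1$data$sample_ids)))
  expect_setequal(unique(s1$data$condition), c("tumor", "normal"))
})

test_that("planted correlations match the factor model's closed form", {
  # lambda = 0.9, alpha = 0.6 at 200 samples: within-sub r = 0.81,
  # cross-sub (same super) r = 0.2916
  cfg <- sim_config(n_background_genes = 0,
                    super_blocks = list(c(15L, 15L), c(15L, 15L)),
                    amplicon_size = 0, n_tumor = 200, n_normal = 0,
                    de_fraction = 0, seed = 7)
  sim <- simulate_expression(cfg)
  cm <- cor(t(sim$data$matrix))
  mem <- setNames(sim$truth$membership$sub, sim$truth$membership$gene)
  sup <- setNames(sim$truth$membership$super, sim$truth$membership$gene)
  g <- rownames(cm)
  ut <- upper.tri(cm)
  same_sub <- outer(mem[g], mem[g], "==") & ut
  same_sup <- outer(sup[g], sup[g], "==") & !outer(mem[g], mem[g], "==") & ut
  expect_equal(mean(cm[same_sub]), 0.81, tolerance = 0.05 / 0.81)
  expect_equal(mean(cm[same_sup]), 0.2916, tolerance = 0.05 / 0.2916)
})

test_that("alpha = 0 decouples sub-blocks and amplicon stays isolated", {
  cfg <- sim_config(n_background_genes = 10,
                    super_blocks = list(c(10L, 10L, 10L, 10L)),
                    super_coupling = 0, amplicon_size = 4,
                    n_tumor = 200, n_normal = 0, de_fraction = 0, seed = 3)
  sim <- simulate_expression(cfg)
  cm <- cor(t(sim$data$matrix))
  mem <- setNames(sim$truth$membership$sub, sim$truth$membership$gene)
  blocks <- sim$truth$membership$gene
  cross <- cm[blocks, blocks][outer(mem[blocks], mem[blocks], "!=") &
                                upper.tri(cm[blocks, blocks])]
  expect_lt(abs(mean(cross)), 0.05)     # expected cross correlation is 0
  amp <- cm[sim$truth$amplicon_genes, blocks]
  expect_lt(abs(mean(amp)), 0.05)       # amplicon uncorrelated with blocks
})

test_that("non-DE genes have unit variance and nesting strictly orders correlations", {
  cfg <- sim_config(n_background_genes = 5,
                    super_blocks = list(c(8L, 8L), c(8L, 8L)),
                    within_sub_loading = 0.75, super_coupling = 0.55,
                    amplicon_size = 0, n_tumor = 4000, n_normal = 0,
                    de_fraction = 0, noise_sd = 1, seed = 5)
  sim <- simulate_expression(cfg)
  v <- apply(sim$data$matrix, 1, var)
  expect_true(all(abs(v - 1) < 0.1))

  cm <- cor(t(sim$data$matrix))
  mem <- setNames(sim$truth$membership$sub, sim$truth$membership$gene)
  sup <- setNames(sim$truth$membership$super, sim$truth$membership$gene)
  b <- sim$truth$membership$gene
  cmb <- cm[b, b]; ut <- upper.tri(cmb)
  within <- mean(cmb[outer(mem[b], mem[b], "==") & ut])
  cross_sub <- mean(cmb[outer(sup[b], sup[b], "==") &
                          outer(mem[b], mem[b], "!=") & ut])
  cross_sup <- mean(cmb[outer(sup[b], sup[b], "!=") & ut])
  expect_gt(within, cross_sub)
  expect_gt(cross_sub, cross_sup)
})

test_that("DE overlay shifts tumor means by the planted amount", {
  cfg <- small_sim(seed = 21, n_tumor = 300, n_normal = 300, de_shift = 1.5)
  sim <- simulate_expression(cfg)
  de <- sim$truth$de_genes
  expect_gt(nrow(de), 0)
  tum <- sim$data$condition == "tumor"
  fc <- rowMeans(sim$data$matrix[de$gene, tum, drop = FALSE]) -
    rowMeans(sim$data$matrix[de$gene, !tum, drop = FALSE])
  expect_equal(unname(fc), de$shift, tolerance = 0.15)
  # de_by_block concentrates DE in the chosen sub-blocks
  cfg2 <- small_sim(seed = 21, de_by_block = 1L)
  sim2 <- simulate_expression(cfg2)
  sub1 <- sim2$truth$block_tree[["B1"]][["S1"]]
  expect_true(all(sim2$truth$de_genes$gene %in% sub1))
})

test_that("gene sets align to sub-blocks; decoys follow the hypergeometric mean", {
  sim <- simulate_expression(small_sim(seed = 2))
  truth <- sim$truth
  sets0 <- generate_gene_sets(truth, n_decoy_sets = 0, seed = 1)
  n_sub <- sum(lengths(truth$block_tree))
  expect_length(sets0, n_sub)                       # one set per sub-block
  expect_setequal(sets0[["SET_B1S1"]], truth$block_tree[["B1"]][["S1"]])

  sets1 <- generate_gene_sets(truth, n_decoy_sets = 3, decoy_size = 5, seed = 1)
  expect_length(sets1, n_sub + 3)
  expect_error(generate_gene_sets(truth, decoy_size = 1000, seed = 1),
               "exceeds")

  # decoys drawn uniformly: mean overlap with a sub-block ~ K*n/N
  universe <- c(unlist(truth$block_tree, use.names = FALSE), truth$amplicon_genes)
  N <- length(universe); K <- length(truth$block_tree[["B1"]][["S1"]]); nd <- 6
  overlaps <- vapply(1:200, function(s) {
    d <- generate_gene_sets(truth, n_decoy_sets = 1, decoy_size = nd, seed = s)
    length(intersect(d[["DECOY_01"]], truth$block_tree[["B1"]][["S1"]]))
  }, 0)
  expected <- K * nd / N
  se <- sqrt(nd * (K / N) * (1 - K / N) * (N - nd) / (N - 1) / 200)
  expect_lt(abs(mean(overlaps) - expected), 4 * se + 1e-9)
})

test_that("expression/label/GMT round-trips preserve the data", {
  sim <- simulate_expression(small_sim(seed = 4))
  sets <- generate_gene_sets(sim$truth, n_decoy_sets = 2, decoy_size = 4, seed = 1)
  d <- withr::local_tempdir()
  write_expression_tsv(sim$data, file.path(d, "e.tsv"), file.path(d, "c.tsv"))
  back <- read_expression_tsv(file.path(d, "e.tsv"), file.path(d, "c.tsv"))
  expect_equal(back$matrix, sim$data$matrix, tolerance = 1e-12)
  expect_identical(back$condition, sim$data$condition)
  write_gmt(sets, file.path(d, "s.gmt"))
  back_sets <- read_gmt(file.path(d, "s.gmt"))
  expect_identical(lapply(back_sets, identity)[names(sets)],
                   unclass(sets)[names(sets)])
  write_truth_json(sim$truth, file.path(d, "t.json"))
  tj <- jsonlite::read_json(file.path(d, "t.json"), simplifyVector = TRUE)
  expect_setequal(tj$amplicon_genes, sim$truth$amplicon_genes)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(within_sub_loading = 1.2), "within_sub_loading")
  expect_error(sim_config(super_coupling = 1), "super_coupling")
  expect_error(sim_config(amplicon_loading = 0.5), "tightest")
  expect_error(sim_config(n_tumor = 0), "positive")
  expect_error(sim_config(noise_sd = 0))
})
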