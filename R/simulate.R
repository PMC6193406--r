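#' Simulation configuration for the synthetic expression generator
#'
#' The generator plants, in one log2 expression matrix, (i) hierarchically
#' nested co-expressed blocks (super-blocks made of sub-blocks, coupled by a
#' shared latent factor), (ii) one tightly co-expressed "amplicon" clique that
#' is uncorrelated with everything else, (iii) tumor-vs-normal shifts on a
#' subset of genes, and (iv) background genes that are pure noise. All genes
#' have unit variance when `noise_sd = 1`, so correlations are analytic:
#' within a sub-block `lambda^2`, across sub-blocks of one super-block
#' `lambda^2 * alpha^2`, across super-blocks 0, amplicon internal
#' `amplicon_loading^2`.
#'
#' Defaults state a world mirroring the discovery cohort the package emulates:
#' 600 genes (200 in blocks, 4 amplicon, 396 background), 493 tumor and 61
#' normal samples, `lambda = 0.9`, `alpha = 0.6`, `amplicon_loading = 0.95`.
#'
#' @param n_background_genes Count of pure-noise genes.
#' @param super_blocks List of integer vectors; element `b` holds the
#'   sub-block sizes of super-block `b`.
#' @param within_sub_loading Factor loading `lambda` in (0,1) of a gene on its
#'   sub-block factor.
#' @param super_coupling Coupling `alpha` in \[0,1) of sub-block factors on
#'   their super-block factor.
#' @param amplicon_size,amplicon_loading Size and loading of the isolated
#'   amplicon clique block (`amplicon_loading >= within_sub_loading`).
#' @param n_tumor,n_normal Sample counts per condition.
#' @param de_fraction Fraction of genes receiving a differential-expression
#'   shift.
#' @param de_shift Shift `delta` (log2 units) added to tumor samples of DE
#'   genes (sign drawn per gene).
#' @param de_by_block Optional integer vector of sub-block indices (in block
#'   order); when given, DE genes are drawn only from those sub-blocks,
#'   concentrating the expression overlay in chosen modules.
#' @param noise_sd Standard deviation scale of the idiosyncratic noise.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_background_genes = 396,
                       super_blocks = list(c(40L, 30L, 30L), c(35L, 25L), c(20L, 20L)),
                       within_sub_loading = 0.9,
                       super_coupling = 0.6,
                       amplicon_size = 4,
                       amplicon_loading = 0.95,
                       n_tumor = 493,
                       n_normal = 61,
                       de_fraction = 0.1,
                       de_shift = 2,
                       de_by_block = NULL,
                       noise_sd = 1,
                       seed = 1L) {
  cfg <- list(
    n_background_genes = as.integer(n_background_genes),
    super_blocks = lapply(super_blocks, as.integer),
    within_sub_loading = within_sub_loading,
    super_coupling = super_coupling,
    amplicon_size = as.integer(amplicon_size),
    amplicon_loading = amplicon_loading,
    n_tumor = as.integer(n_tumor),
    n_normal = as.integer(n_normal),
    de_fraction = de_fraction,
    de_shift = de_shift,
    de_by_block = if (is.null(de_by_block)) NULL else as.integer(de_by_block),
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_background_genes >= 0,
    all(unlist(cfg$super_blocks) >= 0),
    cfg$amplicon_size >= 0,
    cfg$noise_sd > 0,
    cfg$de_fraction >= 0, cfg$de_fraction <= 1
  )
  if (cfg$n_tumor <= 0 || cfg$n_normal < 0) {
    stop("sample counts must be positive (n_normal may be 0 only without DE)")
  }
  l <- cfg$within_sub_loading
  a <- cfg$super_coupling
  if (!(l > 0 && l < 1)) stop("within_sub_loading must be in (0,1)")
  if (!(a >= 0 && a < 1)) stop("super_coupling must be in [0,1)")
  if (!(cfg$amplicon_loading > 0 && cfg$amplicon_loading < 1)) {
    stop("amplicon_loading must be in (0,1)")
  }
  if (cfg$amplicon_size > 0 && cfg$amplicon_loading < l) {
    stop("amplicon_loading must be >= within_sub_loading (amplicon is the tightest block)")
  }
  invisible(cfg)
}

# Gene id layout, in matrix row order: block genes, amplicon genes, background.
sim_gene_ids <- function(cfg) {
  ids <- character(0)
  for (b in seq_along(cfg$super_blocks)) {
    for (s in seq_along(cfg$super_blocks[[b]])) {
      ids <- c(ids, sprintf("B%dS%dG%03d", b, s, seq_len(cfg$super_blocks[[b]][s])))
    }
  }
  c(ids,
    if (cfg$amplicon_size > 0) sprintf("AMP%02d", seq_len(cfg$amplicon_size)),
    if (cfg$n_background_genes > 0) sprintf("BG%04d", seq_len(cfg$n_background_genes)))
}

#' Simulate an expression dataset with planted modular structure
#'
#' Draws from the nested latent-factor model described in [sim_config()]:
#' per sample, each super-block has a standard-normal factor `z_b`; each
#' sub-block factor is `u_s = alpha * z_b + sqrt(1 - alpha^2) * w_s`; a gene
#' in sub-block `s` is `lambda * u_s + sqrt(1 - lambda^2) * noise_sd * eps`.
#' Amplicon genes load on one shared factor with `amplicon_loading` and on
#' nothing else; background genes are pure noise. DE genes get a signed
#' `de_shift` added to tumor samples only. A per-gene baseline (log2 scale,
#' drawn uniformly in \[6, 12\]) is added so the matrix looks like log2
#' microarray intensities; it affects no correlation or fold change.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer overriding `config$seed`.
#' @return A list with elements `data` ([expression_dataset()]) and `truth`
#'   (class `ground_truth`): `block_tree` (list of super-blocks, each a named
#'   list of sub-block gene vectors), `amplicon_genes`, `de_genes` (data.frame
#'   `gene`, `shift`), `membership` (data.frame `gene`, `super`, `sub`), and
#'   `planted_sets` (filled by [generate_gene_sets()]).
#' @examples
#' sim <- simulate_expression(sim_config(
#'   n_background_genes = 10, super_blocks = list(c(5, 5)),
#'   amplicon_size = 3, n_tumor = 20, n_normal = 10, seed = 1))
#' sim$data
#' @export
simulate_expression <- function(config, seed = NULL) {
  validate_sim_config(config)
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  n_samp <- config$n_tumor + config$n_normal
  gene_ids <- sim_gene_ids(config)
  n_gene <- length(gene_ids)
  lam <- config$within_sub_loading
  alp <- config$super_coupling

  sample_ids <- c(sprintf("T%03d", seq_len(config$n_tumor)),
                  sprintf("N%03d", seq_len(config$n_normal)))
  condition <- c(rep("tumor", config$n_tumor), rep("normal", config$n_normal))

  x <- matrix(0, n_gene, n_samp, dimnames = list(gene_ids, sample_ids))

  # sub-block membership bookkeeping
  sub_sizes <- unlist(config$super_blocks)
  n_sub <- length(sub_sizes)
  sub_super <- rep(seq_along(config$super_blocks),
                   lengths(config$super_blocks))
  block_rows <- if (n_sub > 0) seq_len(sum(sub_sizes)) else integer(0)
  sub_of_row <- rep(seq_len(n_sub), sub_sizes)

  with_seed(derive_seed(seed, 1L), {
    if (n_sub > 0) {
      z <- matrix(rnorm(length(config$super_blocks) * n_samp),
                  length(config$super_blocks), n_samp)
      w <- matrix(rnorm(n_sub * n_samp), n_sub, n_samp)
      u <- alp * z[sub_super, , drop = FALSE] + sqrt(1 - alp^2) * w
      eps <- matrix(rnorm(length(block_rows) * n_samp), length(block_rows), n_samp)
      x[block_rows, ] <- lam * u[sub_of_row, , drop = FALSE] +
        sqrt(1 - lam^2) * config$noise_sd * eps
    }
  })

  amp_rows <- if (config$amplicon_size > 0) sum(sub_sizes) + seq_len(config$amplicon_size) else integer(0)
  with_seed(derive_seed(seed, 2L), {
    if (length(amp_rows) > 0) {
      f <- rnorm(n_samp)
      al <- config$amplicon_loading
      x[amp_rows, ] <- al * rep(f, each = length(amp_rows)) +
        sqrt(1 - al^2) * config$noise_sd *
          matrix(rnorm(length(amp_rows) * n_samp), length(amp_rows), n_samp)
    }
  })

  bg_rows <- if (config$n_background_genes > 0) {
    sum(sub_sizes) + config$amplicon_size + seq_len(config$n_background_genes)
  } else integer(0)
  with_seed(derive_seed(seed, 3L), {
    if (length(bg_rows) > 0) {
      x[bg_rows, ] <- config$noise_sd *
        matrix(rnorm(length(bg_rows) * n_samp), length(bg_rows), n_samp)
    }
  })

  # differential expression overlay: signed shift on tumor samples
  de <- data.frame(gene = character(0), shift = numeric(0))
  with_seed(derive_seed(seed, 4L), {
    n_de <- round(config$de_fraction * n_gene)
    if (n_de > 0 && config$n_normal >= 1) {
      pool <- if (is.null(config$de_by_block)) {
        seq_len(n_gene)
      } else {
        which(sub_of_row %in% config$de_by_block)
      }
      n_de <- min(n_de, length(pool))
      rows <- sort(sample(pool, n_de))
      shifts <- sample(c(-1, 1), n_de, replace = TRUE) * config$de_shift
      x[rows, condition == "tumor"] <- x[rows, condition == "tumor"] + shifts
      de <- data.frame(gene = gene_ids[rows], shift = shifts)
    }
  })

  with_seed(derive_seed(seed, 5L), {
    baseline <- runif(n_gene, 6, 12)
    x <- x + baseline
  })

  block_tree <- list()
  row0 <- 0L
  for (b in seq_along(config$super_blocks)) {
    super <- list()
    for (s in seq_along(config$super_blocks[[b]])) {
      sz <- config$super_blocks[[b]][s]
      super[[sprintf("S%d", s)]] <- gene_ids[row0 + seq_len(sz)]
      row0 <- row0 + sz
    }
    block_tree[[sprintf("B%d", b)]] <- super
  }
  membership <- data.frame(
    gene = gene_ids[block_rows],
    super = sprintf("B%d", sub_super[sub_of_row]),
    sub = sprintf("B%dS%d", sub_super[sub_of_row],
                  unlist(lapply(lengths(config$super_blocks), seq_len))[sub_of_row])
  )

  truth <- structure(
    list(block_tree = block_tree,
         amplicon_genes = gene_ids[amp_rows],
         de_genes = de,
         membership = membership,
         planted_sets = NULL),
    class = "ground_truth"
  )
  list(data = expression_dataset(x, condition = condition), truth = truth)
}

#' Generate gene sets aligned to planted sub-blocks, plus decoys
#'
#' Emits one set per planted sub-block (its genes, optionally contaminated
#' with extra random genes) and `n_decoy_sets` decoy sets drawn uniformly from
#' the simulated gene universe.
#'
#' @param truth The `truth` element returned by [simulate_expression()].
#' @param n_decoy_sets,decoy_size Number and size of random decoy sets.
#' @param contamination Count of random non-member genes appended to each
#'   sub-block set (default 0: the set equals the sub-block exactly).
#' @param universe Character vector of all gene ids decoys may be drawn from;
#'   defaults to all genes recorded in the truth (blocks, amplicon) -- pass
#'   the dataset's full `gene_ids` to include background genes.
#' @param seed Integer seed.
#' @return Named list of character vectors (a gene-set collection); sub-block
#'   sets are named like `SET_B1S2`, decoys `DECOY_01`, ...
#' @export
generate_gene_sets <- function(truth, n_decoy_sets = 10, decoy_size = 25,
                               contamination = 0, universe = NULL, seed = 1L) {
  if (length(truth$block_tree) == 0 && length(truth$amplicon_genes) == 0) {
    stop("empty ground truth")
  }
  if (is.null(universe)) {
    universe <- c(unlist(truth$block_tree, use.names = FALSE), truth$amplicon_genes)
  }
  if (decoy_size > length(universe)) stop("decoy_size exceeds gene universe")
  sets <- list()
  with_seed(derive_seed(seed, 11L), {
    for (b in names(truth$block_tree)) {
      for (s in names(truth$block_tree[[b]])) {
        members <- truth$block_tree[[b]][[s]]
        if (contamination > 0) {
          extra <- sample(setdiff(universe, members),
                          min(contamination, length(universe) - length(members)))
          members <- c(members, extra)
        }
        sets[[paste0("SET_", b, s)]] <- members
      }
    }
    if (n_decoy_sets > 0) {
      for (i in seq_len(n_decoy_sets)) {
        sets[[sprintf("DECOY_%02d", i)]] <- sort(sample(universe, decoy_size))
      }
    }
  })
  sets
}

#' Edge budget implied by the generator's planted structure
#'
#' The design density of a simulated network: all within-sub-block pairs, all
#' amplicon pairs, and 12% of the cross-sub-block (same super-block) pairs.
#' The 12% constant was fixed at design time from the estimator's null and
#' signal quantiles at the default cohort size so that the implied MI cutoff
#' admits fewer than ~5 spurious (independent-pair) edges per network while
#' every sub-block pair keeps at least ~10 linking edges.
#'
#' @param config A [sim_config()].
#' @return Integer edge count, used as the default `top_edges` for simulated
#'   pipeline runs.
#' @export
design_top_edges <- function(config) {
  within <- sum(vapply(unlist(config$super_blocks), function(s) s * (s - 1) / 2, 0))
  amp <- config$amplicon_size * (config$amplicon_size - 1) / 2
  cross <- sum(vapply(config$super_blocks, function(sz) {
    (sum(sz)^2 - sum(sz^2)) / 2
  }, 0))
  as.integer(round(within + amp + 0.12 * cross))
}

#' Write ground truth as JSON
#'
#' @param truth A `ground_truth` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(block_tree = truth$block_tree,
         amplicon_genes = truth$amplicon_genes,
         de_genes = truth$de_genes,
         membership = truth$membership,
         planted_sets = truth$planted_sets),
    path, auto_unbox = FALSE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
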