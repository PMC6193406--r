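#' Pipeline configuration
#'
#' One flat configuration for the end-to-end run:
#' simulate (or load) -> MI network -> differential expression -> components
#' -> hierarchical modules -> enrichment -> report.
#'
#' @param expression,conditions,gmt Input file paths (expression TSV,
#'   condition TSV, GMT), or `NULL` when simulating.
#' @param simulate A [sim_config()] to generate inputs, or `NULL`.
#' @param top_edges Edge budget for [prune_top_edges()]. Default (`NULL`)
#'   resolves to 10000 for file inputs and to [design_top_edges()] of the
#'   simulation config for simulated runs.
#' @param dpi_epsilon When non-`NULL`, [dpi_prune()] with this tolerance is
#'   applied before top-k pruning (off by default: the network is defined by
#'   pure MI ranking).
#' @param network_samples `"tumor"` (default) infers the network from tumor
#'   samples only, mirroring a single-cohort discovery design; `"all"` uses
#'   every sample.
#' @param fdr_threshold,lfc_threshold DEG thresholds (defaults 1e-5 and 1).
#' @param trials,seed,max_depth,min_split Module-search settings (see
#'   [build_hierarchy()]).
#' @param min_module_size,universe_policy Enrichment settings (see
#'   [enrich_modules()]).
#' @param component_floor Components smaller than this are censused but not
#'   partitioned or enriched (default 3).
#' @param out_dir Output directory (created if missing).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression = NULL, conditions = NULL, gmt = NULL,
                            simulate = NULL, top_edges = NULL,
                            dpi_epsilon = NULL, network_samples = c("tumor", "all"),
                            fdr_threshold = 1e-5, lfc_threshold = 1,
                            trials = 10, seed = 1L, max_depth = 5,
                            min_split = 3, min_module_size = 5,
                            universe_policy = "network", component_floor = 3,
                            out_dir = tempfile("coexmap_run_")) {
  network_samples <- match.arg(network_samples)
  if (is.null(simulate) && is.null(expression)) {
    stop("either an expression matrix or a simulation config is required")
  }
  if (!is.null(expression) && !file.exists(expression)) {
    stop("expression file not found: ", expression)
  }
  if (fdr_threshold <= 0 || lfc_threshold <= 0) stop("thresholds must be positive")
  structure(
    list(expression = expression, conditions = conditions, gmt = gmt,
         simulate = simulate, top_edges = top_edges,
         dpi_epsilon = dpi_epsilon, network_samples = network_samples,
         fdr_threshold = fdr_threshold, lfc_threshold = lfc_threshold,
         trials = trials, seed = as.integer(seed), max_depth = max_depth,
         min_split = min_split, min_module_size = min_module_size,
         universe_policy = universe_policy, component_floor = component_floor,
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

stage_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order, writing every stage's outputs under
#' `config$out_dir`: `expression.tsv` / `conditions.tsv` / `truth.json` /
#' `sets.gmt` (simulated runs), `edges.tsv` + `network.sif`, `deg.tsv`,
#' one `component_XX.tree` / `.json` per analyzed component,
#' `enrichment.tsv`, `module_expression.tsv`, and `report.json`. Identical
#' config and seed give byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log one line per stage.
#' @return A report bundle (list): `census`, `trees`, `enrichment`,
#'   `module_expression`, `degs`, `network`, and (simulated runs) `truth`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  t0 <- Sys.time()

  # --- stage: data -----------------------------------------------------
  truth <- NULL
  sets <- NULL
  if (!is.null(config$simulate)) {
    sim <- simulate_expression(config$simulate, seed = config$seed)
    data <- sim$data
    truth <- sim$truth
    sets <- generate_gene_sets(
      truth, universe = data$gene_ids,
      decoy_size = min(25L, max(2L, length(data$gene_ids) %/% 4L)),
      seed = config$seed)
    truth$planted_sets <- sets
    write_expression_tsv(data, out("expression.tsv"), out("conditions.tsv"))
    write_truth_json(truth, out("truth.json"))
    write_gmt(sets, out("sets.gmt"))
    stage_log(verbose, "simulate", "%d genes x %d samples, %d gene sets",
              length(data$gene_ids), length(data$sample_ids), length(sets))
  } else {
    data <- read_expression_tsv(config$expression, config$conditions)
    if (!is.null(config$gmt)) sets <- read_gmt(config$gmt)
    stage_log(verbose, "load", "%d genes x %d samples",
              length(data$gene_ids), length(data$sample_ids))
  }

  # --- stage: MI network ----------------------------------------------
  net_samples <- NULL
  if (config$network_samples == "tumor" && !is.null(data$condition)) {
    net_samples <- data$sample_ids[data$condition == "tumor"]
  }
  mi_tab <- build_mi_table(data, samples = net_samples)
  if (!is.null(config$dpi_epsilon)) {
    before <- nrow(mi_tab)
    mi_tab <- dpi_prune(mi_tab, config$dpi_epsilon)
    stage_log(verbose, "dpi", "pruned %d of %d pairs", before - nrow(mi_tab), before)
  }
  top_edges <- config$top_edges %||%
    (if (!is.null(config$simulate)) design_top_edges(config$simulate) else 10000L)
  net <- prune_top_edges(mi_tab, k = top_edges)
  write_edge_list(net, out("edges.tsv"))
  write_sif(net, out("network.sif"))
  stage_log(verbose, "network", "%d nodes, %d edges (top %d of %d pairs)",
            length(net$nodes), nrow(net$edges), top_edges, nrow(mi_tab))

  # --- stage: differential expression ---------------------------------
  degs <- NULL
  if (!is.null(data$condition) && min(table(data$condition)) >= 2) {
    degs <- run_diff_expression(data, config$fdr_threshold, config$lfc_threshold)
    write_deg_table(degs, out("deg.tsv"))
    stage_log(verbose, "deg", "%d of %d genes called (FDR < %g, |log2FC| > %g)",
              sum(degs$is_deg), nrow(degs), config$fdr_threshold,
              config$lfc_threshold)
  } else {
    warning("missing or degenerate condition labels: DE overlay skipped")
  }

  # --- stage: components + hierarchy ----------------------------------
  comps <- connected_components(net)
  sizes <- lengths(comps)
  census <- list(
    n_nodes = length(net$nodes),
    n_edges = nrow(net$edges),
    n_components = length(comps),
    component_sizes = sizes,
    n_two_node_islands = sum(sizes == 2),
    giant_share = if (length(sizes)) max(sizes) / length(net$nodes) else 0,
    analyzed = which(sizes >= config$component_floor)
  )
  stage_log(verbose, "components", "%d components; giant %d/%d nodes; %d analyzed",
            census$n_components, if (length(sizes)) max(sizes) else 0,
            census$n_nodes, length(census$analyzed))

  node_index <- setNames(seq_along(net$nodes), net$nodes)
  trees <- list()
  enrich_all <- list()
  modexpr_all <- list()
  for (ci in census$analyzed) {
    comp <- comps[[ci]]
    tree <- build_hierarchy(net, comp, trials = config$trials,
                            seed = derive_seed(config$seed, 200L + ci),
                            max_depth = config$max_depth,
                            min_split = config$min_split)
    pr <- pagerank(net, comp)
    tree <- label_modules(tree, pr)
    rates <- visit_rates(net, comp)
    write_tree_file(tree, rates, out(sprintf("component_%02d.tree", ci)),
                    node_index = node_index)
    write_tree_json(tree, out(sprintf("component_%02d.json", ci)))
    trees[[as.character(ci)]] <- tree
    annotated <- unique(unlist(sets, use.names = FALSE))
    if (!is.null(sets) &&
        (config$universe_policy == "annotation" ||
         length(intersect(comp, annotated)) > 0)) {
      et <- enrich_modules(tree, sets, universe_policy = config$universe_policy,
                           min_module_size = config$min_module_size)
      if (nrow(et) > 0) {
        et <- cbind(component = ci, et)
        enrich_all[[length(enrich_all) + 1L]] <- et
      }
    }
    if (!is.null(degs)) {
      me <- summarize_module_expression(tree, degs)
      modexpr_all[[length(modexpr_all) + 1L]] <- cbind(component = ci, me)
    }
  }
  stage_log(verbose, "modules", "%d trees built", length(trees))

  enrichment <- if (length(enrich_all)) do.call(rbind, enrich_all) else NULL
  if (!is.null(enrichment)) write_enrichment_tsv(enrichment, out("enrichment.tsv"))
  module_expression <- if (length(modexpr_all)) do.call(rbind, modexpr_all) else NULL
  if (!is.null(module_expression)) {
    write.table(module_expression, out("module_expression.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  # --- stage: report ---------------------------------------------------
  stopifnot(sum(census$component_sizes) == census$n_nodes)   # census identity
  provenance <- list(
    package = "coexmap",
    version = as.character(packageVersion("coexmap")),
    seed = config$seed,
    top_edges = top_edges,
    dpi_epsilon = config$dpi_epsilon,
    network_samples = config$network_samples,
    fdr_threshold = config$fdr_threshold,
    lfc_threshold = config$lfc_threshold,
    trials = config$trials, max_depth = config$max_depth,
    min_split = config$min_split, min_module_size = config$min_module_size,
    universe_policy = config$universe_policy,
    component_floor = config$component_floor,
    simulated = !is.null(config$simulate)
  )
  report <- list(census = census, provenance = provenance)
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  stage_log(verbose, "done", "outputs in %s (%.1f s)", config$out_dir,
            as.numeric(difftime(Sys.time(), t0, units = "secs")))

  invisible(list(census = census, trees = trees, enrichment = enrichment,
                 module_expression = module_expression, degs = degs,
                 network = net, truth = truth, provenance = provenance,
                 out_dir = config$out_dir))
}

#' Global gene partitions implied by a set of component trees
#'
#' The first level of network modularity is its connected components; when a
#' component's tree has supermodule structure (depth >= 2), its top-level
#' modules refine the component at level 1. Level 2 is the leaf-module
#' partition. Both partitions are global: module paths are prefixed with the
#' component id.
#'
#' @param trees Named list of `module_tree`s, as in the `trees` element of a
#'   [run_pipeline()] report bundle.
#' @return List with named character vectors `level1` and `level2`
#'   (gene -> group id).
#' @export
global_partitions <- function(trees) {
  lv1 <- character(0); lv2 <- character(0)
  for (nm in names(trees)) {
    tr <- trees[[nm]]
    if (tree_depth(tr) >= 2) {
      p1 <- tree_partition(tr, 1L)
      lv1[names(p1)] <- paste0(nm, "/", p1)
    } else {
      lv1[tr$genes] <- nm
    }
    p2 <- tree_leaf_partition(tr)
    lv2[names(p2)] <- paste0(nm, "/", p2)
  }
  list(level1 = lv1, level2 = lv2)
}

#' Per-module differential-expression summary
#'
#' For every module of the tree: the median log2 fold change of its genes
#' (NA when no gene is covered by the DEG table), and the fractions of
#' members called up (`is_deg` and log2FC > 0), called down, and unclassified
#' (absent from the DEG table).
#'
#' @param tree A `module_tree`.
#' @param degs A `deg_table` with `is_deg` (see [call_degs()]); may cover
#'   only part of the tree's genes.
#' @return `data.frame`: `module_path`, `module_label`, `n_genes`,
#'   `median_log2fc`, `frac_up`, `frac_down`, `frac_unclassified`.
#' @export
summarize_module_expression <- function(tree, degs) {
  idx <- if (is.null(degs) || nrow(degs) == 0) integer(0) else
    setNames(seq_len(nrow(degs)), degs$gene)
  rows <- lapply(tree_nodes(tree, include_root = TRUE), function(node) {
    g <- node$genes
    hit <- idx[intersect(g, names(idx))]
    n_up <- if (length(hit)) sum(degs$is_deg[hit] & degs$log2fc[hit] > 0) else 0L
    n_dn <- if (length(hit)) sum(degs$is_deg[hit] & degs$log2fc[hit] < 0) else 0L
    data.frame(
      module_path = node$path,
      module_label = node$label %||% NA_character_,
      n_genes = length(g),
      median_log2fc = if (length(hit)) median(degs$log2fc[hit]) else NA_real_,
      frac_up = n_up / length(g),
      frac_down = n_dn / length(g),
      frac_unclassified = (length(g) - length(hit)) / length(g),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
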