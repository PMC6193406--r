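#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` containing `K` annotated ones. Computed by log-gamma
#' arithmetic (log binomial coefficients combined with log-sum-exp) for
#' numerical stability at large parameters.
#'
#' @param k Observed overlap (`0 <= k <= min(K, n)`).
#' @param K Annotated genes in the universe.
#' @param n Module size (draw size).
#' @param N Universe size (`K, n <= N`).
#' @return The tail probability in (0, 1\].
#' @examples
#' hypergeom_tail(3, 5, 8, 20)   # 37310/125970
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k < 0 || k > min(K, n)) stop("k must lie in [0, min(K, n)]")
  if (k == 0) return(1)
  i <- k:min(K, n)
  lg <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(1, exp(logsumexp(lg)))
}

#' Read and write GMT gene-set collections
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' member genes.
#'
#' @param path File path.
#' @param sets Named list of character vectors.
#' @param descriptions Optional named descriptions (defaults to the set name).
#' @return `read_gmt` returns a named list of character vectors with a
#'   `descriptions` attribute; `write_gmt` returns `path` invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  attr(sets, "descriptions") <- setNames(vapply(parts, `[`, "", 2L), names(sets))
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions)) {
      descriptions[[nm]]
    } else nm
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation of gene sets in tree modules
#'
#' Every module and submodule of the tree (at any depth) with at least
#' `min_module_size` annotated members is tested against every gene set with
#' at least one universe member, using [hypergeom_tail()]. BH adjustment is
#' applied separately within each hierarchy depth, because module-level and
#' submodule-level enrichments are separate analyses.
#'
#' @param tree A `module_tree` (labeled trees carry their label through).
#' @param sets Named list of character vectors (e.g. from [read_gmt()] or
#'   [generate_gene_sets()]).
#' @param universe_policy `"network"`: the universe is the component's genes
#'   possessing at least one annotation; `"annotation"`: all annotated genes.
#' @param min_module_size Smallest number of annotated module members tested.
#' @param fdr_threshold Significance threshold on q stored in `significant`.
#' @return `data.frame` of class `enrichment_table` with columns
#'   `module_path`, `module_label`, `depth`, `set`, `k`, `K`, `n`, `N`, `p`,
#'   `q`, `significant`, sorted by (module path, q).
#' @export
enrich_modules <- function(tree, sets,
                           universe_policy = c("network", "annotation"),
                           min_module_size = 5, fdr_threshold = 0.05) {
  universe_policy <- match.arg(universe_policy)
  if (length(sets) == 0) stop("empty gene-set collection")
  annotated <- unique(unlist(sets, use.names = FALSE))
  universe <- switch(universe_policy,
    network = intersect(tree$genes, annotated),
    annotation = annotated
  )
  if (length(universe) == 0) stop("empty universe under policy ", universe_policy)
  N <- length(universe)
  set_in_univ <- lapply(sets, intersect, universe)
  Ks <- lengths(set_in_univ)
  keep_sets <- names(sets)[Ks >= 1]          # sets disjoint from universe are skipped

  rows <- list()
  for (node in tree_nodes(tree)) {
    depth <- attr(node, "depth")
    mod_univ <- intersect(node$genes, universe)
    n <- length(mod_univ)
    if (n < min_module_size) next
    for (nm in keep_sets) {
      k <- length(intersect(set_in_univ[[nm]], mod_univ))
      rows[[length(rows) + 1L]] <- data.frame(
        module_path = node$path,
        module_label = node$label %||% NA_character_,
        depth = depth,
        set = nm,
        k = k, K = Ks[[nm]], n = n, N = N,
        p = hypergeom_tail(k, Ks[[nm]], n, N),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(module_path = character(0), module_label = character(0),
                      depth = integer(0), set = character(0), k = integer(0),
                      K = integer(0), n = integer(0), N = integer(0),
                      p = numeric(0), q = numeric(0), significant = logical(0))
    class(out) <- c("enrichment_table", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (d in unique(out$depth)) {
    sel <- out$depth == d
    out$q[sel] <- bh_adjust(out$p[sel])
  }
  out$significant <- out$q < fdr_threshold
  out <- out[order(out$module_path, out$q, out$set), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Write an enrichment table as TSV
#'
#' @param table An `enrichment_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
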