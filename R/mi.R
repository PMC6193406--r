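#' Mutual information between two expression profiles
#'
#' Rank-based estimator: both vectors are rank-transformed, discretized into
#' `B = max(2, floor(n^(1/3)))` equal-frequency bins, and the plug-in MI of
#' the joint histogram is computed with the Miller-Madow bias correction,
#' clamped at zero. Ranks make the estimate exactly invariant to strictly
#' monotone transforms of either input. Units are nats.
#'
#' @param x,y Numeric vectors of equal length `n >= 20` with finite values.
#' @return Nonnegative MI estimate in nats. A constant input yields 0 with a
#'   warning (degenerate but not an error: uninformative genes simply fail to
#'   enter the network).
#' @examples
#' set.seed(1)
#' z <- rnorm(500); y <- 0.8 * z + 0.6 * rnorm(500)
#' estimate_mi(z, y)
#' @export
estimate_mi <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("length mismatch")
  if (n < 20) stop("need at least 20 samples")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (min(x) == max(x) || min(y) == max(y)) {
    warning("constant vector: MI set to 0")
    return(0)
  }
  B <- mi_bins(n)
  mi_from_bins(bin_ranks(x, B), bin_ranks(y, B), n, B)
}

mi_bins <- function(n) max(2L, as.integer(floor(n^(1 / 3) + 1e-9)))

# Equal-frequency bin index in 1..B from ranks; ties broken by position so the
# map is deterministic and monotone-invariant.
bin_ranks <- function(x, B) {
  n <- length(x)
  as.integer(ceiling(rank(x, ties.method = "first") * B / n))
}

mi_from_bins <- function(bx, by, n, B) {
  cnt <- tabulate((bx - 1L) * B + by, B * B)
  nz <- cnt[cnt > 0L] / n
  px <- tabulate(bx, B) / n
  py <- tabulate(by, B) / n
  px <- px[px > 0]
  py <- py[py > 0]
  mi <- -sum(px * log(px)) - sum(py * log(py)) + sum(nz * log(nz))
  mm <- (length(px) - 1) / (2 * n) + (length(py) - 1) / (2 * n) -
    (length(nz) - 1) / (2 * n)
  max(0, mi + mm)
}

#' All-pairs mutual information table
#'
#' Computes [estimate_mi()] for every unordered gene pair (genes are binned
#' once, so the table is exactly consistent with pairwise calls). Pairs are
#' stored with `gene_a < gene_b` lexicographically.
#'
#' @param data An [expression_dataset()].
#' @param subset Optional character vector restricting to a gene subset.
#' @param samples Optional sample ids (or logical/integer index) selecting the
#'   samples the MI is computed on.
#' @return A `data.frame` of class `mi_table` with columns
#'   `gene_a`, `gene_b`, `mi`.
#' @export
build_mi_table <- function(data, subset = NULL, samples = NULL) {
  m <- data$matrix
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  if (!is.null(subset)) {
    missing <- setdiff(subset, rownames(m))
    if (length(missing)) stop("unknown genes in subset: ", paste(head(missing), collapse = ", "))
    m <- m[subset, , drop = FALSE]
  }
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids")
  g <- nrow(m)
  if (g < 2) stop("need at least 2 genes")
  n <- ncol(m)
  if (n < 20) stop("need at least 20 samples")
  B <- mi_bins(n)

  genes <- rownames(m)
  ord <- order(genes)            # lexicographic gene order => gene_a < gene_b
  m <- m[ord, , drop = FALSE]
  genes <- genes[ord]

  const <- apply(m, 1L, function(r) min(r) == max(r))
  if (any(const)) warning("constant gene(s): MI set to 0 for their pairs")
  bins <- matrix(0L, g, n)
  for (i in seq_len(g)) bins[i, ] <- bin_ranks(m[i, ], B)

  npair <- g * (g - 1L) / 2L
  ia <- integer(npair); ib <- integer(npair); mi <- numeric(npair)
  pos <- 0L
  for (i in seq_len(g - 1L)) {
    bi <- bins[i, ]
    for (j in (i + 1L):g) {
      pos <- pos + 1L
      ia[pos] <- i; ib[pos] <- j
      mi[pos] <- if (const[i] || const[j]) 0 else mi_from_bins(bi, bins[j, ], n, B)
    }
  }
  structure(
    data.frame(gene_a = genes[ia], gene_b = genes[ib], mi = mi,
               stringsAsFactors = FALSE),
    class = c("mi_table", "data.frame")
  )
}

#' Data-processing-inequality pruning of an MI table
#'
#' For every triangle `(i, j, k)` present in the table, the edge `(i, j)` is
#' marked for removal when `mi(i,j) < min(mi(i,k), mi(j,k)) * (1 - epsilon)`;
#' all marked edges are removed simultaneously after scanning every triangle,
#' so the strongest edge of a triangle is never removed.
#'
#' @param table An `mi_table` (see [build_mi_table()]).
#' @param epsilon Tolerance in \[0,1\]; `epsilon = 1` disables removal.
#' @return The pruned `mi_table`.
#' @export
dpi_prune <- function(table, epsilon = 0) {
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0,1]")
  genes <- sort(unique(c(table$gene_a, table$gene_b)))
  g <- length(genes)
  M <- matrix(0, g, g, dimnames = list(genes, genes))
  ia <- match(table$gene_a, genes)
  ib <- match(table$gene_b, genes)
  M[cbind(ia, ib)] <- table$mi
  M[cbind(ib, ia)] <- table$mi
  present <- matrix(FALSE, g, g)
  present[cbind(ia, ib)] <- TRUE
  present[cbind(ib, ia)] <- TRUE

  drop <- logical(nrow(table))
  for (e in seq_len(nrow(table))) {
    i <- ia[e]; j <- ib[e]
    common <- which(present[i, ] & present[j, ])
    common <- common[common != i & common != j]
    if (length(common) == 0) next
    indirect <- pmin(M[i, common], M[j, common])
    drop[e] <- any(table$mi[e] < indirect * (1 - epsilon))
  }
  out <- table[!drop, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("mi_table", "data.frame"))
}

#' Keep the top-k MI pairs as the transcriptional network
#'
#' The network the downstream modular analysis runs on is the `k` highest-MI
#' pairs (all pairs if fewer exist). Ties at the cutoff are broken
#' lexicographically by `(gene_a, gene_b)` for cross-platform reproducibility.
#' Genes with no surviving edge are excluded from the network.
#'
#' @param table An `mi_table`.
#' @param k Edge budget (default 10000, the conventional cutoff for this
#'   analysis).
#' @return A [gene_network()].
#' @export
prune_top_edges <- function(table, k = 10000) {
  if (nrow(table) == 0) stop("empty MI table")
  if (k < 1) stop("k must be >= 1")
  ord <- order(-table$mi, table$gene_a, table$gene_b)
  keep <- ord[seq_len(min(k, nrow(table)))]
  edges <- table[sort(keep), , drop = FALSE]
  edges <- edges[edges$mi > 0, , drop = FALSE]
  rownames(edges) <- NULL
  gene_network(edges)
}

#' Read / write MI edge lists
#'
#' TSV columns `gene_a`, `gene_b`, `mi` (6 decimal places) with one header
#' line; the SIF flavor writes `gene_a mi gene_b` without a header for graph
#' viewers.
#'
#' @param x An `mi_table` or [gene_network()].
#' @param path File path.
#' @return `path` (writers, invisibly) or an `mi_table` (reader).
#' @export
write_edge_list <- function(x, path) {
  edges <- if (inherits(x, "gene_network")) x$edges else x
  out <- data.frame(gene_a = edges$gene_a, gene_b = edges$gene_b,
                    mi = sprintf("%.6f", edges$mi))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$mi <- as.numeric(df$mi)
  structure(df, class = c("mi_table", "data.frame"))
}

#' @rdname write_edge_list
#' @export
write_sif <- function(x, path) {
  edges <- if (inherits(x, "gene_network")) x$edges else x
  lines <- sprintf("%s\t%.6f\t%s", edges$gene_a, edges$mi, edges$gene_b)
  writeLines(lines, path)
  invisible(path)
}
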