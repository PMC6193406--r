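#' Expression dataset container
#'
#' Bundles a genes-by-samples matrix of log2 expression values with sample
#' condition labels. This is the common input of the network-inference and
#' differential-expression stages.
#'
#' @param matrix Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are used as gene and sample identifiers unless `gene_ids` /
#'   `sample_ids` are given.
#' @param condition Character or factor vector, one of `"tumor"`/`"normal"`
#'   per sample, or `NULL` when no contrast is available.
#' @param gene_ids,sample_ids Optional identifier vectors overriding dimnames.
#' @return An object of class `expression_dataset`: a list with elements
#'   `matrix`, `gene_ids`, `sample_ids`, `condition`.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' expression_dataset(m, condition = c("tumor", "tumor", "tumor", "normal", "normal"))
#' @export
expression_dataset <- function(matrix, condition = NULL,
                               gene_ids = rownames(matrix),
                               sample_ids = colnames(matrix)) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("`matrix` must be a numeric matrix (genes x samples)")
  }
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample identifiers are required (dimnames or explicit)")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(matrix) || length(sample_ids) != ncol(matrix)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (!is.null(condition)) {
    condition <- as.character(condition)
    if (length(condition) != ncol(matrix)) {
      stop("every sample needs a condition label")
    }
    if (!all(condition %in% c("tumor", "normal"))) {
      stop("condition labels must be 'tumor' or 'normal'")
    }
    names(condition) <- sample_ids
  }
  dimnames(matrix) <- list(gene_ids, sample_ids)
  structure(
    list(matrix = matrix, gene_ids = gene_ids, sample_ids = sample_ids,
         condition = condition),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  if (!is.null(x$condition)) {
    tab <- table(x$condition)
    cat("  conditions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read / write expression matrices and condition labels as TSV
#'
#' The expression TSV has gene ids in the first column (`gene`) and one column
#' per sample; the condition TSV has columns `sample` and `condition`.
#'
#' @param data An [expression_dataset()].
#' @param path,cond_path File paths. `cond_path` may be `NULL` to skip labels.
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns an [expression_dataset()].
#' @export
write_expression_tsv <- function(data, path, cond_path = NULL) {
  # %.17g survives the decimal round-trip exactly, so downstream stages are
  # byte-reproducible whether they start from memory or from this file
  chr <- matrix(sprintf("%.17g", data$matrix), nrow(data$matrix),
                dimnames = dimnames(data$matrix))
  df <- data.frame(gene = data$gene_ids, chr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cond_path) && !is.null(data$condition)) {
    write.table(
      data.frame(sample = data$sample_ids, condition = unname(data$condition)),
      cond_path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, cond_path = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  condition <- NULL
  if (!is.null(cond_path)) {
    cd <- read.delim(cond_path, stringsAsFactors = FALSE)
    condition <- cd$condition[match(colnames(m), cd$sample)]
    if (anyNA(condition)) stop("condition file does not cover all samples")
  }
  expression_dataset(m, condition = condition)
}
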