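#' Module trees
#'
#' A `module_tree` is the nested partition of one connected component:
#' the root covers the component, internal nodes are modules/submodules with
#' colon-separated 1-based path addresses (`"1"`, `"1:2"`, ...), and each
#' node's children partition its gene set. Nodes carry their member genes,
#' their codebook contribution to the hierarchical codelength (bits), and --
#' after [label_modules()] -- a label gene.
#'
#' @param genes Character vector of member genes.
#' @param children `NULL` for a leaf module, else list of child nodes.
#' @param path Path address string (root uses `"root"`).
#' @return A tree node (list with class `module_node`; the root additionally
#'   has class `module_tree`).
#' @keywords internal
new_module_node <- function(genes, children = NULL, path = NA_character_) {
  structure(
    list(path = path, genes = sort(genes), children = children,
         label = NA_character_, codelength = NA_real_),
    class = "module_node"
  )
}

# Assign path addresses ("1", "1:2", ...) below the root.
assign_paths <- function(node, prefix = NULL) {
  if (!is.null(node$children)) {
    for (i in seq_along(node$children)) {
      p <- if (is.null(prefix)) as.character(i) else paste(prefix, i, sep = ":")
      node$children[[i]]$path <- p
      node$children[[i]] <- assign_paths(node$children[[i]], p)
    }
  }
  node
}

#' Flatten a module tree
#'
#' @param tree A `module_tree`.
#' @param include_root Include the root node?
#' @return List of nodes in depth-first order; each has a `depth` attribute
#'   (root = 0).
#' @export
tree_nodes <- function(tree, include_root = FALSE) {
  out <- list()
  walk <- function(node, depth) {
    attr(node, "depth") <- depth
    if (depth > 0 || include_root) out[[length(out) + 1L]] <<- node
    for (ch in node$children %||% list()) walk(ch, depth + 1L)
  }
  walk(tree, 0L)
  out
}

#' @rdname tree_nodes
#' @export
tree_depth <- function(tree) {
  nodes <- tree_nodes(tree)
  if (length(nodes) == 0) 0L else max(vapply(nodes, attr, 0L, "depth"))
}

#' Gene partitions implied by a module tree
#'
#' `tree_partition(tree, depth)` cuts the tree at a depth: every gene is
#' assigned the path of its ancestor at that depth (or of its deepest
#' available module when the branch is shallower). `tree_leaf_partition()`
#' assigns each gene its leaf module path.
#'
#' @param tree A `module_tree`.
#' @param depth Cut depth (1 = top-level modules).
#' @return Named character vector: gene -> module path.
#' @export
tree_partition <- function(tree, depth = 1L) {
  out <- character(0)
  walk <- function(node, d) {
    if (d == depth || is.null(node$children)) {
      out[node$genes] <<- node$path
    } else {
      for (ch in node$children) walk(ch, d + 1L)
    }
  }
  for (ch in tree$children %||% list()) walk(ch, 1L)
  out
}

#' @rdname tree_partition
#' @export
tree_leaf_partition <- function(tree) {
  out <- character(0)
  walk <- function(node) {
    if (is.null(node$children)) out[node$genes] <<- node$path
    else for (ch in node$children) walk(ch)
  }
  for (ch in tree$children %||% list()) walk(ch)
  out
}

validate_module_tree <- function(tree, component = NULL) {
  check <- function(node) {
    if (!is.null(node$children)) {
      kid_genes <- unlist(lapply(node$children, `[[`, "genes"))
      if (anyDuplicated(kid_genes)) stop("children overlap in tree node ", node$path)
      if (!setequal(kid_genes, node$genes)) {
        stop("children do not partition node ", node$path)
      }
      for (ch in node$children) check(ch)
    }
  }
  check(tree)
  if (!is.null(component) && !setequal(tree$genes, component)) {
    stop("tree does not cover the component")
  }
  invisible(TRUE)
}

#' @export
print.module_tree <- function(x, ...) {
  nodes <- tree_nodes(x)
  cat(sprintf("module_tree: %d genes, %d modules, depth %d, codelength %.4f bits\n",
              length(x$genes), length(nodes), tree_depth(x),
              x$codelength))
  invisible(x)
}

#' Write a module tree in Infomap-style .tree format
#'
#' One line per gene: `path flow "gene" node_index`, where `path` is the leaf
#' module address extended with the gene's 1-based position inside the module
#' (ordered by decreasing flow), and `flow` is the gene's visit rate within
#' its component. Header lines are prefixed with `#`.
#'
#' @param tree A `module_tree`.
#' @param rates Visit rates covering the tree's genes (see [visit_rates()]).
#' @param path Output file path.
#' @param node_index Optional named integer vector mapping genes to a stable
#'   network-wide index (defaults to position in the sorted component).
#' @return `path`, invisibly.
#' @export
write_tree_file <- function(tree, rates, path, node_index = NULL) {
  genes <- tree$genes
  if (is.null(node_index)) node_index <- setNames(seq_along(genes), genes)
  leaf <- tree_leaf_partition(tree)
  lines <- c(sprintf("# codelength %.10f bits", tree$codelength),
             "# path flow name node_index")
  for (node in tree_nodes(tree)) {
    if (!is.null(node$children)) next
    g <- node$genes[order(-rates[node$genes], node$genes)]
    lines <- c(lines, sprintf("%s:%d %.8f \"%s\" %d",
                              node$path, seq_along(g), rates[g], g,
                              node_index[g]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_tree_file
#' @export
read_tree_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, " ")
  data.frame(
    path = vapply(parts, `[`, "", 1L),
    flow = as.numeric(vapply(parts, `[`, "", 2L)),
    gene = gsub("\"", "", vapply(parts, `[`, "", 3L)),
    node_index = as.integer(vapply(parts, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

#' Serialize a module tree (with labels and codelengths) as JSON
#'
#' @param tree A `module_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  strip <- function(node) {
    out <- list(path = node$path, label = node$label,
                n_genes = length(node$genes),
                codelength = node$codelength)
    if (is.null(node$children)) out$genes <- node$genes
    else out$children <- lapply(node$children, strip)
    out
  }
  jsonlite::write_json(strip(tree), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
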