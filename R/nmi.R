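#' Normalized mutual information between two partitions
#'
#' `I(A; B) / mean(H(A), H(B))` (arithmetic normalization, the community-
#' detection convention): 1 for identical clusterings, ~0 for independent
#' ones. When both partitions are trivial (single cluster each) the NMI is
#' defined as 1.
#'
#' @param a,b Cluster labels. If named, they are aligned on their common
#'   names; otherwise they must be positionally aligned and equally long.
#' @return NMI in \[0, 1\].
#' @export
partition_nmi <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    if (length(common) == 0) stop("no common elements")
    a <- a[common]; b <- b[common]
  }
  if (length(a) != length(b)) stop("partitions must cover the same elements")
  n <- length(a)
  tab <- table(a, b)
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  ha <- -sum(plogp(pi_)); hb <- -sum(plogp(pj_))
  if (ha == 0 && hb == 0) return(1)
  expect <- outer(pi_, pj_)
  pos <- pij > 0
  mi <- sum(pij[pos] * log2(pij[pos] / expect[pos]))
  max(0, min(1, mi / ((ha + hb) / 2)))
}
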