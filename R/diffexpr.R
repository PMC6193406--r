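#' Per-gene two-group linear model
#'
#' Ordinary least squares for the one-factor model
#' `y_ij = mu + alpha_i + eps_j` (condition i in tumor/normal): per gene the
#' group means, the log2 fold change `mean(tumor) - mean(normal)`, the pooled
#' residual variance `s_g^2 = RSS / d_g`, and the residual degrees of freedom
#' `d_g = n_tumor + n_normal - 2`.
#'
#' @param data An [expression_dataset()] with both conditions present
#'   (>= 2 samples each).
#' @return `data.frame` of class `gene_stats`: `gene`, `mean_tumor`,
#'   `mean_normal`, `log2fc`, `s2`, `df`, plus `n_tumor`/`n_normal`
#'   attributes.
#' @export
fit_gene_models <- function(data) {
  if (is.null(data$condition)) stop("missing condition labels")
  tum <- data$condition == "tumor"
  nrm <- data$condition == "normal"
  nt <- sum(tum); nn <- sum(nrm)
  if (nt < 2 || nn < 2) stop("each condition needs at least 2 samples")
  mt <- rowMeans(data$matrix[, tum, drop = FALSE])
  mn <- rowMeans(data$matrix[, nrm, drop = FALSE])
  rss <- rowSums((data$matrix[, tum, drop = FALSE] - mt)^2) +
    rowSums((data$matrix[, nrm, drop = FALSE] - mn)^2)
  df <- nt + nn - 2L
  out <- data.frame(
    gene = data$gene_ids,
    mean_tumor = unname(mt),
    mean_normal = unname(mn),
    log2fc = unname(mt - mn),
    s2 = unname(rss / df),
    df = df,
    stringsAsFactors = FALSE
  )
  attr(out, "n_tumor") <- nt
  attr(out, "n_normal") <- nn
  class(out) <- c("gene_stats", "data.frame")
  out
}

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used by the moment estimator of the prior degrees of freedom.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in seq_len(100)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

#' Empirical-Bayes moderated t-statistics
#'
#' Shrinks per-gene residual variances toward a common prior value before
#' forming t-statistics. The prior degrees of freedom `d0` and prior variance
#' `s0^2` come from matching the first two moments of `log(s_g^2)` using the
#' digamma/trigamma identities of the scaled chi-square distribution: with
#' `e_g = log(s_g^2) - digamma(d_g/2) + log(d_g/2)`,
#' `trigamma(d0/2) = var(e) - mean(trigamma(d_g/2))` (prior df infinite when
#' the right-hand side is not positive, in which case all variances shrink
#' completely to `s0^2` and the reference distribution is normal), and
#' `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. The moderated variance
#' is `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)`; the moderated t is the two-sample
#' statistic with that variance and `d0 + d_g` degrees of freedom.
#'
#' @param stats A `gene_stats` table from [fit_gene_models()] (>= 10 genes).
#' @param d0 Optional override of the prior degrees of freedom; `0` gives the
#'   ordinary pooled t, `Inf` complete shrinkage.
#' @return `data.frame` of class `deg_table`: `gene`, `log2fc`, `s2_post`,
#'   `t`, `p`, with prior estimates in attributes `d0` and `s0_2`.
#' @export
ebayes_moderate <- function(stats, d0 = NULL) {
  if (nrow(stats) < 10 && is.null(d0)) {
    stop("moment estimation needs at least 10 genes")
  }
  nt <- attr(stats, "n_tumor"); nn <- attr(stats, "n_normal")
  s2 <- pmax(stats$s2, 1e-12)     # guard degenerate zero-variance genes
  dg <- stats$df
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  if (is.null(d0)) {
    if (length(unique(signif(s2, 12))) < 2) {
      stop("fewer than 2 distinct residual variances: moment matching is degenerate")
    }
    rhs <- var(e) - mean(trigamma(dg / 2))
    if (rhs <= 0) {
      d0 <- Inf
      s0_2 <- exp(mean(e))
    } else {
      d0 <- 2 * trigamma_inverse(rhs)
      s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
  } else {
    s0_2 <- exp(mean(e))
    if (is.finite(d0) && d0 > 0) {
      s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
  }
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2)) else {
    (d0 * s0_2 + dg * s2) / (d0 + dg)
  }
  tstat <- stats$log2fc / sqrt(s2_post * (1 / nt + 1 / nn))
  p <- 2 * pt(-abs(tstat), df = d0 + dg)
  out <- data.frame(
    gene = stats$gene,
    log2fc = stats$log2fc,
    s2_post = s2_post,
    t = tstat,
    p = p,
    stringsAsFactors = FALSE
  )
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the input
#' order.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return q-values in \[0, 1\], `q >= p` elementwise.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  m <- length(pvalues)
  if (m == 0) return(numeric(0))
  ord <- order(pvalues)
  q <- pvalues[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Call differentially expressed genes
#'
#' A gene is a DEG iff its BH q-value is below `fdr_threshold` and its
#' absolute log2 fold change exceeds `lfc_threshold`; defaults `1e-5` and `1`
#' (the thresholds of the analysis this package reproduces).
#'
#' @param table A `deg_table` from [ebayes_moderate()].
#' @param fdr_threshold,lfc_threshold Positive thresholds.
#' @return The table with columns `q` and `is_deg` added.
#' @export
call_degs <- function(table, fdr_threshold = 1e-5, lfc_threshold = 1) {
  if (fdr_threshold <= 0 || lfc_threshold <= 0) stop("thresholds must be positive")
  table$q <- bh_adjust(table$p)
  table$is_deg <- table$q < fdr_threshold & abs(table$log2fc) > lfc_threshold
  table
}

#' Differential expression in one call
#'
#' Convenience wrapper: [fit_gene_models()], [ebayes_moderate()],
#' [call_degs()].
#'
#' @inheritParams fit_gene_models
#' @inheritParams call_degs
#' @return A `deg_table` with `q` and `is_deg`.
#' @export
run_diff_expression <- function(data, fdr_threshold = 1e-5, lfc_threshold = 1) {
  call_degs(ebayes_moderate(fit_gene_models(data)),
            fdr_threshold = fdr_threshold, lfc_threshold = lfc_threshold)
}

#' Write a DEG table as TSV
#'
#' Columns: gene, log2FC, t, p, q, is_deg.
#'
#' @param table A `deg_table` with q-values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(table, path) {
  out <- data.frame(gene = table$gene, log2FC = table$log2fc, t = table$t,
                    p = table$p, q = table$q, is_deg = table$is_deg)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
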