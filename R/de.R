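#' Two-group differential expression between LS and NS cells
#'
#' Per gene: the fold change is `log2((mean_LS + 1) / (mean_NS + 1))` on
#' FPKM, the p-value comes from Welch's two-sample t-test on
#' log2(FPKM + 1), and multiple testing is corrected by Benjamini-Hochberg
#' over all tested genes. A gene is called differentially expressed when
#' `p_adj < alpha` and `|log2fc| > lfc_threshold` (defaults 0.05 and 2.5).
#' Differential genes are ranked by descending log2 fold change (ties broken
#' by ascending p-value, then gene id).
#'
#' Degenerate genes (zero variance in both groups with equal means) get
#' p = 1; zero variance with unequal means gives p = 0.
#'
#' @param x An [expression_matrix()] of FPKM values.
#' @param labels Character vector (`"LS"`/`"NS"`), one per cell, optionally
#'   named by cell id.
#' @param alpha Adjusted-p threshold for the DEG call (default 0.05,
#'   strict).
#' @param lfc_threshold Absolute log2-fold-change threshold (default 2.5,
#'   strict).
#' @return A data.frame (class `de_result`) with columns `gene_id`,
#'   `mean_ls`, `mean_ns`, `log2fc`, `p_value`, `p_adj`, `is_deg`, `rank`
#'   (rank among DEGs by descending log2fc; NA otherwise).
#' @export
de_test <- function(x, labels, alpha = 0.05, lfc_threshold = 2.5) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$value_kind != "fpkm")
    stop("`de_test()` expects FPKM values", call. = FALSE)
  cells <- colnames(x$values)
  if (!is.null(names(labels))) labels <- labels[cells]
  if (length(labels) != length(cells))
    stop("`labels` must give one label per cell", call. = FALSE)
  g1 <- labels == "LS"
  g2 <- labels == "NS"
  if (sum(g1) < 2 || sum(g2) < 2)
    stop("both groups need at least 2 cells", call. = FALSE)
  v <- x$values
  l <- log2(v + 1)
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(l[, g1, drop = FALSE])
  m2 <- rowMeans(l[, g2, drop = FALSE])
  v1 <- rowSums((l[, g1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((l[, g2, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  deg0 <- se2 == 0
  p[deg0] <- ifelse(m1[deg0] == m2[deg0], 1, 0)
  tstat[deg0] <- ifelse(m1[deg0] == m2[deg0], 0,
                        sign(m1[deg0] - m2[deg0]) * Inf)
  p_adj <- p.adjust(p, method = "BH")
  mean_ls <- rowMeans(v[, g1, drop = FALSE])
  mean_ns <- rowMeans(v[, g2, drop = FALSE])
  log2fc <- log2((mean_ls + 1) / (mean_ns + 1))
  res <- data.frame(gene_id = rownames(v), mean_ls = mean_ls,
                    mean_ns = mean_ns, log2fc = log2fc, p_value = p,
                    p_adj = p_adj,
                    is_deg = p_adj < alpha & abs(log2fc) > lfc_threshold,
                    rank = NA_integer_, stringsAsFactors = FALSE,
                    row.names = NULL)
  ranked <- rank_degs(res)
  res$rank[match(ranked$gene_id, res$gene_id)] <- seq_len(nrow(ranked))
  class(res) <- c("de_result", "data.frame")
  res
}

#' Rank differential genes by descending log2 fold change
#'
#' @param results A `de_result` from [de_test()].
#' @return The DEG rows ordered by descending `log2fc`, ties broken by
#'   ascending `p_value` then `gene_id` (stable); empty when there are no
#'   DEGs.
#' @export
rank_degs <- function(results) {
  d <- as.data.frame(results)[which(results$is_deg), , drop = FALSE]
  d[order(-d$log2fc, d$p_value, d$gene_id), , drop = FALSE]
}

#' Top expressed genes within a group
#'
#' Genes ordered by mean FPKM within the chosen group; ties are broken
#' deterministically by gene id.
#'
#' @param x An [expression_matrix()] of FPKM values.
#' @param labels Character vector of group labels, one per cell.
#' @param group Group to summarize (default `"LS"`).
#' @param n Number of genes to return (default 200).
#' @return Character vector of gene ids.
#' @export
top_expressed <- function(x, labels, group = "LS", n = 200) {
  stopifnot(inherits(x, "expression_matrix"))
  cells <- colnames(x$values)
  if (!is.null(names(labels))) labels <- labels[cells]
  sel <- labels == group
  if (!any(sel)) stop("group ", group, " is empty", call. = FALSE)
  m <- rowMeans(x$values[, sel, drop = FALSE])
  if (n > length(m)) {
    warning("`n` exceeds the gene count; returning all genes",
            call. = FALSE)
    n <- length(m)
  }
  rownames(x$values)[order(-m, rownames(x$values))][seq_len(n)]
}
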