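#' Welch's unpaired two-sample t-test
#'
#' Two-sided Welch test with Satterthwaite degrees of freedom, used for all
#' LS-vs-NS panel comparisons because the two groups have unequal variances.
#' When both groups are constant the test degenerates: p = 1 for equal
#' means, p = 0 otherwise.
#'
#' @param a,b Numeric vectors, each of length >= 2 with finite values.
#' @return A list with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("values must be finite", call. = FALSE)
  if (var(a) == 0 && var(b) == 0) {
    d <- mean(a) - mean(b)
    if (d == 0) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(d) * Inf, df = NA_real_, p = 0))
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Paired t-test on response counts
#'
#' Two-sided paired t-test on before/after event counts, used for
#' drug-treatment comparisons of spontaneous and evoked calcium responses.
#' Zero-variance differences degenerate: p = 1 when all differences are
#' zero, otherwise the direction is exact and p = 0.
#'
#' @param before,after Equal-length paired numeric vectors, n >= 2.
#' @return A list with `t`, `df`, `p`.
#' @export
paired_response_test <- function(before, after) {
  if (length(before) != length(after))
    stop("`before` and `after` must be paired (equal length)", call. = FALSE)
  n <- length(before)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- before - after
  if (sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = n - 1, p = 1))
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0))
  }
  ht <- t.test(before, after, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Significance stars
#'
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.001, empty otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "")))
}

#' Default ion-channel and receptor gene panels
#'
#' The curated panel table shipped with the package: one symbol-prefix
#' regular expression per panel (Na+/K+-ATPase, voltage-gated channel
#' families, ionotropic and metabotropic receptor families). The protocol
#' does not enumerate genes, so the table is configurable: pass any named
#' list of patterns or explicit gene-id vectors to [panel_compare()].
#'
#' @param path Path to a tab-separated file with columns `panel` and
#'   `pattern`; defaults to the table shipped in `inst/extdata/panels.tsv`.
#' @return Named list mapping panel name to a symbol-prefix regex.
#' @export
default_panels <- function(path = system.file("extdata", "panels.tsv",
                                              package = "vivoseq")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  setNames(as.list(tab$pattern), tab$panel)
}

#' Compare gene panels between LS and NS cells
#'
#' Resolves each panel to its member genes present in the matrix (a panel
#' given as a single `^`-anchored string is treated as a regex over gene
#' ids; otherwise as an explicit gene-id vector), aggregates member FPKM
#' per cell, and compares LS against NS with [welch_t()]. The default
#' aggregate is the per-cell sum over panel genes; `per_gene` tests every
#' member gene separately. Panels resolving to no genes are skipped with a
#' warning.
#'
#' @param x An [expression_matrix()] of FPKM values.
#' @param labels Character vector (`"LS"`/`"NS"`) per cell, optionally
#'   named by cell id.
#' @param panels Named list of panels; see [default_panels()].
#' @param aggregate `"sum"` (default) or `"per_gene"`.
#' @param adjust Add a BH-adjusted p-value column across rows
#'   (default TRUE).
#' @return Data.frame with one row per panel (or per gene) and columns
#'   `panel`, `gene`, `n_genes`, `mean_ls`, `sd_ls`, `mean_ns`, `sd_ns`,
#'   `t`, `df`, `p_value`, (`p_adj`,) `stars`.
#' @export
panel_compare <- function(x, labels, panels = default_panels(),
                          aggregate = c("sum", "per_gene"), adjust = TRUE) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$value_kind != "fpkm")
    stop("`panel_compare()` expects FPKM values", call. = FALSE)
  aggregate <- match.arg(aggregate)
  cells <- colnames(x$values)
  if (!is.null(names(labels))) labels <- labels[cells]
  ls <- labels == "LS"
  ns <- labels == "NS"
  if (sum(ls) < 2 || sum(ns) < 2)
    stop("both groups need at least 2 cells", call. = FALSE)
  rows <- list()
  for (nm in names(panels)) {
    spec <- panels[[nm]]
    genes <- if (is.character(spec) && length(spec) == 1 &&
                 startsWith(spec, "^"))
      grep(spec, rownames(x$values), value = TRUE)
    else intersect(spec, rownames(x$values))
    if (length(genes) == 0) {
      warning("panel ", nm, ": no member genes present; skipped",
              call. = FALSE)
      next
    }
    stats_for <- function(stat, gene) {
      w <- welch_t(stat[ls], stat[ns])
      data.frame(panel = nm, gene = gene, n_genes = length(genes),
                 mean_ls = mean(stat[ls]), sd_ls = sd(stat[ls]),
                 mean_ns = mean(stat[ns]), sd_ns = sd(stat[ns]),
                 t = w$t, df = w$df, p_value = w$p,
                 stringsAsFactors = FALSE)
    }
    if (aggregate == "sum") {
      stat <- colSums(x$values[genes, , drop = FALSE])
      rows[[length(rows) + 1]] <- stats_for(stat, NA_character_)
    } else {
      for (g in genes)
        rows[[length(rows) + 1]] <- stats_for(x$values[g, ], g)
    }
  }
  if (length(rows) == 0)
    return(data.frame(panel = character(0)))
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- p.adjust(out$p_value, method = "BH")
  out$stars <- significance_stars(out$p_value)
  rownames(out) <- NULL
  out
}
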