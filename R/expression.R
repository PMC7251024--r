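#' Genes x cells expression matrix with gene metadata
#'
#' Container for a genes-by-cells expression table carrying the per-gene
#' transcript length and biotype needed for FPKM normalization and the
#' protein-coding filter. `value_kind` records whether the values are raw
#' fragment counts or FPKM.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), cells
#'   in columns (colnames = cell ids), all values >= 0.
#' @param gene_length_bp Numeric vector of transcript lengths (bp), one per
#'   gene, all > 0.
#' @param biotype Character vector of gene biotypes (e.g. "protein_coding"),
#'   one per gene.
#' @param value_kind Either `"counts"` or `"fpkm"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_length_bp, biotype,
                              value_kind = c("counts", "fpkm")) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  if (nrow(values) > 0 && is.null(rownames(values)))
    stop("`values` must have gene rownames", call. = FALSE)
  if (ncol(values) > 0 && is.null(colnames(values)))
    stop("`values` must have cell colnames", call. = FALSE)
  if (any(values < 0)) stop("expression values must be >= 0", call. = FALSE)
  if (length(gene_length_bp) != nrow(values) ||
      length(biotype) != nrow(values))
    stop("`gene_length_bp` and `biotype` must have one entry per gene",
         call. = FALSE)
  if (any(gene_length_bp <= 0))
    stop("gene lengths must be positive", call. = FALSE)
  structure(list(values = values,
                 gene_length_bp = setNames(as.numeric(gene_length_bp),
                                           rownames(values)),
                 biotype = setNames(as.character(biotype), rownames(values)),
                 value_kind = value_kind),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells (%s)\n",
              nrow(x$values), ncol(x$values), x$value_kind))
  invisible(x)
}

#' Subset an expression matrix, keeping gene metadata in step
#'
#' @param x An [expression_matrix()].
#' @param i Gene index (integer, logical or gene ids).
#' @param j Cell index (integer, logical or cell ids).
#' @param ... Ignored.
#' @return An [expression_matrix()].
#' @export
`[.expression_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  expression_matrix(x$values[i, j, drop = FALSE],
                    gene_length_bp = x$gene_length_bp[i],
                    biotype = x$biotype[i],
                    value_kind = x$value_kind)
}

#' Normalize fragment counts to FPKM
#'
#' `fpkm[g, c] = count[g, c] * 1e9 / (length_bp[g] * total_counts[c])`:
#' fragments per kilobase of transcript per million mapped fragments.
#'
#' @param x An [expression_matrix()] of counts.
#' @return An [expression_matrix()] with `value_kind = "fpkm"`.
#' @export
compute_fpkm <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$value_kind != "counts")
    stop("`compute_fpkm()` expects fragment counts", call. = FALSE)
  lib <- colSums(x$values)
  if (any(lib == 0))
    stop("zero library size for cell(s): ",
         paste(colnames(x$values)[lib == 0], collapse = ", "), call. = FALSE)
  v <- x$values * 1e9 / x$gene_length_bp   # recycles per gene (rows)
  v <- sweep(v, 2, lib, "/")
  expression_matrix(v, x$gene_length_bp, x$biotype, value_kind = "fpkm")
}

#' Filter genes by biotype and detection
#'
#' Keeps protein-coding genes whose FPKM reaches `min_fpkm` (inclusive) in
#' at least one cell (`rule = "any"`, the default) or in every cell
#' (`rule = "all"`). Gene order is preserved.
#'
#' @param x An [expression_matrix()] of FPKM values.
#' @param min_fpkm Detection threshold (default 1, inclusive).
#' @param rule `"any"` (detected in >= 1 sample) or `"all"` (in every
#'   sample).
#' @param coding_only Restrict to protein-coding genes (default TRUE).
#' @return A filtered [expression_matrix()].
#' @export
filter_genes <- function(x, min_fpkm = 1, rule = c("any", "all"),
                         coding_only = TRUE) {
  stopifnot(inherits(x, "expression_matrix"))
  rule <- match.arg(rule)
  if (x$value_kind != "fpkm")
    stop("`filter_genes()` expects FPKM values", call. = FALSE)
  detected <- if (rule == "any")
    apply(x$values, 1, max) >= min_fpkm
  else
    apply(x$values, 1, min) >= min_fpkm
  keep <- detected & (!coding_only | x$biotype == "protein_coding")
  if (!any(keep)) warning("no genes pass the gene filter", call. = FALSE)
  x[keep, ]
}

#' Per-cell detected-gene counts
#'
#' Number of genes per cell with expression strictly greater than
#' `threshold` (per the "greater than 1 or 5 FPKM" convention).
#'
#' @param x An [expression_matrix()].
#' @param threshold Strict detection threshold (default 1).
#' @return Named integer vector, one count per cell.
#' @export
detected_genes <- function(x, threshold = 1) {
  stopifnot(inherits(x, "expression_matrix"), threshold > 0)
  colSums(x$values > threshold)
}

#' Per-cell expressed protein-coding gene counts
#'
#' Number of protein-coding genes per cell at or above `min_fpkm`
#' (inclusive); this is the quantity tested by the fewer-than-1,000-genes
#' cell filter.
#'
#' @param x An [expression_matrix()] of FPKM values.
#' @param min_fpkm Inclusive expression threshold (default 1).
#' @param coding_only Restrict to protein-coding genes (default TRUE).
#' @return Named integer vector, one count per cell.
#' @export
expressed_gene_counts <- function(x, min_fpkm = 1, coding_only = TRUE) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$value_kind != "fpkm")
    stop("`expressed_gene_counts()` expects FPKM values", call. = FALSE)
  rows <- if (coding_only) x$biotype == "protein_coding" else
    rep(TRUE, nrow(x$values))
  colSums(x$values[rows, , drop = FALSE] >= min_fpkm)
}

#' Staged metric-based cell filtering
#'
#' Removes cells in three ordered stages with strict thresholds exactly as
#' worded in the protocol: cDNA concentration below `cdna_min` pg/uL
#' (reason `cdna`), then mitochondrial fraction greater than `mito_max`
#' (reason `mito`), then fewer than `genes_min` expressed protein-coding
#' genes (reason `genes`). A cell with a missing metric is retained and
#' flagged rather than silently dropped.
#'
#' @param records Data.frame with columns `cell_id`, `cdna_pg_ul`,
#'   `mito_fraction`, `n_genes_detected`.
#' @param cdna_min cDNA threshold in pg/uL (default 1000; removal is
#'   strictly below).
#' @param mito_max Mitochondrial fraction threshold (default 0.25; removal
#'   is strictly above).
#' @param genes_min Detected-gene threshold (default 1000; removal is
#'   strictly below).
#' @return A list with `kept` (cell ids), `removed` (data.frame `cell_id`,
#'   `stage`, `reason`), `flagged` (data.frame of cells with missing
#'   metrics) and `stages` (per-stage in/removed/kept counts).
#' @export
filter_cells_metrics <- function(records, cdna_min = 1000, mito_max = 0.25,
                                 genes_min = 1000) {
  need <- c("cell_id", "cdna_pg_ul", "mito_fraction", "n_genes_detected")
  if (!all(need %in% names(records)))
    stop("`records` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  removed <- data.frame(cell_id = character(0), stage = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  flagged <- data.frame(cell_id = character(0), metric = character(0),
                        stringsAsFactors = FALSE)
  stages <- data.frame(stage = character(0), n_in = integer(0),
                       n_removed = integer(0), n_kept = integer(0),
                       stringsAsFactors = FALSE)
  current <- records
  run_stage <- function(stage, metric, fails) {
    miss <- is.na(current[[metric]])
    if (any(miss))
      flagged <<- rbind(flagged, data.frame(cell_id = current$cell_id[miss],
                                            metric = metric,
                                            stringsAsFactors = FALSE))
    out <- !miss & fails
    if (any(out))
      removed <<- rbind(removed,
                        data.frame(cell_id = current$cell_id[out],
                                   stage = stage, reason = stage,
                                   stringsAsFactors = FALSE))
    stages <<- rbind(stages, data.frame(stage = stage, n_in = nrow(current),
                                        n_removed = sum(out),
                                        n_kept = sum(!out),
                                        stringsAsFactors = FALSE))
    current <<- current[!out, , drop = FALSE]
  }
  run_stage("cdna", "cdna_pg_ul", current$cdna_pg_ul < cdna_min)
  run_stage("mito", "mito_fraction", current$mito_fraction > mito_max)
  run_stage("genes", "n_genes_detected",
            current$n_genes_detected < genes_min)
  list(kept = current$cell_id, removed = removed, flagged = flagged,
       stages = stages)
}

#' Multiplicative marker-gene doublet scores
#'
#' Per-cell products of FPKM values over mutually exclusive marker sets:
#' `s_astro = Gfap x S100b x Aqp4`, `s_oligo = Olig1 x Olig2 x Mbp`,
#' `s_ex = Slc17a7 x Neurod2`, `s_in = Gad1 x Gad2` and
#' `s_ex_in = s_ex x s_in`. A cell is flagged as a doublet when
#' `s_astro > 0`, `s_oligo > 0` (neuron contaminated by glia) or
#' `s_ex_in > 0` (co-expression of excitatory and inhibitory markers). A
#' marker gene absent from the matrix is treated as all-zero with a warning.
#'
#' @param x An [expression_matrix()] of FPKM values.
#' @return Data.frame with columns `cell_id`, `s_astro`, `s_oligo`, `s_ex`,
#'   `s_in`, `s_ex_in`, `is_doublet`.
#' @export
doublet_scores <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$value_kind != "fpkm")
    stop("`doublet_scores()` expects FPKM values", call. = FALSE)
  n <- ncol(x$values)
  grab <- function(sym) {
    if (sym %in% rownames(x$values)) x$values[sym, ] else {
      warning("marker gene ", sym, " absent; treated as zero",
              call. = FALSE)
      rep(0, n)
    }
  }
  prod_of <- function(set) Reduce(`*`, lapply(set, grab))
  s_astro <- prod_of(.marker_sets$astro)
  s_oligo <- prod_of(.marker_sets$oligo)
  s_ex <- prod_of(.marker_sets$ex)
  s_in <- prod_of(.marker_sets$inh)
  s_ex_in <- s_ex * s_in
  data.frame(cell_id = colnames(x$values),
             s_astro = unname(s_astro), s_oligo = unname(s_oligo),
             s_ex = unname(s_ex), s_in = unname(s_in),
             s_ex_in = unname(s_ex_in),
             is_doublet = unname(s_astro > 0 | s_oligo > 0 | s_ex_in > 0),
             stringsAsFactors = FALSE)
}

#' Run the full staged quality control
#'
#' Fixed stage order: FPKM normalization (when counts are supplied), gene
#' filtering (protein-coding, detected at >= `min_fpkm`), the three metric
#' cell filters, then marker-product doublet removal. Detected-gene counts
#' for the cell filter are recomputed from the FPKM matrix (protein-coding
#' genes at >= `min_fpkm`), superseding any counts in `records`.
#'
#' @param x An [expression_matrix()] (counts or FPKM).
#' @param records Per-cell QC metadata; see [filter_cells_metrics()]. The
#'   `n_genes_detected` column is optional.
#' @inheritParams filter_cells_metrics
#' @inheritParams filter_genes
#' @return A list with `report` (a `qc_report`: per-stage counts, removed
#'   cells with reasons, final kept set), `matrix` (the gene-filtered FPKM
#'   matrix restricted to kept cells), `doublet_scores` and
#'   `n_genes_detected`.
#' @export
run_qc <- function(x, records, cdna_min = 1000, mito_max = 0.25,
                   genes_min = 1000, min_fpkm = 1, rule = "any") {
  stopifnot(inherits(x, "expression_matrix"))
  if (!setequal(colnames(x$values), records$cell_id))
    stop("cell ids of `x` and `records` do not match", call. = FALSE)
  records <- records[match(colnames(x$values), records$cell_id), ,
                     drop = FALSE]
  fpkm <- if (x$value_kind == "counts") compute_fpkm(x) else x
  xf <- filter_genes(fpkm, min_fpkm = min_fpkm, rule = rule)
  nd <- expressed_gene_counts(fpkm, min_fpkm = min_fpkm)
  records$n_genes_detected <- as.integer(nd[records$cell_id])
  metric <- filter_cells_metrics(records, cdna_min = cdna_min,
                                 mito_max = mito_max, genes_min = genes_min)
  ds <- doublet_scores(xf[, metric$kept])
  glia <- ds$s_astro > 0 | ds$s_oligo > 0
  exin <- !glia & ds$s_ex_in > 0
  flagged_cells <- glia | exin
  doublet_removed <- data.frame(
    cell_id = ds$cell_id[flagged_cells],
    stage = rep("doublet", sum(flagged_cells)),
    reason = ifelse(glia[flagged_cells], "doublet_glia", "doublet_ex_in"),
    stringsAsFactors = FALSE)
  kept <- setdiff(metric$kept, doublet_removed$cell_id)
  stages <- rbind(metric$stages,
                  data.frame(stage = "doublet", n_in = length(metric$kept),
                             n_removed = nrow(doublet_removed),
                             n_kept = length(kept),
                             stringsAsFactors = FALSE))
  report <- structure(
    list(stages = stages,
         removed = rbind(metric$removed, doublet_removed),
         flagged = metric$flagged,
         kept_cells = kept,
         n_cells_in = ncol(x$values),
         n_genes_in = nrow(x$values),
         n_genes_kept = nrow(xf$values),
         thresholds = list(cdna_min = cdna_min, mito_max = mito_max,
                           genes_min = genes_min, min_fpkm = min_fpkm,
                           gene_filter = rule)),
    class = "qc_report")
  list(report = report, matrix = xf[, kept], doublet_scores = ds,
       n_genes_detected = nd)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Staged QC: %d cells in, %d kept; %d of %d genes kept\n",
              x$n_cells_in, length(x$kept_cells), x$n_genes_kept,
              x$n_genes_in))
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Cell-cell Pearson correlation structure of a cohort
#'
#' Pearson correlations between cells on log2(FPKM + 1), with the median
#' within-group correlation over off-diagonal pairs reported per label
#' group. Constant cells yield undefined correlations, which are recorded
#' as missing.
#'
#' @param x An [expression_matrix()] of FPKM values.
#' @param labels Character vector of group labels, one per cell (or named
#'   by cell id).
#' @return A list with `correlation` (symmetric cell x cell matrix, unit
#'   diagonal) and `median_within` (named vector of per-group medians).
#' @export
cohort_correlation <- function(x, labels) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$value_kind != "fpkm")
    stop("`cohort_correlation()` expects FPKM values", call. = FALSE)
  cells <- colnames(x$values)
  if (!is.null(names(labels))) labels <- labels[cells]
  if (length(labels) != length(cells))
    stop("`labels` must give one label per cell", call. = FALSE)
  groups <- unique(labels)
  if (any(table(labels) < 2))
    stop("every group needs at least 2 cells", call. = FALSE)
  l <- log2(x$values + 1)
  C <- suppressWarnings(cor(l))
  diag(C) <- 1
  med <- vapply(groups, function(g) {
    sub <- C[labels == g, labels == g]
    median(sub[lower.tri(sub)], na.rm = TRUE)
  }, numeric(1))
  list(correlation = C, median_within = setNames(med, groups))
}
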