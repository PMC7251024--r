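# Simplified weighted co-expression module analysis: soft-power adjacency,
# average-linkage gene dendrogram, scanned fixed-height cut with a size
# floor, eigengene merging, and module-trait correlation with the LS
# indicator appended as the "white" pseudo-module.

.module_palette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

#' Configuration for the co-expression module analysis
#'
#' @param soft_power Soft-thresholding power beta applied to the absolute
#'   correlation (default 6, the common unsigned-network default; the source
#'   protocol leaves it unstated).
#' @param min_cluster_size Minimum genes per module (default 10); smaller
#'   clusters are assigned to "grey" (unassigned).
#' @param merge_cor_threshold Modules whose eigengenes correlate above this
#'   value are merged (default 0.75).
#' @param use_tom Apply the topological-overlap transform to the adjacency
#'   before clustering (default FALSE).
#' @param max_cut_frac Candidate cut heights are restricted to below this
#'   fraction of the maximum merge height (default 0.99), so a cohort of
#'   mutually independent genes yields no modules rather than one giant one.
#' @return An object of class `module_config`.
#' @export
module_config <- function(soft_power = 6, min_cluster_size = 10,
                          merge_cor_threshold = 0.75, use_tom = FALSE,
                          max_cut_frac = 0.99) {
  if (!isTRUE(soft_power >= 1) || soft_power != round(soft_power))
    stop("`soft_power` must be a positive integer", call. = FALSE)
  if (!isTRUE(min_cluster_size >= 2))
    stop("`min_cluster_size` must be >= 2", call. = FALSE)
  if (!isTRUE(merge_cor_threshold >= 0) ||
      !isTRUE(merge_cor_threshold <= 1))
    stop("`merge_cor_threshold` must be in [0, 1]", call. = FALSE)
  structure(list(soft_power = soft_power,
                 min_cluster_size = min_cluster_size,
                 merge_cor_threshold = merge_cor_threshold,
                 use_tom = isTRUE(use_tom),
                 max_cut_frac = max_cut_frac),
            class = "module_config")
}

# log2(FPKM + 1) working matrix (genes x cells)
log_expr <- function(x, genes = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- if (x$value_kind == "fpkm") log2(x$values + 1) else
    stop("expected FPKM values", call. = FALSE)
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  v
}

#' Soft-power co-expression adjacency
#'
#' `a_ij = |pearson(g_i, g_j)|^beta` on log2(FPKM + 1), with unit diagonal;
#' optionally transformed to topological overlap. Constant genes get zero
#' correlation to everything, with a warning.
#'
#' @param x An [expression_matrix()] of FPKM values (typically restricted to
#'   the differential genes).
#' @param genes Optional gene ids to restrict to.
#' @param config A [module_config()].
#' @return Symmetric gene x gene adjacency matrix with values in [0, 1].
#' @export
build_adjacency <- function(x, genes = NULL, config = module_config()) {
  e <- log_expr(x, genes)
  if (nrow(e) < config$min_cluster_size)
    stop("need at least `min_cluster_size` genes", call. = FALSE)
  if (ncol(e) < 4) stop("need at least 4 cells", call. = FALSE)
  sds <- apply(e, 1, sd)
  if (any(sds == 0))
    warning("constant gene(s) assigned zero correlation: ",
            paste(utils::head(rownames(e)[sds == 0], 5), collapse = ", "),
            call. = FALSE)
  C <- suppressWarnings(cor(t(e)))
  C[!is.finite(C)] <- 0
  A <- abs(C)^config$soft_power
  diag(A) <- 1
  if (config$use_tom) A <- tom_similarity(A)
  A
}

# topological-overlap similarity of an adjacency matrix
tom_similarity <- function(A) {
  diag(A) <- 0
  L <- A %*% A
  k <- colSums(A)
  kmin <- outer(k, k, pmin)
  T <- (L + A) / (kmin + 1 - A)
  diag(T) <- 1
  dimnames(T) <- dimnames(A)
  T
}

#' Average-linkage gene dendrogram
#'
#' Hierarchical clustering of genes on the dissimilarity `1 - adjacency`
#' (or `1 - TOM`).
#'
#' @param adjacency Adjacency matrix from [build_adjacency()].
#' @return An `hclust` tree.
#' @export
cluster_genes <- function(adjacency) {
  hclust(as.dist(1 - adjacency), method = "average")
}

#' Cut the dendrogram into modules
#'
#' A simplified stand-in for dynamic tree cutting: candidate cut heights
#' (midpoints between merge heights, capped below `max_cut_frac` of the
#' maximum height) are scanned and the height maximizing the number of
#' clusters of at least `min_cluster_size` genes is chosen (highest such
#' height on ties, so module membership saturates before distinct modules
#' merge). Clusters below the size floor become "grey"
#' (unassigned). Modules whose eigengenes correlate above
#' `merge_cor_threshold` are then merged iteratively. Module colors are
#' assigned by decreasing module size from a fixed palette.
#'
#' @param dendro An `hclust` tree from [cluster_genes()].
#' @param x The [expression_matrix()] the tree was built from (used for
#'   eigengene-based merging).
#' @param config A [module_config()].
#' @return Named character vector (class `module_assignment`) mapping each
#'   gene to a module color, with `"grey"` meaning unassigned.
#' @export
cut_modules <- function(dendro, x, config = module_config()) {
  genes <- dendro$labels
  hmax <- max(dendro$height)
  h <- sort(unique(dendro$height))
  cand <- if (length(h) > 1) (h[-length(h)] + h[-1]) / 2 else numeric(0)
  cand <- c(cand, config$max_cut_frac * hmax)
  cand <- cand[cand <= config$max_cut_frac * hmax + 1e-12 & cand > 0]
  best_n <- 0L
  best_cl <- NULL
  for (lev in cand) {
    cl <- cutree(dendro, h = lev)
    nvalid <- sum(table(cl) >= config$min_cluster_size)
    # prefer the highest qualifying height so module membership saturates
    if (nvalid >= best_n && nvalid > 0) {
      best_n <- nvalid
      best_cl <- cl
    }
  }
  assignment <- setNames(rep("grey", length(genes)), genes)
  if (best_n > 0) {
    sizes <- table(best_cl)
    valid <- names(sizes)[sizes >= config$min_cluster_size]
    ord <- valid[order(-sizes[valid], as.integer(valid))]
    for (i in seq_along(ord))
      assignment[best_cl == as.integer(ord[i])] <- .module_palette[i]
    assignment <- merge_modules(assignment, x, config)
  }
  structure(assignment, class = "module_assignment")
}

# iteratively merge module pairs whose eigengenes correlate above threshold
merge_modules <- function(assignment, x, config) {
  repeat {
    mods <- setdiff(unique(assignment), "grey")
    if (length(mods) < 2) break
    ME <- module_eigengenes(x, assignment)
    C <- cor(ME)
    diag(C) <- -Inf
    top <- which(C == max(C), arr.ind = TRUE)[1, ]
    if (max(C) <= config$merge_cor_threshold) break
    a <- colnames(ME)[top[1]]
    b <- colnames(ME)[top[2]]
    # merged module takes the color of the larger member
    sizes <- table(assignment)
    keep <- if (sizes[a] >= sizes[b]) a else b
    drop <- if (keep == a) b else a
    assignment[assignment == drop] <- keep
  }
  assignment
}

#' Module eigengene
#'
#' First principal component of the per-gene standardized log2(FPKM + 1)
#' expression of the module's genes across cells, scaled to unit variance,
#' with the sign chosen so the eigengene correlates non-negatively with the
#' module's mean expression profile. A singular module (all genes constant)
#' falls back to the standardized module mean, with a warning.
#'
#' @param x An [expression_matrix()] of FPKM values.
#' @param genes Gene ids of the module.
#' @return A list with `scores` (named per-cell eigengene values, unit
#'   variance) and `var_explained` (fraction of variance carried by the
#'   first component).
#' @export
module_eigengene <- function(x, genes) {
  e <- log_expr(x, genes)
  z <- t(scale(t(e)))
  ok <- apply(z, 1, function(r) all(is.finite(r)))
  if (!any(ok)) {
    warning("singular module: falling back to standardized module mean",
            call. = FALSE)
    m <- colMeans(e)
    s <- sd(m)
    scores <- if (s > 0) (m - mean(m)) / s else m * 0
    return(list(scores = setNames(scores, colnames(e)),
                var_explained = NA_real_))
  }
  z <- z[ok, , drop = FALSE]
  sv <- svd(z)
  scores <- sv$v[, 1]
  scores <- scores / sd(scores)
  mean_prof <- colMeans(e)
  if (sd(mean_prof) > 0 && cor(scores, mean_prof) < 0)
    scores <- -scores
  list(scores = setNames(scores, colnames(e)),
       var_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Eigengenes of all modules
#'
#' @param x An [expression_matrix()] of FPKM values.
#' @param assignment A `module_assignment` (or named character vector);
#'   "grey" genes are skipped.
#' @return Numeric matrix, cells x modules.
#' @export
module_eigengenes <- function(x, assignment) {
  mods <- setdiff(unique(assignment), "grey")
  ME <- vapply(mods, function(m)
    module_eigengene(x, names(assignment)[assignment == m])$scores,
    numeric(ncol(x$values)))
  ME <- matrix(ME, ncol = length(mods),
               dimnames = list(colnames(x$values), mods))
  ME
}

#' Module-trait correlation with the trait as the "white" module
#'
#' Appends the binary LS indicator as pseudo-module "white", computes the
#' Pearson correlation matrix over eigengenes plus trait, two-sided
#' p-values from the t-distribution with n - 2 degrees of freedom
#' (`t = r * sqrt((n - 2) / (1 - r^2))`), and an average-linkage dendrogram
#' of modules + trait on `1 - correlation`.
#'
#' @param eigengenes Cells x modules matrix from [module_eigengenes()].
#' @param trait Binary (0/1 or logical) LS indicator, one value per cell.
#' @param trait_label Label for the trait pseudo-module (default "white").
#' @return An object of class `module_trait_result` with `correlation`,
#'   `p_value`, `dendrogram`, `trait_label`, `n`.
#' @export
module_trait <- function(eigengenes, trait, trait_label = "white") {
  trait <- as.numeric(trait)
  if (length(trait) != nrow(eigengenes))
    stop("`trait` must give one value per cell", call. = FALSE)
  if (sd(trait) == 0) stop("`trait` is constant", call. = FALSE)
  M <- cbind(eigengenes, trait)
  colnames(M)[ncol(M)] <- trait_label
  n <- nrow(M)
  C <- cor(M)
  r2 <- pmin(C^2, 1 - 1e-15)
  tstat <- C * sqrt((n - 2) / (1 - r2))
  P <- 2 * pt(-abs(tstat), n - 2)
  diag(P) <- 0
  dend <- hclust(as.dist(1 - C), method = "average")
  structure(list(correlation = C, p_value = P, dendrogram = dend,
                 trait_label = trait_label, n = n),
            class = "module_trait_result")
}

#' @export
print.module_trait_result <- function(x, ...) {
  tc <- x$correlation[x$trait_label, ]
  tc <- tc[names(tc) != x$trait_label]
  cat("Module-trait correlations (trait =", x$trait_label, "):\n")
  print(round(sort(tc, decreasing = TRUE), 3))
  invisible(x)
}

#' End-to-end co-expression module analysis
#'
#' Convenience wrapper: adjacency, dendrogram, module cut with merging,
#' eigengenes, and module-trait correlation.
#'
#' @param x An [expression_matrix()] of FPKM values.
#' @param genes Gene ids to analyze (typically the ranked DEGs).
#' @param trait Binary LS indicator per cell.
#' @param config A [module_config()].
#' @return A list with `assignment`, `eigengenes`, `trait_result`,
#'   `dendrogram`, `adjacency`.
#' @export
run_coexpression <- function(x, genes, trait, config = module_config()) {
  A <- build_adjacency(x, genes, config)
  dendro <- cluster_genes(A)
  assignment <- cut_modules(dendro, x[genes, ], config)
  mods <- setdiff(unique(assignment), "grey")
  ME <- if (length(mods) > 0) module_eigengenes(x[genes, ], assignment)
  trait_result <- if (length(mods) > 0) module_trait(ME, trait)
  list(assignment = assignment, eigengenes = ME,
       trait_result = trait_result, dendrogram = dendro, adjacency = A)
}
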