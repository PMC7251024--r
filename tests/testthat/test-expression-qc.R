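# FPKM normalization, gene/cell filters, doublet scores, staged QC.

test_that("compute_fpkm matches the hand formula and an oracle", {
  x <- toy_counts()
  f <- compute_fpkm(x)
  # count 10, length 1,000 bp, library 1e6 -> FPKM = 10
  expect_equal(f$values["gA", "c1"], 10)
  # zero count stays zero
  expect_equal(f$values["gA", "c2"], 0)
  # whole matrix against the independent formula
  lib <- colSums(x$values)
  oracle <- x$values * 1e9 /
    outer(unname(x$gene_length_bp), unname(lib))
  expect_equal(unname(f$values), unname(oracle), tolerance = 1e-9)
  expect_equal(f$value_kind, "fpkm")

  # doubling all counts in one cell leaves its FPKM column unchanged
  x2 <- x
  x2$values[, "c1"] <- x2$values[, "c1"] * 2
  expect_equal(compute_fpkm(x2)$values[, "c1"], f$values[, "c1"])

  x$values[, 2] <- 0
  expect_error(compute_fpkm(x), "zero library")
})

test_that("filter_genes keeps coding genes detected at >= 1 FPKM", {
  v <- matrix(c(0, 0, 0,
                1, 0, 0,
                0.4, 0.9, 0.2,
                50, 80, 90), nrow = 4, byrow = TRUE,
              dimnames = list(c("zero", "edge", "low", "nc"),
                              c("c1", "c2", "c3")))
  x <- expression_matrix(v, rep(1000, 4),
                         c(rep("protein_coding", 3), "lincRNA"), "fpkm")
  kept <- rownames(filter_genes(x)$values)
  expect_identical(kept, "edge")  # FPKM exactly 1 in one cell is kept
  # the "all" rule requires detection in every sample
  expect_warning(k2 <- filter_genes(x, rule = "all"), "no genes")
  expect_equal(nrow(k2$values), 0)
  # without the coding restriction the high lncRNA survives
  expect_setequal(rownames(filter_genes(x, coding_only = FALSE)$values),
                  c("edge", "nc"))
})

test_that("metric filters use the strict thresholds exactly as stated", {
  rec <- data.frame(
    cell_id = sprintf("c%d", 1:7),
    cdna_pg_ul = c(999, 1000, 2000, 2000, 2000, 2000, NA),
    mito_fraction = c(0.1, 0.1, 0.25, 0.2501, 0.1, 0.1, 0.1),
    n_genes_detected = c(5000, 5000, 5000, 5000, 1000, 999, 5000))
  out <- filter_cells_metrics(rec)
  expect_setequal(out$kept, c("c2", "c3", "c5", "c7"))
  expect_equal(out$removed$reason[out$removed$cell_id == "c1"], "cdna")
  expect_equal(out$removed$reason[out$removed$cell_id == "c4"], "mito")
  expect_equal(out$removed$reason[out$removed$cell_id == "c6"], "genes")
  # missing metric: retained and flagged, not dropped
  expect_true("c7" %in% out$flagged$cell_id)
  # conservation and stage ordering
  expect_setequal(c(out$kept, out$removed$cell_id), rec$cell_id)
  expect_identical(out$stages$stage, c("cdna", "mito", "genes"))
})

test_that("doublet scores are marker products with strict positivity", {
  syms <- c("Gfap", "S100b", "Aqp4", "Olig1", "Olig2", "Mbp",
            "Slc17a7", "Neurod2", "Gad1", "Gad2")
  v <- matrix(0, nrow = 10, ncol = 3,
              dimnames = list(syms, c("astro2", "clean", "exin")))
  v[c("Gfap", "S100b", "Aqp4"), "astro2"] <- c(2, 1, 3)
  v[c("Gfap", "S100b"), "clean"] <- c(2, 1)  # Aqp4 = 0
  v[c("Slc17a7", "Neurod2", "Gad1", "Gad2"), "exin"] <- c(1, 2, 3, 4)
  x <- expression_matrix(v, rep(1000, 10), rep("protein_coding", 10),
                         "fpkm")
  ds <- doublet_scores(x)
  expect_equal(ds$s_astro, c(6, 0, 0))
  expect_equal(ds$s_ex_in, c(0, 0, 1 * 2 * 3 * 4))
  expect_identical(ds$is_doublet, c(TRUE, FALSE, TRUE))
  # scale invariance of the flag
  x10 <- x; x10$values <- x10$values * 10
  expect_identical(doublet_scores(x10)$is_doublet, ds$is_doublet)

  # absent marker treated as zero with a warning
  x2 <- x["Gfap" != rownames(v), ]
  expect_warning(ds2 <- doublet_scores(x2), "Gfap")
  expect_equal(ds2$s_astro, c(0, 0, 0))
})

test_that("run_qc applies the staged order and conserves cells", {
  fx <- gen_qc_fixture(seed = 1)
  qc <- run_qc(fx$matrix, fx$qc_meta)
  rep_ <- qc$report
  expect_equal(length(rep_$kept_cells), 53)
  expect_identical(rep_$stages$stage,
                   c("cdna", "mito", "genes", "doublet"))
  expect_equal(rep_$stages$n_removed, c(2, 2, 1, 5))
  # conservation: kept + removed = input, disjoint
  expect_setequal(c(rep_$kept_cells, rep_$removed$cell_id),
                  fx$qc_meta$cell_id)
  expect_equal(anyDuplicated(c(rep_$kept_cells, rep_$removed$cell_id)), 0)
  expect_equal(ncol(qc$matrix$values), 53)
  expect_equal(qc$matrix$value_kind, "fpkm")

  # no-failure cohort: everything kept
  clean <- gen_expression_cohort(expr_sim_params(n_ls = 6, n_ns = 4,
                                                 n_genes = 400,
                                                 n_de_genes = 5,
                                                 n_modules = 0, seed = 2))
  # (small 400-gene cohort: relax the detected-gene floor accordingly;
  # glial markers are all-zero here, so the doublet stage warns that the
  # gene filter dropped them and treats them as zero)
  suppressWarnings(qc2 <- run_qc(clean$matrix, clean$qc_meta,
                                 genes_min = 100))
  expect_equal(length(qc2$report$kept_cells), 10)
  expect_equal(nrow(qc2$report$removed), 0)

  bad <- clean$qc_meta
  bad$cell_id[1] <- "stranger"
  expect_error(run_qc(clean$matrix, bad), "do not match")
})

test_that("detected_genes counts strictly above the threshold", {
  v <- matrix(c(0, 1, 1.0001, 5, 10, 0), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  x <- expression_matrix(v, rep(1000, 3), rep("protein_coding", 3),
                         "fpkm")
  expect_equal(unname(detected_genes(x, 1)), c(1, 2))
  # brute-force oracle on a random matrix
  set.seed(5)
  v <- matrix(rexp(200, 1 / 3), nrow = 20,
              dimnames = list(sprintf("g%d", 1:20), sprintf("c%d", 1:10)))
  x <- expression_matrix(v, rep(1000, 20), rep("protein_coding", 20),
                         "fpkm")
  expect_equal(unname(detected_genes(x, 2)),
               unname(apply(v, 2, function(col) sum(col > 2))))
})

test_that("cohort correlation has unit structure and null behavior", {
  # duplicated cells correlate exactly 1
  set.seed(8)
  base <- rexp(300, 1 / 10)
  v <- cbind(a1 = base, a2 = base, b1 = rexp(300, 1 / 10),
             b2 = rexp(300, 1 / 10))
  rownames(v) <- sprintf("g%d", 1:300)
  x <- expression_matrix(v, rep(1000, 300), rep("protein_coding", 300),
                         "fpkm")
  cc <- cohort_correlation(x, c("LS", "LS", "NS", "NS"))
  expect_equal(cc$correlation["a1", "a2"], 1)
  expect_true(isSymmetric(cc$correlation))
  expect_equal(unname(diag(cc$correlation)), rep(1, 4))

  # independent noise cells: median within-group correlation near zero
  set.seed(9)
  v <- matrix(rlnorm(2000 * 12, 1, 1), nrow = 2000,
              dimnames = list(sprintf("g%d", 1:2000),
                              sprintf("c%d", 1:12)))
  x <- expression_matrix(v, rep(1000, 2000),
                         rep("protein_coding", 2000), "fpkm")
  cc <- cohort_correlation(x, rep(c("LS", "NS"), each = 6))
  expect_true(all(abs(cc$median_within) < 0.05))

  # planted shared LS structure raises the LS median above the NS median
  fx <- gen_expression_cohort(expr_sim_params(seed = 4))
  cc2 <- cohort_correlation(filter_genes(compute_fpkm(fx$matrix)),
                            fx$truth$cell_labels)
  expect_gt(cc2$median_within["LS"], cc2$median_within["NS"])

  expect_error(cohort_correlation(x, rep("LS", 12)), NA)
  expect_error(cohort_correlation(x, c("LS", rep("NS", 11))),
               "at least 2")
})
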