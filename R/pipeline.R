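#' Pipeline configuration
#'
#' Collects all stage parameters. The defaults reproduce the protocol's
#' stated thresholds exactly: SNR >= 2 event detection, >= 4 / <= 1
#' classification, cDNA < 1,000 pg/uL, mitochondrial fraction > 25%,
#' < 1,000 expressed protein-coding genes, FPKM >= 1 gene detection,
#' p_adj < 0.05 with |log2FC| > 2.5, and minimum module size 10.
#'
#' @param seed Integer seed for simulation.
#' @param simulate Generate the canonical synthetic fixtures instead of
#'   reading inputs.
#' @param traces_csv,protocol_json Paths to calcium inputs (ignored when
#'   `simulate`).
#' @param expression_dir Path to an expression cohort directory (see
#'   [read_expression_dir()]).
#' @param out_dir Optional output directory for stage TSV/JSON files.
#' @param snr,ls_min,ns_max Calcium thresholds.
#' @param cdna_min,mito_max,genes_min,min_fpkm QC thresholds.
#' @param alpha,lfc_threshold DEG thresholds.
#' @param module_cfg A [module_config()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, simulate = FALSE, traces_csv = NULL,
                            protocol_json = NULL, expression_dir = NULL,
                            out_dir = NULL, snr = 2, ls_min = 4, ns_max = 1,
                            cdna_min = 1000, mito_max = 0.25,
                            genes_min = 1000, min_fpkm = 1, alpha = 0.05,
                            lfc_threshold = 2.5,
                            module_cfg = module_config()) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full vivo-seq pipeline
#'
#' Fixed stage order: calcium classification, label join by cell id, staged
#' expression QC, LS-vs-NS differential expression, co-expression modules on
#' the ranked DEGs, and panel statistics. With `simulate = TRUE` the two
#' canonical synthetic fixtures are generated under the configured seed;
#' otherwise inputs are read from the configured paths. Identical
#' configurations produce identical reports.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `run_report`: stage summaries, cohort counts,
#'   threshold echo, and the stage results themselves (in `$results`).
#' @export
run_pipeline <- function(config = pipeline_config(simulate = TRUE)) {
  stopifnot(inherits(config, "pipeline_config"))
  if (isTRUE(config$simulate)) {
    cal <- gen_calcium_fixture(seed = config$seed)
    expr <- gen_qc_fixture(seed = config$seed)
  } else {
    if (is.null(config$traces_csv) || is.null(config$protocol_json) ||
        is.null(config$expression_dir))
      stop("without `simulate`, `traces_csv`, `protocol_json` and ",
           "`expression_dir` must be set", call. = FALSE)
    cal <- list(traces = read_traces_csv(config$traces_csv),
                protocol = read_protocol_json(config$protocol_json))
    expr <- read_expression_dir(config$expression_dir)
  }

  profiles <- classify_cohort(cal$traces, cal$protocol, snr = config$snr,
                              ls_min = config$ls_min,
                              ns_max = config$ns_max)

  expr_cells <- colnames(expr$matrix$values)
  orphans <- setdiff(expr_cells, profiles$cell_id)
  if (length(orphans) > 0)
    stop("expression cells without calcium labels: ",
         paste(utils::head(orphans, 10), collapse = ", "), call. = FALSE)
  labels <- setNames(profiles$label[match(expr_cells, profiles$cell_id)],
                     expr_cells)

  qc <- run_qc(expr$matrix, expr$qc_meta, cdna_min = config$cdna_min,
               mito_max = config$mito_max, genes_min = config$genes_min,
               min_fpkm = config$min_fpkm)
  kept <- qc$report$kept_cells
  kept_labels <- labels[kept]
  analysis_cells <- kept[kept_labels %in% c("LS", "NS")]
  mat <- qc$matrix[, analysis_cells]
  lab <- kept_labels[analysis_cells]

  de <- de_test(mat, lab, alpha = config$alpha,
                lfc_threshold = config$lfc_threshold)
  degs <- rank_degs(de)

  coexpr <- NULL
  if (nrow(degs) >= config$module_cfg$min_cluster_size)
    coexpr <- run_coexpression(mat, degs$gene_id, trait = lab == "LS",
                               config = config$module_cfg)

  panels <- panel_compare(mat, lab)

  report <- structure(list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("vivoseq")),
    thresholds = config[c("snr", "ls_min", "ns_max", "cdna_min",
                          "mito_max", "genes_min", "min_fpkm", "alpha",
                          "lfc_threshold")],
    counts = list(
      n_traces = nrow(profiles),
      n_ls_recorded = sum(profiles$label == "LS"),
      n_ns_recorded = sum(profiles$label == "NS"),
      n_excluded_recorded = sum(profiles$label == "excluded"),
      n_cells_expression = length(expr_cells),
      n_cells_after_qc = length(kept),
      n_ls_final = sum(lab == "LS"),
      n_ns_final = sum(lab == "NS"),
      n_genes_filtered = qc$report$n_genes_kept,
      n_degs = nrow(degs),
      n_modules = if (is.null(coexpr)) 0L else
        length(setdiff(unique(coexpr$assignment), "grey")),
      n_panels = nrow(panels)),
    qc_stages = qc$report$stages,
    results = list(profiles = profiles, qc = qc, de = de, degs = degs,
                   coexpression = coexpr, panels = panels,
                   labels = lab)),
    class = "run_report")

  if (!is.null(config$out_dir)) write_run_outputs(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  c_ <- x$counts
  cat("vivo-seq run report (seed", x$seed, ")\n")
  cat(sprintf("  calcium: %d traces -> %d LS, %d NS, %d excluded\n",
              c_$n_traces, c_$n_ls_recorded, c_$n_ns_recorded,
              c_$n_excluded_recorded))
  cat(sprintf("  QC: %d cells -> %d kept (%d LS, %d NS); %d genes\n",
              c_$n_cells_expression, c_$n_cells_after_qc, c_$n_ls_final,
              c_$n_ns_final, c_$n_genes_filtered))
  cat(sprintf("  DE: %d DEGs; modules: %d; panels tested: %d\n",
              c_$n_degs, c_$n_modules, c_$n_panels))
  invisible(x)
}

# write per-stage TSV/JSON outputs under `dir`
write_run_outputs <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- report$results
  wtsv <- function(df, name)
    write.table(df, file.path(dir, name), sep = "\t", row.names = FALSE,
                quote = FALSE)
  wtsv(res$profiles, "response_profiles.tsv")
  write_qc_report_json(res$qc$report, file.path(dir, "qc_report.json"))
  wtsv(as.data.frame(res$de), "de_results.tsv")
  if (!is.null(res$coexpression)) {
    a <- res$coexpression$assignment
    wtsv(data.frame(gene = names(a), module = unname(a)), "modules.tsv")
    me <- res$coexpression$eigengenes
    wtsv(data.frame(cell_id = rownames(me), me, check.names = FALSE),
         "eigengenes.tsv")
    tr <- res$coexpression$trait_result
    wtsv(data.frame(module = rownames(tr$correlation),
                    correlation = tr$correlation[, tr$trait_label],
                    p_value = tr$p_value[, tr$trait_label]),
         "module_trait.tsv")
  }
  wtsv(res$panels, "panel_results.tsv")
  slim <- report[c("seed", "package_version", "thresholds", "counts")]
  slim$qc_stages <- report$qc_stages
  jsonlite::write_json(slim, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(dir)
}

#' Validate pipeline input files
#'
#' Checks formats and internal consistency of the input files without
#' mutating them: file existence and readability, required trace columns,
#' duplicated cell ids, strictly increasing protocol onsets, matrix/metadata
#' dimension agreement.
#'
#' @param traces_csv,protocol_json,expression_dir Input paths; any may be
#'   `NULL` to skip that check.
#' @return A data.frame of diagnostics (`severity`, `code`, `message`);
#'   zero rows when everything is well-formed.
#' @export
validate_inputs <- function(traces_csv = NULL, protocol_json = NULL,
                            expression_dir = NULL) {
  diags <- data.frame(severity = character(0), code = character(0),
                      message = character(0), stringsAsFactors = FALSE)
  add <- function(severity, code, message)
    diags <<- rbind(diags, data.frame(severity = severity, code = code,
                                      message = message,
                                      stringsAsFactors = FALSE))
  if (!is.null(traces_csv)) {
    if (!file.exists(traces_csv)) {
      add("error", "missing_file", paste("unreadable:", traces_csv))
    } else {
      long <- tryCatch(read.csv(traces_csv, stringsAsFactors = FALSE),
                       error = function(e) NULL)
      need <- c("cell_id", "time_s", "f_cell", "f_background")
      if (is.null(long) || !all(need %in% names(long))) {
        add("error", "bad_trace_format",
            paste("trace CSV must have columns",
                  paste(need, collapse = ", ")))
      } else {
        dup <- duplicated(long[, c("cell_id", "time_s")])
        if (any(dup))
          add("error", "duplicate_trace_sample",
              paste("duplicated (cell_id, time_s) rows, e.g. cell",
                    long$cell_id[dup][1]))
      }
    }
  }
  if (!is.null(protocol_json)) {
    if (!file.exists(protocol_json)) {
      add("error", "missing_file", paste("unreadable:", protocol_json))
    } else {
      p <- tryCatch(jsonlite::read_json(protocol_json,
                                        simplifyVector = TRUE),
                    error = function(e) NULL)
      if (is.null(p) || is.null(p$onsets_s)) {
        add("error", "bad_protocol_format",
            "protocol JSON lacks `onsets_s`")
      } else if (length(p$onsets_s) > 1 && any(diff(p$onsets_s) <= 0)) {
        add("error", "nonincreasing_onsets",
            "stimulus onsets are not strictly increasing")
      }
    }
  }
  if (!is.null(expression_dir)) {
    cells_tsv <- file.path(expression_dir, "cells.tsv")
    if (!dir.exists(expression_dir)) {
      add("error", "missing_file", paste("unreadable:", expression_dir))
    } else if (!file.exists(cells_tsv)) {
      add("error", "missing_file", paste("unreadable:", cells_tsv))
    } else {
      cells <- read.delim(cells_tsv, stringsAsFactors = FALSE)
      dup <- duplicated(cells$cell_id)
      if (any(dup))
        add("error", "duplicate_cell_id",
            paste("duplicated cell id:", cells$cell_id[dup][1]))
      ex <- tryCatch(read_expression_dir(expression_dir),
                     error = function(e) NULL)
      if (is.null(ex)) {
        add("error", "bad_matrix", "expression matrix unreadable")
      } else if (!setequal(colnames(ex$matrix$values),
                           ex$qc_meta$cell_id)) {
        add("error", "cell_id_mismatch",
            "matrix columns and cells.tsv ids differ")
      }
    }
  }
  diags
}
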