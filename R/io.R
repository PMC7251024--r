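# Readers and writers for the package's plain-text exchange formats:
# long-format trace CSV, protocol JSON, and the expression directory
# (matrix.tsv or matrix.mtx triplet with genes.tsv and cells.tsv).

#' Write traces as long-format CSV
#'
#' Columns: `cell_id`, `time_s`, `f_cell`, `f_background`.
#'
#' @param traces List of [fluorescence_trace()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  long <- do.call(rbind, lapply(traces, function(tr)
    data.frame(cell_id = tr$cell_id,
               time_s = frame_times(length(tr$f_cell), tr$frame_rate_hz),
               f_cell = tr$f_cell, f_background = tr$f_background,
               stringsAsFactors = FALSE)))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read traces from long-format CSV
#'
#' @param path CSV path with columns `cell_id`, `time_s`, `f_cell`,
#'   `f_background`.
#' @param frame_rate_hz Frame rate to attach; inferred from the time column
#'   when `NULL`.
#' @return List of [fluorescence_trace()] objects, in file order.
#' @export
read_traces_csv <- function(path, frame_rate_hz = NULL) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "time_s", "f_cell", "f_background")
  if (!all(need %in% names(long)))
    stop("trace CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  ids <- unique(long$cell_id)
  lapply(ids, function(id) {
    sub <- long[long$cell_id == id, , drop = FALSE]
    sub <- sub[order(sub$time_s), , drop = FALSE]
    rate <- frame_rate_hz %||% (1 / median(diff(sub$time_s)))
    fluorescence_trace(id, sub$f_cell, sub$f_background,
                       frame_rate_hz = rate)
  })
}

#' Write a stimulus protocol as JSON
#' @param protocol A [stimulus_protocol()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protocol_json <- function(protocol, path) {
  jsonlite::write_json(unclass(protocol), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a stimulus protocol from JSON
#' @param path JSON path written by [write_protocol_json()].
#' @return A [stimulus_protocol()].
#' @export
read_protocol_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  stimulus_protocol(p$onsets_s, p$stim_duration_s, p$isi_s,
                    p$frame_rate_hz, p$pre_baseline_window_s)
}

#' Write an expression cohort directory
#'
#' Writes `genes.tsv` (`id`, `length_bp`, `biotype`), `cells.tsv` (the QC
#' metadata), and the matrix either as dense `matrix.tsv` (genes x cells) or
#' as sparse MatrixMarket `matrix.mtx`.
#'
#' @param x An [expression_matrix()].
#' @param qc_meta Per-cell QC metadata data.frame (see
#'   [gen_expression_cohort()]); may be `NULL`.
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` (dense) or `"mtx"` (sparse triplet).
#' @return `dir`, invisibly.
#' @export
write_expression_dir <- function(x, qc_meta = NULL, dir,
                                 format = c("tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "expression_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- data.frame(id = rownames(x$values),
                      length_bp = unname(x$gene_length_bp),
                      biotype = unname(x$biotype),
                      stringsAsFactors = FALSE)
  write.table(genes, file.path(dir, "genes.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  cells <- qc_meta %||% data.frame(cell_id = colnames(x$values),
                                   stringsAsFactors = FALSE)
  write.table(cells, file.path(dir, "cells.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (format == "tsv") {
    write.table(data.frame(gene_id = rownames(x$values), x$values,
                           check.names = FALSE, stringsAsFactors = FALSE),
                file.path(dir, "matrix.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(x$values, sparse = TRUE),
                    file.path(dir, "matrix.mtx"))
  }
  writeLines(x$value_kind, file.path(dir, "value_kind.txt"))
  invisible(dir)
}

#' Read an expression cohort directory
#'
#' Counterpart of [write_expression_dir()]; detects `matrix.tsv` or
#' `matrix.mtx`.
#'
#' @param dir Directory path.
#' @return A list with `matrix` (an [expression_matrix()]) and `qc_meta`.
#' @export
read_expression_dir <- function(dir) {
  genes <- read.delim(file.path(dir, "genes.tsv"),
                      stringsAsFactors = FALSE)
  cells <- read.delim(file.path(dir, "cells.tsv"),
                      stringsAsFactors = FALSE)
  kind_file <- file.path(dir, "value_kind.txt")
  kind <- if (file.exists(kind_file)) readLines(kind_file)[1] else "counts"
  tsv <- file.path(dir, "matrix.tsv")
  mtx <- file.path(dir, "matrix.mtx")
  if (file.exists(tsv)) {
    tab <- read.delim(tsv, check.names = FALSE, stringsAsFactors = FALSE)
    values <- as.matrix(tab[, -1, drop = FALSE])
    rownames(values) <- tab[[1]]
  } else if (file.exists(mtx)) {
    values <- as.matrix(Matrix::readMM(mtx))
    rownames(values) <- genes$id
    colnames(values) <- cells$cell_id
  } else {
    stop("no matrix.tsv or matrix.mtx in ", dir, call. = FALSE)
  }
  x <- expression_matrix(values,
                         gene_length_bp = genes$length_bp[
                           match(rownames(values), genes$id)],
                         biotype = genes$biotype[
                           match(rownames(values), genes$id)],
                         value_kind = kind)
  list(matrix = x, qc_meta = cells)
}

#' Write a QC report as JSON
#' @param report A `qc_report` from [run_qc()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}
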