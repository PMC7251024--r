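# Synthetic cohorts with planted ground truth.
#
# The generators state the world the analysis assumes: a 5-repetition grating
# protocol with stimulus-locked exponential-decay transients over slow
# correlated background noise, and a Smart-seq2-like negative-binomial count
# matrix with marker structure for pyramidal cells, interneurons, astrocytes
# and oligodendrocytes, planted LS-vs-NS differential genes, planted
# co-expression modules (one tracking the LS trait), designed doublets and
# designed QC-metric failures.

# marker sets used both by the generator and by doublet scoring
.marker_sets <- list(
  astro = c("Gfap", "S100b", "Aqp4"),
  oligo = c("Olig1", "Olig2", "Mbp"),
  ex    = c("Slc17a7", "Neurod2"),
  inh   = c("Gad1", "Gad2")
)

# curated channel/receptor symbols planted as ordinary background genes so
# the default panels resolve on synthetic cohorts
.channel_symbols <- c(
  "Atp1a1", "Atp1a3", "Atp1b1", "Scn1a", "Scn2a", "Scn8a", "Kcna1", "Kcnc1",
  "Kcnq2", "Cacna1a", "Cacna1b", "Kcnma1", "Kcnn2", "Clcn2", "Gria1",
  "Gria2", "Grin1", "Grin2a", "Grin2b", "Grik2", "Grid1", "Gabra1",
  "Gabrb2", "Gabbr1", "Gabbr2", "Chrna4", "Chrnb2", "Chrm1", "Htr1a",
  "Htr2a", "Htr3a", "Grm1", "Grm5", "Drd1", "Drd2", "Cnr1"
)

#' Parameters for a synthetic calcium-trace cohort
#'
#' @param n_cells Number of cells.
#' @param response_design Integer vector (length `n_cells`) of intended
#'   positive repetitions per cell, each in `0..n_reps`; `NULL` draws each
#'   uniformly at generation time.
#' @param n_reps Stimulus repetitions (default 5).
#' @param stim_duration_s,isi_s,frame_rate_hz Protocol constants
#'   (defaults 5 s, 15 s, 30 frames/s).
#' @param transient_amplitude_snr Transient peak amplitude as a multiple of
#'   the noise SD (default 5). When `noise_sd = 0` a fixed peak of 0.5 dF/F
#'   is used instead.
#' @param transient_decay_s Exponential decay constant of a transient in
#'   seconds (default 1).
#' @param noise_sd Marginal SD of the dF/F background noise (default 0.02).
#' @param noise_corr_s Smoothness of the background noise: the SD in
#'   seconds of the Gaussian kernel applied to white noise (default 5,
#'   emulating slow vasomotion-scale background fluctuation; `0` gives
#'   frame-iid noise). See the methods vignette.
#' @param spontaneous_tail_s Stimulus-free recording appended after the
#'   last inter-stimulus interval (default 120 s), emulating the
#'   spontaneous-activity segment of a session; it lengthens the baseline
#'   available to the noise estimator.
#' @param seed Integer seed; identical parameters and seed give bitwise
#'   identical cohorts.
#' @return An object of class `calcium_sim_params`.
#' @export
calcium_sim_params <- function(n_cells, response_design = NULL, n_reps = 5,
                               stim_duration_s = 5, isi_s = 15,
                               frame_rate_hz = 30,
                               transient_amplitude_snr = 5,
                               transient_decay_s = 1, noise_sd = 0.02,
                               noise_corr_s = 5, spontaneous_tail_s = 120,
                               seed = 1) {
  if (!isTRUE(n_cells >= 1)) stop("`n_cells` must be >= 1", call. = FALSE)
  if (!isTRUE(n_reps >= 1)) stop("`n_reps` must be >= 1", call. = FALSE)
  if (!isTRUE(stim_duration_s > 0) || !isTRUE(isi_s > 0) ||
      !isTRUE(frame_rate_hz > 0))
    stop("durations and frame rate must be positive", call. = FALSE)
  if (!isTRUE(transient_decay_s > 0))
    stop("`transient_decay_s` must be positive", call. = FALSE)
  if (!isTRUE(noise_sd >= 0)) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!isTRUE(spontaneous_tail_s >= 0))
    stop("`spontaneous_tail_s` must be >= 0", call. = FALSE)
  if (!is.null(response_design)) {
    response_design <- as.integer(response_design)
    if (length(response_design) != n_cells ||
        any(response_design < 0) || any(response_design > n_reps))
      stop("`response_design` must give one count in [0, n_reps] per cell",
           call. = FALSE)
  }
  structure(as.list(environment()), class = "calcium_sim_params")
}

# Smooth correlated Gaussian noise: white noise convolved with a Gaussian
# kernel of SD `corr_s` seconds, rescaled to marginal SD `sd`. The kernel
# makes the process differentiable, so its level-crossing rate matches the
# smooth slow background fluctuations of ROI-averaged traces.
smooth_noise <- function(n, sd, frame_rate_hz, corr_s) {
  if (sd <= 0) return(numeric(n))
  if (corr_s <= 0) return(rnorm(n, 0, sd))
  half <- ceiling(4 * corr_s * frame_rate_hz)
  k <- dnorm(seq(-half, half) / frame_rate_hz, 0, corr_s)
  pad <- length(k)
  e <- rnorm(n + 2 * pad)
  x <- stats::convolve(e, rev(k), type = "open")  # FFT convolution
  x <- x[(pad + half + 1):(pad + half + n)]
  sd * x / sqrt(sum(k^2))
}

#' Generate a synthetic calcium-trace cohort
#'
#' Each cell's dF/F signal is a flat baseline plus, for each designed
#' positive repetition, an instantaneous-rise exponential-decay transient
#' starting at a uniform-random latency within the first second of the
#' stimulus window, over smooth correlated background noise. Transients are
#' truncated below 1e-3 of their peak so designed-null windows are exactly
#' flat in the noiseless regime. The raw two-channel traces are constructed
#' so that the cell-minus-background baseline `f0` is 1 arbitrary unit.
#'
#' @param params A [calcium_sim_params()] object.
#' @return A list with `traces` (list of [fluorescence_trace()]), `protocol`
#'   (a [stimulus_protocol()]) and `truth` (a list with `cell_ids`,
#'   `response_design`, `positive_reps` and designed `cell_labels` under the
#'   >=4 / <=1 rule).
#' @export
gen_calcium_cohort <- function(params) {
  stopifnot(inherits(params, "calcium_sim_params"))
  withr::with_seed(params$seed, {
    p <- params
    protocol <- default_protocol(p$n_reps, p$stim_duration_s, p$isi_s,
                                 p$frame_rate_hz)
    total_s <- p$isi_s + p$n_reps * (p$stim_duration_s + p$isi_s) +
      p$spontaneous_tail_s
    n <- round(total_s * p$frame_rate_hz)
    t <- frame_times(n, p$frame_rate_hz)
    design <- p$response_design %||% sample(0:p$n_reps, p$n_cells,
                                            replace = TRUE)
    amp <- if (p$noise_sd > 0) p$transient_amplitude_snr * p$noise_sd else 0.5
    cell_ids <- sprintf("cell_%03d", seq_len(p$n_cells))
    positive_reps <- vector("list", p$n_cells)
    traces <- vector("list", p$n_cells)
    for (i in seq_len(p$n_cells)) {
      reps <- sort(sample(seq_len(p$n_reps), design[i]))
      positive_reps[[i]] <- reps
      sig <- numeric(n)
      for (r in reps) {
        t0 <- protocol$onsets_s[r] +
          runif(1, 0, min(1, p$stim_duration_s))
        dt <- t - t0
        tr <- amp * exp(-dt / p$transient_decay_s)
        tr[dt < 0 | tr < amp * 1e-3] <- 0
        sig <- sig + tr
      }
      d <- sig + smooth_noise(n, p$noise_sd, p$frame_rate_hz,
                              p$noise_corr_s)
      f_bg <- 1 + smooth_noise(n, 0.1 * p$noise_sd, p$frame_rate_hz,
                               p$noise_corr_s)
      traces[[i]] <- fluorescence_trace(cell_ids[i],
                                        f_cell = f_bg + 1 + d,
                                        f_background = f_bg,
                                        frame_rate_hz = p$frame_rate_hz)
    }
    labels <- ifelse(design >= 4, "LS", ifelse(design <= 1, "NS", "excluded"))
    list(traces = traces, protocol = protocol,
         truth = list(cell_ids = cell_ids,
                      response_design = design,
                      positive_reps = positive_reps,
                      cell_labels = setNames(labels, cell_ids)))
  })
}

#' Canonical 83-trace calcium fixture
#'
#' Mirrors the recorded cohort bookkeeping: 83 traces of which 41 are
#' designed with >= 4 positive repetitions (LS), 22 with <= 1 (NS) and 20
#' with exactly 2 or 3 (excluded), so the classifier retains 63 cells. The
#' fixture is noiseless (see the methods vignette) so classification is
#' exact and deterministic.
#'
#' @param seed Integer seed.
#' @return As [gen_calcium_cohort()].
#' @export
gen_calcium_fixture <- function(seed = 3) {
  design <- c(rep(5L, 21), rep(4L, 20),   # 41 designed light-sensitive
              rep(1L, 11), rep(0L, 11),   # 22 designed non-light-sensitive
              rep(3L, 10), rep(2L, 10))   # 20 designed excluded
  gen_calcium_cohort(calcium_sim_params(
    n_cells = 83, response_design = design, noise_sd = 0, seed = seed))
}

#' Parameters for a synthetic expression cohort
#'
#' @param n_ls,n_ns Numbers of LS- and NS-labeled cells (defaults 41 and 12,
#'   the surviving cohort sizes).
#' @param n_genes Total genes (default 2000).
#' @param n_de_genes Planted LS-up differential genes (default 100).
#' @param de_log2fc Planted log2 fold change (default 3).
#' @param n_modules,module_size Planted co-expression modules and their size
#'   (defaults 5 modules of 30 genes).
#' @param trait_module_index Which module's latent factor is a noisy copy of
#'   the LS indicator (default 1).
#' @param doublet_design List of `list(cell = index, type = ...)` entries
#'   with type `"astro"`, `"oligo"` or `"ex_in"`; those cells co-express the
#'   corresponding marker sets.
#' @param metric_failure_design List of `list(cell = index, reason = ...)`
#'   entries with reason `"cdna"`, `"mito"` or `"genes"`; those cells violate
#'   exactly that QC threshold.
#' @param mean_library_size Expected fragments per cell (default 5e5).
#' @param dispersion Negative-binomial overdispersion (default 0.2).
#' @param seed Integer seed.
#' @return An object of class `expr_sim_params`.
#' @export
expr_sim_params <- function(n_ls = 41, n_ns = 12, n_genes = 2000,
                            n_de_genes = 100, de_log2fc = 3, n_modules = 5,
                            module_size = 30, trait_module_index = 1,
                            doublet_design = list(),
                            metric_failure_design = list(),
                            mean_library_size = 5e5, dispersion = 0.2,
                            seed = 1) {
  counts <- c(n_ls, n_ns, n_genes, n_de_genes, n_modules, module_size)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (n_ls + n_ns < 1) stop("need at least one cell", call. = FALSE)
  n_reserved <- length(unlist(.marker_sets)) + length(.channel_symbols)
  if (n_de_genes + n_modules * module_size + n_reserved > n_genes)
    stop("infeasible design: more planted genes than `n_genes`",
         call. = FALSE)
  if (n_modules > 0 &&
      (trait_module_index < 1 || trait_module_index > n_modules))
    stop("`trait_module_index` out of range", call. = FALSE)
  n_cells <- n_ls + n_ns
  for (d in doublet_design)
    if (!d$type %in% c("astro", "oligo", "ex_in") ||
        d$cell < 1 || d$cell > n_cells)
      stop("invalid doublet design entry", call. = FALSE)
  for (d in metric_failure_design)
    if (!d$reason %in% c("cdna", "mito", "genes") ||
        d$cell < 1 || d$cell > n_cells)
      stop("invalid metric failure design entry", call. = FALSE)
  if (!isTRUE(mean_library_size > 0) || !isTRUE(dispersion > 0))
    stop("`mean_library_size` and `dispersion` must be positive",
         call. = FALSE)
  structure(as.list(environment()), class = "expr_sim_params")
}

#' Generate a synthetic single-cell expression cohort
#'
#' Negative-binomial fragment counts with log-normal per-cell size factors
#' and gene lengths in 500-10,000 bp; FPKM normalization is left to the
#' downstream pipeline so that operation is exercised. Planted structure:
#' LS-up differential genes shifted by `de_log2fc`; per-module latent
#' factors shared by module genes, with the trait module's factor a noisy
#' copy of the LS indicator; every cell expresses one neuronal marker pair
#' (excitatory or inhibitory); designed doublets additionally co-express the
#' designed marker set; designed metric failures violate exactly their QC
#' threshold.
#'
#' @param params An [expr_sim_params()] object.
#' @return A list with `matrix` (an [expression_matrix()] of counts),
#'   `qc_meta` (data.frame: `cell_id`, `cdna_pg_ul`, `mito_fraction`,
#'   `n_genes_detected`, `label`) and `truth` (planted ground truth:
#'   `cell_labels`, `de_gene_ids`, `module_assignments`, `trait_module`,
#'   `doublet_ids`, `metric_fail_ids`, `neuron_type`).
#' @export
gen_expression_cohort <- function(params) {
  stopifnot(inherits(params, "expr_sim_params"))
  withr::with_seed(params$seed, {
    p <- params
    n_cells <- p$n_ls + p$n_ns
    cell_ids <- sprintf("cell_%03d", seq_len(n_cells))
    labels <- setNames(c(rep("LS", p$n_ls), rep("NS", p$n_ns)), cell_ids)
    ls_ind <- as.numeric(labels == "LS")

    marker_syms <- unlist(.marker_sets, use.names = FALSE)
    n_sym <- length(marker_syms) + length(.channel_symbols)
    gene_ids <- c(marker_syms, .channel_symbols,
                  sprintf("gene_%04d", seq_len(p$n_genes - n_sym)))
    marker_idx <- seq_along(marker_syms)
    anon_start <- n_sym + 1
    de_idx <- if (p$n_de_genes > 0)
      anon_start + seq_len(p$n_de_genes) - 1 else integer(0)
    mod_idx <- if (p$n_modules > 0)
      anon_start + p$n_de_genes +
        seq_len(p$n_modules * p$module_size) - 1 else integer(0)
    bg_idx <- setdiff(seq_len(p$n_genes),
                      c(marker_idx, de_idx, mod_idx))

    lengths <- sample(500:10000, p$n_genes, replace = TRUE)
    # short planted differential genes: high FPKM at modest count mass so
    # the library-composition shift stays small (see methods vignette)
    lengths[de_idx] <- sample(500:1500, length(de_idx), replace = TRUE)
    biotype <- rep("protein_coding", p$n_genes)
    n_nc <- min(floor(0.05 * p$n_genes), length(bg_idx))
    if (n_nc > 0)
      biotype[utils::tail(bg_idx, n_nc)] <- "lincRNA"

    base <- rlnorm(p$n_genes, log(100), 1)
    base <- base * p$mean_library_size / sum(base)
    base[marker_idx] <- 0
    base[de_idx] <- runif(length(de_idx), 30, 80)
    base[mod_idx] <- runif(length(mod_idx), 30, 100)

    sf <- rlnorm(n_cells, 0, 0.3)
    mu <- outer(base, sf)

    if (length(de_idx) > 0)
      mu[de_idx, ls_ind == 1] <- mu[de_idx, ls_ind == 1] * 2^p$de_log2fc

    module_assign <- integer(0)
    if (p$n_modules > 0) {
      module_assign <- rep(seq_len(p$n_modules), each = p$module_size)
      names(module_assign) <- gene_ids[mod_idx]
      for (m in seq_len(p$n_modules)) {
        f <- if (m == p$trait_module_index)
          as.numeric(scale(ls_ind)) + rnorm(n_cells, 0, 0.3)
        else rnorm(n_cells)
        gi <- mod_idx[module_assign == m]
        w <- runif(length(gi), 0.8, 1.2)
        mu[gi, ] <- mu[gi, ] * 2^outer(w, f)
      }
    }

    # each cell is one neuron type; doublets add further marker sets
    neuron_type <- sample(c("ex", "inh"), n_cells, replace = TRUE,
                          prob = c(0.8, 0.2))
    marker_mu <- 50
    forced_pos <- vector("list", n_cells)
    set_markers <- function(mu, set, cell) {
      mu[match(.marker_sets[[set]], gene_ids), cell] <-
        marker_mu * sf[cell]
      mu
    }
    for (i in seq_len(n_cells))
      mu <- set_markers(mu, neuron_type[i], i)
    doublet_ids <- character(0)
    for (d in p$doublet_design) {
      sets <- if (d$type == "ex_in") c("ex", "inh") else d$type
      for (s in sets) mu <- set_markers(mu, s, d$cell)
      forced_pos[[d$cell]] <- match(unlist(.marker_sets[sets]), gene_ids)
      doublet_ids <- c(doublet_ids, cell_ids[d$cell])
    }

    counts <- matrix(rnbinom(p$n_genes * n_cells, mu = mu,
                             size = 1 / p$dispersion),
                     nrow = p$n_genes, ncol = n_cells,
                     dimnames = list(gene_ids, cell_ids))
    # construction guarantee: a designed doublet expresses every marker of
    # its designed set
    for (i in seq_len(n_cells))
      if (length(forced_pos[[i]]) > 0)
        counts[forced_pos[[i]], i] <- pmax(counts[forced_pos[[i]], i], 1L)

    cdna <- runif(n_cells, 1200, 4000)
    mito <- rbeta(n_cells, 2, 38)
    metric_fail_ids <- character(0)
    for (d in p$metric_failure_design) {
      metric_fail_ids[cell_ids[d$cell]] <- d$reason
      if (d$reason == "cdna") cdna[d$cell] <- runif(1, 300, 900)
      if (d$reason == "mito") mito[d$cell] <- runif(1, 0.26, 0.5)
      if (d$reason == "genes") {
        keep <- sample(p$n_genes, 500)
        zero <- setdiff(seq_len(p$n_genes), keep)
        counts[zero, d$cell] <- 0L
      }
    }

    mat <- expression_matrix(counts, gene_length_bp = lengths,
                             biotype = biotype, value_kind = "counts")
    fpkm <- compute_fpkm(mat)
    nd <- expressed_gene_counts(fpkm, min_fpkm = 1, coding_only = TRUE)
    qc_meta <- data.frame(cell_id = cell_ids, cdna_pg_ul = cdna,
                          mito_fraction = mito,
                          n_genes_detected = as.integer(nd),
                          label = unname(labels),
                          stringsAsFactors = FALSE)
    list(matrix = mat, qc_meta = qc_meta,
         truth = list(cell_labels = labels,
                      de_gene_ids = gene_ids[de_idx],
                      module_assignments = module_assign,
                      trait_module = if (p$n_modules > 0)
                        p$trait_module_index else NA_integer_,
                      doublet_ids = doublet_ids,
                      metric_fail_ids = metric_fail_ids,
                      neuron_type = setNames(neuron_type, cell_ids)))
  })
}

#' Canonical 63-cell QC fixture
#'
#' Mirrors the sequenced cohort bookkeeping: 63 cells (41 LS, 22 NS) of
#' which, by design, 2 fail the cDNA-concentration filter, 2 the
#' mitochondrial-fraction filter and 1 the detected-gene filter (five
#' distinct cells); among the remaining 58, exactly 4 are astro/oligo
#' doublets and 1 is an excitatory-inhibitory doublet. The 53 survivors
#' carry 41 LS and 12 NS labels. All designed failures sit in the NS block
#' so labels stay consistent with the 83-trace calcium fixture.
#'
#' @param seed Integer seed.
#' @return As [gen_expression_cohort()].
#' @export
gen_qc_fixture <- function(seed = 1) {
  gen_expression_cohort(expr_sim_params(
    n_ls = 41, n_ns = 22,
    metric_failure_design = list(
      list(cell = 44, reason = "cdna"), list(cell = 45, reason = "cdna"),
      list(cell = 47, reason = "mito"), list(cell = 48, reason = "mito"),
      list(cell = 50, reason = "genes")),
    doublet_design = list(
      list(cell = 53, type = "astro"), list(cell = 56, type = "astro"),
      list(cell = 58, type = "oligo"), list(cell = 60, type = "oligo"),
      list(cell = 62, type = "ex_in")),
    seed = seed))
}
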