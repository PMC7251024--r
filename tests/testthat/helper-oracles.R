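# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# adjusted Rand index between two labelings
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Benjamini-Hochberg step-up, written from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Welch statistic from the textbook formulas
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# paired t from the textbook formula
paired_oracle <- function(before, after) {
  d <- before - after
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# build a dff_trace object directly from values
make_dff <- function(values, rate = 10, cell_id = "cell") {
  structure(list(values = values, f0 = 1, frame_rate_hz = rate,
                 cell_id = cell_id), class = "dff_trace")
}

# a small single-onset protocol for window-level unit tests:
# onset 10 s, 2 s stimulus, 10 Hz; pre-baseline 6-8 s
small_protocol <- function(onsets = 10, stim = 2, rate = 10)
  stimulus_protocol(onsets, stim_duration_s = stim, isi_s = 5,
                    frame_rate_hz = rate)

# counts fixture: 3 genes x 3 cells with known lengths/biotypes
toy_counts <- function() {
  v <- matrix(c(10, 100, 999890,
                0, 50, 999950,
                5, 20, 999975), nrow = 3,
              dimnames = list(c("gA", "gB", "gC"),
                              c("c1", "c2", "c3")))
  expression_matrix(v, gene_length_bp = c(1000, 2000, 500),
                    biotype = c("protein_coding", "protein_coding",
                                "lincRNA"),
                    value_kind = "counts")
}
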