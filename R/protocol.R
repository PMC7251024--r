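#' Stimulus protocol for repeated visual stimulation
#'
#' Describes the timing of a repeated sensory stimulation experiment: the
#' stimulus onsets, stimulus duration, inter-stimulus interval and the
#' acquisition frame rate. Every windowed calcium computation (baseline
#' estimation, per-repetition response scoring, response magnitude) derives
#' its sample windows from this object.
#'
#' @param onsets_s Numeric vector of stimulus onset times in seconds,
#'   strictly increasing, at least one stimulus duration apart.
#' @param stim_duration_s Stimulus duration in seconds (default 5 s drifting
#'   grating).
#' @param isi_s Inter-stimulus interval in seconds (default 15 s).
#' @param frame_rate_hz Acquisition frame rate in frames per second
#'   (default 30).
#' @param pre_baseline_window_s Length-2 numeric: the pre-stimulus baseline
#'   window expressed as seconds *before* each onset. The default `c(2, 4)`
#'   means the window from 4 s to 2 s before onset.
#' @return An object of class `stimulus_protocol`.
#' @export
#' @examples
#' stimulus_protocol(onsets_s = c(15, 35, 55, 75, 95))
stimulus_protocol <- function(onsets_s, stim_duration_s = 5, isi_s = 15,
                              frame_rate_hz = 30,
                              pre_baseline_window_s = c(2, 4)) {
  if (!is.numeric(onsets_s) || length(onsets_s) < 1 || anyNA(onsets_s))
    stop("`onsets_s` must be a non-empty numeric vector", call. = FALSE)
  if (length(onsets_s) > 1 && any(diff(onsets_s) < stim_duration_s))
    stop("stimulus onsets must be strictly increasing and at least one ",
         "stimulus duration apart", call. = FALSE)
  if (!isTRUE(stim_duration_s > 0) || !isTRUE(isi_s > 0) ||
      !isTRUE(frame_rate_hz > 0))
    stop("`stim_duration_s`, `isi_s` and `frame_rate_hz` must be positive",
         call. = FALSE)
  if (length(pre_baseline_window_s) != 2 || any(pre_baseline_window_s < 0) ||
      diff(sort(pre_baseline_window_s)) <= 0)
    stop("`pre_baseline_window_s` must be two distinct non-negative offsets",
         call. = FALSE)
  structure(
    list(onsets_s = as.numeric(onsets_s),
         stim_duration_s = stim_duration_s,
         isi_s = isi_s,
         frame_rate_hz = frame_rate_hz,
         pre_baseline_window_s = sort(pre_baseline_window_s)),
    class = "stimulus_protocol"
  )
}

#' Default 5-repetition grating protocol
#'
#' The canonical protocol: `n_reps` stimuli of `stim_duration_s` seconds
#' separated by `isi_s` seconds, with one inter-stimulus interval of lead-in
#' before the first onset (so pre-stimulus baselines exist for every
#' repetition).
#'
#' @inheritParams stimulus_protocol
#' @param n_reps Number of stimulus repetitions (default 5).
#' @return A `stimulus_protocol`.
#' @export
default_protocol <- function(n_reps = 5, stim_duration_s = 5, isi_s = 15,
                             frame_rate_hz = 30) {
  if (!isTRUE(n_reps >= 1)) stop("`n_reps` must be >= 1", call. = FALSE)
  onsets <- isi_s + (seq_len(n_reps) - 1) * (stim_duration_s + isi_s)
  stimulus_protocol(onsets, stim_duration_s, isi_s, frame_rate_hz)
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("Stimulus protocol:", length(x$onsets_s), "repetitions,",
      x$stim_duration_s, "s stimulus,", x$isi_s, "s ISI,",
      x$frame_rate_hz, "frames/s\n")
  cat("  onsets (s):", paste(x$onsets_s, collapse = ", "), "\n")
  invisible(x)
}

# sample times of an n-frame trace
frame_times <- function(n, frame_rate_hz) (seq_len(n) - 1) / frame_rate_hz

# logical mask: TRUE for samples inside any stimulus window
stim_sample_mask <- function(n, protocol) {
  t <- frame_times(n, protocol$frame_rate_hz)
  mask <- rep(FALSE, n)
  for (on in protocol$onsets_s)
    mask <- mask | (t >= on & t <= on + protocol$stim_duration_s)
  mask
}

# indices of samples in [from, to]; empty when the window is off-trace
window_indices <- function(n, frame_rate_hz, from, to) {
  t <- frame_times(n, frame_rate_hz)
  which(t >= from & t <= to)
}

# trace duration in seconds (time of last sample)
trace_end_s <- function(n, frame_rate_hz) (n - 1) / frame_rate_hz
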