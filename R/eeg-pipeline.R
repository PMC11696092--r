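#' @title EEG preprocessing pipeline
#' @description Transforms continuous multichannel EEG plus word-onset
#'   events into per-participant, per-condition token feature vectors:
#'   zero-phase band-pass filtering, word-locked epoching with token-word
#'   sharing and pre-stimulus baseline correction, average re-referencing,
#'   and concatenation of electrode-by-time windows into condition vectors.
#' @name eeg_pipeline
NULL

#' Default 28-channel 10-20 montage
#'
#' Standard 10-20 electrode names including the centro-parietal sites that
#' define the early (N400-like) and late (P600-like) condition subsets.
#'
#' @return Character vector of 28 electrode names.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
    "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
    "O1", "Oz", "O2")
}

#' Construct a continuous EEG recording
#'
#' @param data Numeric matrix, electrodes x samples (microvolts).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param electrode_names Unique electrode names, one per row of `data`.
#' @return An object of class `continuous_recording`.
#' @export
continuous_recording <- function(data, sampling_rate, electrode_names) {
  data <- as.matrix(data)
  if (sampling_rate <= 0) stop_invalid("sampling_rate must be > 0")
  if (length(electrode_names) != nrow(data) ||
      anyDuplicated(electrode_names)) {
    stop_invalid("electrode_names must be unique, one per data row")
  }
  if (anyNA(data)) stop_invalid("recording contains missing samples")
  structure(list(data = data, sampling_rate = sampling_rate,
                 electrode_names = as.character(electrode_names)),
            class = "continuous_recording")
}

# steady-state initial conditions for a direct-form II transposed IIR
# filter (unit-step response state), so forward/backward passes start
# without a start-up transient
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  if (n == 1L) return(numeric(0))
  comp <- rbind(-a[-1] / a[1], cbind(diag(n - 2L), 0))
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1L) - t(comp), B)
}

# zero-phase IIR filtering of matrix columns: odd-reflection padding,
# forward pass, time-reversed second pass, both started from steady state
zero_phase_filter <- function(b, a, x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  pad <- 3L * (n - 1L)
  if (nrow(x) <= pad + 1L) {
    stop_invalid("signal too short to filter (need > ", pad + 1L,
                 " samples)")
  }
  out <- cpp_filtfilt_mat(b, a, x, pad, lfilter_zi(b, a))
  if (vec) drop(out) else out
}

#' Zero-phase band-pass filter
#'
#' Order-4 Butterworth band-pass applied forward and backward (filtfilt
#' with odd-reflection edge padding and steady-state initialisation),
#' giving zero phase distortion — standard ERP practice. The passband gain
#' is ~1 and out-of-band components (DC drift, line-frequency noise) are
#' strongly attenuated.
#'
#' @param recording A [continuous_recording()].
#' @param low_hz,high_hz Band edges; `0 < low_hz < high_hz < Nyquist`.
#' @return A filtered `continuous_recording` of the same shape.
#' @export
bandpass_filter <- function(recording, low_hz = 0.5, high_hz = 30) {
  stopifnot(inherits(recording, "continuous_recording"))
  fs <- recording$sampling_rate
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stop_invalid("need 0 < low_hz < high_hz < sampling_rate / 2")
  }
  bf <- signal::butter(4, c(low_hz, high_hz) / (fs / 2), type = "pass")
  out <- t(zero_phase_filter(bf$b, bf$a, t(recording$data)))
  continuous_recording(out, fs, recording$electrode_names)
}

#' Epoch a recording around word onsets and align tokens to words
#'
#' Extracts a fixed window of `tmin` to `tmax` seconds around each word
#' onset (default -0.2 to +1.5 s, i.e. `round(1.7 * fs)` samples), subtracts
#' the per-channel mean of the pre-onset `[-200, 0)` ms interval from the
#' whole epoch (baseline correction), and duplicates each word's epoch for
#' every token mapped to that word, so tokens of one word share identical
#' EEG data. Events whose window would run past the recording edge are
#' dropped with a warning and counted.
#'
#' @param recording A [continuous_recording()] (typically already
#'   band-pass filtered).
#' @param events Data frame with columns `onset_s` and `word_index`.
#' @param token_map Data frame with columns `token_index` and `word_index`;
#'   defaults to one token per word.
#' @return An `epoch_set`: `epochs` array (tokens x electrodes x samples),
#'   `window = c(-0.2, 1.5)`, `sampling_rate`, `token_map`,
#'   `electrode_names`, and `n_dropped`.
#' @export
epoch_and_align <- function(recording, events, token_map = NULL,
                            tmin = -0.2, tmax = 1.5) {
  stopifnot(inherits(recording, "continuous_recording"))
  fs <- recording$sampling_rate
  n_pre <- round(-tmin * fs)              # samples in [tmin, 0)
  n_post <- round(tmax * fs)              # samples in [0, tmax)
  n_epoch <- n_pre + n_post               # round(1.7 s * fs) for defaults
  if (is.null(token_map)) {
    token_map <- data.frame(token_index = seq_len(nrow(events)),
                            word_index = events$word_index)
  }
  n_samp <- ncol(recording$data)
  onset_idx <- round(events$onset_s * fs) + 1L
  lo <- onset_idx - n_pre
  hi <- onset_idx + n_post - 1L
  keep <- lo >= 1L & hi <= n_samp
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    warning(n_dropped, " event(s) too close to the recording edge; dropped",
            call. = FALSE)
  }
  kept_words <- events$word_index[keep]
  n_ch <- nrow(recording$data)
  keep_idx <- which(keep)
  # gather all epochs in one indexing pass: channels x (word, sample)
  col_idx <- unlist(lapply(keep_idx, function(w) lo[w]:hi[w]))
  gathered <- recording$data[, col_idx, drop = FALSE]
  dim(gathered) <- c(n_ch, n_epoch, length(kept_words))
  word_epochs <- aperm(gathered, c(3L, 1L, 2L))
  base <- word_epochs[, , seq_len(n_pre), drop = FALSE]
  dim(base) <- c(length(kept_words) * n_ch, n_pre)
  word_epochs <- word_epochs - rowMeans(base)
  tm <- token_map[token_map$word_index %in% kept_words, , drop = FALSE]
  row_of_word <- match(tm$word_index, kept_words)
  epochs <- word_epochs[row_of_word, , , drop = FALSE]
  structure(list(epochs = epochs, window = c(tmin, tmax),
                 sampling_rate = fs, token_map = tm,
                 electrode_names = recording$electrode_names,
                 n_dropped = n_dropped),
            class = "epoch_set")
}

#' Average re-reference epochs
#'
#' Re-expresses every sample relative to the instantaneous mean over all
#' electrodes (whole-brain average reference), so the cross-electrode mean
#' is 0 at every time point. Idempotent.
#'
#' @param epochs An `epoch_set` with >= 2 electrodes.
#' @return The re-referenced `epoch_set`.
#' @export
average_reference <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$epochs)
  if (d[2] < 2L) stop_invalid("average reference needs >= 2 electrodes")
  arr <- aperm(epochs$epochs, c(2L, 1L, 3L))    # ch x token x sample
  chmean <- colMeans(arr)                       # token x sample
  arr <- arr - rep(as.vector(chmean), each = d[2])
  epochs$epochs <- aperm(arr, c(2L, 1L, 3L))
  epochs
}

#' Spatiotemporal condition definitions
#'
#' The four analysis conditions: `full` (all electrodes, 0-1500 ms),
#' `early` (N400-associated sites C3, Cz, C4, P3, Pz, P4, CP1, CP2,
#' 250-450 ms), `late` (P600-associated sites C3, Cz, C4, P3, Pz, P4,
#' 500-800 ms) and `baseline` (all electrodes, -200-0 ms pre-stimulus
#' control). Windows are half-open `[start, end)` in milliseconds relative
#' to word onset, so at 250 Hz the full window holds exactly 375 samples.
#'
#' @param name One of `"full"`, `"early"`, `"late"`, `"baseline"`.
#' @param montage Electrode names available (used by `"full"`/`"baseline"`).
#' @return List with `name`, `electrodes`, `window_ms`.
#' @export
condition_spec <- function(name = c("full", "early", "late", "baseline"),
                           montage = default_montage()) {
  name <- match.arg(name)
  switch(name,
    full = list(name = "full", electrodes = montage,
                window_ms = c(0, 1500)),
    early = list(name = "early",
                 electrodes = c("C3", "Cz", "C4", "P3", "Pz", "P4",
                                "CP1", "CP2"),
                 window_ms = c(250, 450)),
    late = list(name = "late",
                electrodes = c("C3", "Cz", "C4", "P3", "Pz", "P4"),
                window_ms = c(500, 800)),
    baseline = list(name = "baseline", electrodes = montage,
                    window_ms = c(-200, 0))
  )
}

#' Build per-token condition feature vectors
#'
#' Selects the condition's electrodes (in montage order) and time window
#' (half-open `[start, end)` in ms, mapped to sample indices), then
#' concatenates the time-contiguous samples electrode by electrode into one
#' feature vector per token. With the default montage at 250 Hz this yields
#' D = 10500 for the full window, 400 for early, and 450 for late.
#'
#' @param epochs A baseline-corrected, re-referenced `epoch_set`.
#' @param condition A [condition_spec()] (or one of its names).
#' @return An `eeg_feature_matrix`: list with `vectors` (tokens x D),
#'   `condition`, `electrodes`, `window_ms`, `token_map`.
#' @export
build_condition_vectors <- function(epochs, condition) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.character(condition)) {
    condition <- condition_spec(condition, montage = epochs$electrode_names)
  }
  unknown <- setdiff(condition$electrodes, epochs$electrode_names)
  if (length(unknown)) {
    stop_invalid("unknown electrode(s): ", paste(unknown, collapse = ", "))
  }
  fs <- epochs$sampling_rate
  tmin <- epochs$window[1]
  # within-epoch sample index for time t ms: offset from the first sample
  first <- round(condition$window_ms[1] / 1000 * fs) - round(tmin * fs) + 1L
  n_win <- round(diff(condition$window_ms) / 1000 * fs)
  sample_idx <- first:(first + n_win - 1L)
  n_epoch <- dim(epochs$epochs)[3]
  if (sample_idx[1] < 1L || sample_idx[n_win] > n_epoch) {
    stop_invalid("condition window outside the epoch")
  }
  elec_idx <- which(epochs$electrode_names %in% condition$electrodes)
  n_tok <- dim(epochs$epochs)[1]
  vectors <- matrix(NA_real_, n_tok, length(elec_idx) * n_win)
  for (i in seq_len(n_tok)) {
    seg <- epochs$epochs[i, elec_idx, sample_idx, drop = FALSE]
    # electrode-major concatenation: each electrode's window is contiguous
    vectors[i, ] <- as.vector(t(seg[1, , ]))
  }
  structure(list(vectors = vectors, condition = condition$name,
                 electrodes = epochs$electrode_names[elec_idx],
                 window_ms = condition$window_ms,
                 token_map = epochs$token_map),
            class = "eeg_feature_matrix")
}
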