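# EFP feature extraction: 12-s Pz segment -> notch -> Stockwell ->
# 10 energy-uniform bands x 48 time points (4-Hz grid).

#' Feature window container
#'
#' @param values numeric matrix, bands x time blocks, of band-averaged
#'   S-transform amplitudes on the 4-Hz grid (non-negative, finite).
#' @param end_time time of the window's last sample (s); the window covers
#'   `(end_time - 12, end_time]`.
#' @return object of class `efp_features`.
#' @export
feature_window <- function(values, end_time) {
  stopifnot(is.matrix(values))
  if (!all(is.finite(values)) || any(values < -1e-12))
    stop_param("feature values must be finite and non-negative")
  structure(list(values = values, end_time = end_time),
            class = "efp_features")
}

#' Extract one EFP feature window from an EEG recording
#'
#' Takes the 12 s of Pz ending at `end_time`, removes 50-Hz line
#' interference, computes the Stockwell transform over the band range,
#' averages amplitudes within each energy-uniform band, and reduces the time
#' axis to the 4-Hz feature grid by non-overlapping block means. For the
#' standard geometry (10 bands, 12-s window at 250 Hz) the result is the
#' 10 x 48 window the EFP model consumes.
#'
#' @param recording an [eeg_recording()] containing Pz.
#' @param bands an [band_definition()].
#' @param end_time window end time (s); the recording must contain the 12 s
#'   ending there. Times are snapped to the nearest EEG sample, so jitter
#'   below half a sampling interval does not change the output.
#' @param window window length (s).
#' @param out_rate feature grid rate (Hz).
#' @return an [feature_window()].
#' @export
extract_features <- function(recording, bands, end_time, window = 12,
                             out_rate = 4) {
  stopifnot(inherits(recording, "efp_eeg"), inherits(bands, "efp_bands"))
  rate <- recording$rate
  nseg <- round(window * rate)
  i_end <- round((end_time - recording$t0) * rate)
  if (i_end < nseg || i_end > ncol(recording$data))
    stop_param("recording does not contain the ", window,
               " s ending at t = ", end_time, " s")
  x <- eeg_channel(recording, "Pz")[(i_end - nseg + 1):i_end]
  x <- notch_filter(x, rate)
  fr <- c(bands$edges[1], bands$edges[length(bands$edges)])
  tf <- stockwell_transform(x, rate, f_range = fr)
  bi <- band_index(bands, tf$freqs)
  keep <- !is.na(bi)
  # band-average the amplitude rows
  bmeans <- rowsum(tf$amplitudes[keep, , drop = FALSE], bi[keep]) /
    as.vector(table(bi[keep]))
  # block-average the time axis to the feature grid
  n_blocks <- round(window * out_rate)
  blk <- floor((seq_len(nseg) - 1) / (nseg / n_blocks)) + 1L
  vals <- t(rowsum(t(bmeans), blk) / as.vector(table(blk)))
  dimnames(vals) <- NULL
  feature_window(vals, end_time = end_time)
}

#' Feature matrix for many window end-times
#'
#' Flattens [extract_features()] windows (column-major, band index fastest)
#' into the rows of a matrix, one row per requested end time.
#'
#' @inheritParams extract_features
#' @param times vector of window end times (s).
#' @return list with `x` (matrix, `length(times)` x `bands*blocks`) and
#'   `times`.
#' @export
feature_matrix <- function(recording, bands, times, window = 12,
                           out_rate = 4) {
  rows <- lapply(times, function(tt)
    as.vector(extract_features(recording, bands, tt, window, out_rate)$values))
  list(x = do.call(rbind, rows), times = times)
}
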