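#' Block schedules for neurofeedback protocols
#'
#' A schedule is an ordered set of labelled, non-overlapping blocks with
#' onsets and durations in seconds. Block intervals are half-open:
#' `[onset, onset + duration)`.
#'
#' @param blocks data.frame with columns `label`, `onset`, `duration`.
#' @param protocol_name free-text protocol identifier.
#' @return An object of class `efp_schedule` (a data.frame with attribute
#'   `protocol_name`).
#' @export
nf_schedule <- function(blocks, protocol_name = "custom") {
  stopifnot(is.data.frame(blocks),
            all(c("label", "onset", "duration") %in% names(blocks)))
  blocks <- blocks[c("label", "onset", "duration")]
  blocks$label <- as.character(blocks$label)
  if (nrow(blocks) < 1L) stop_param("schedule must contain at least one block")
  if (any(!is.finite(blocks$onset)) || any(blocks$duration <= 0))
    stop_param("block onsets must be finite and durations positive")
  if (is.unsorted(blocks$onset, strictly = TRUE))
    stop_param("block onsets must be strictly increasing")
  ends <- blocks$onset + blocks$duration
  if (any(ends[-nrow(blocks)] > blocks$onset[-1] + 1e-9))
    stop_param("schedule blocks must not overlap")
  structure(blocks, class = c("efp_schedule", "data.frame"),
            protocol_name = protocol_name)
}

#' Build a standard protocol schedule
#'
#' * `"efp_nf"`: one EEG neurofeedback training session -- a 3-min
#'   resting-state baseline followed by five cycles of Watch (60 s) and
#'   Regulate (180 s); 1380 s of timed blocks in total. Debrief segments
#'   between cycles are untimed and not scheduled.
#' * `"fmri_nf"`: one rt-fMRI neurofeedback assessment run -- a 54-s
#'   resting-state baseline followed by two cycles of Watch (60 s),
#'   Regulate (60 s), Washout (feedback display, 9 s) and Fixation (15 s);
#'   342 s in total.
#'
#' @param protocol one of `"efp_nf"`, `"fmri_nf"`.
#' @return An [nf_schedule()] object.
#' @examples
#' s <- build_schedule("efp_nf")
#' sum(s$duration)  # 1380
#' @export
build_schedule <- function(protocol = c("efp_nf", "fmri_nf")) {
  if (!is.character(protocol) || length(protocol) != 1L ||
      !protocol %in% c("efp_nf", "fmri_nf"))
    stop_param("unknown protocol; expected \"efp_nf\" or \"fmri_nf\"")
  if (protocol == "efp_nf") {
    labels <- c("Rest", rep(c("Watch", "Regulate"), 5))
    durs <- c(180, rep(c(60, 180), 5))
  } else {
    labels <- c("Rest", rep(c("Watch", "Regulate", "Washout", "Fixation"), 2))
    durs <- c(54, rep(c(60, 60, 9, 15), 2))
  }
  onsets <- cumsum(c(0, durs[-length(durs)]))
  nf_schedule(data.frame(label = labels, onset = onsets, duration = durs),
              protocol_name = protocol)
}

schedule_duration <- function(schedule) {
  max(schedule$onset + schedule$duration)
}

# Block label at each time (half-open intervals); times outside any block
# get NA.
schedule_label_at <- function(schedule, times) {
  idx <- findInterval(times, schedule$onset)
  lab <- rep(NA_character_, length(times))
  ok <- idx >= 1L
  inside <- ok & times < (schedule$onset[pmax(idx, 1L)] +
                          schedule$duration[pmax(idx, 1L)])
  lab[inside] <- schedule$label[idx[inside]]
  lab
}

# Index of the block containing each time (NA outside blocks).
schedule_block_at <- function(schedule, times) {
  idx <- findInterval(times, schedule$onset)
  out <- rep(NA_integer_, length(times))
  ok <- idx >= 1L
  inside <- ok & times < (schedule$onset[pmax(idx, 1L)] +
                          schedule$duration[pmax(idx, 1L)])
  out[inside] <- idx[inside]
  out
}
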