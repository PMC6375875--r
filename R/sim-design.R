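#' Trial-timing configuration
#'
#' Timing of one trial in the simulated session: a fixation cross, a video
#' (static phase, dynamic phase, static phase) and a fixed post-video
#' padding standing in for the self-paced response plus feedback slide.
#'
#' @param fixation_ms fixation duration before video onset.
#' @param video_ms total video duration (static + dynamic + static).
#' @param dynamic_onset_ms start of the dynamic phase, ms from video onset.
#' @param dynamic_offset_ms end of the dynamic phase, ms from video onset.
#' @param padding_ms response/feedback padding after the video.
#' @param srate sampling rate (Hz) in which onset samples are expressed.
#' @return list of timing parameters.
#' @export
design_timing <- function(fixation_ms = 1000, video_ms = 6000,
                          dynamic_onset_ms = 2000, dynamic_offset_ms = 4000,
                          padding_ms = 2000, srate = 1000) {
  stopifnot(fixation_ms >= 0, video_ms > 0,
            dynamic_onset_ms < dynamic_offset_ms,
            dynamic_offset_ms <= video_ms)
  list(fixation_ms = fixation_ms, video_ms = video_ms,
       dynamic_onset_ms = dynamic_onset_ms,
       dynamic_offset_ms = dynamic_offset_ms,
       padding_ms = padding_ms, srate = srate)
}

#' Generate a balanced randomized trial design
#'
#' Builds the per-trial event table of a session: `n_blocks` blocks, each
#' containing `trials_per_condition` trials of every condition in a seeded
#' random order. Video onsets are spaced by
#' `fixation + video + padding`, so consecutive onsets are separated by at
#' least the video length plus the fixation period.
#'
#' @param n_blocks number of blocks (>= 1).
#' @param trials_per_condition trials of each condition per block (>= 1).
#' @param conditions character vector of condition labels.
#' @param timing a [design_timing()] list.
#' @param seed integer seed controlling the within-block condition order.
#' @return A `data.frame` of class `eeg_design` with columns `block`,
#'   `trial` (1-based within session), `condition`, `onset_sample`
#'   (video onset, in samples at `timing$srate`). The timing list is kept
#'   as attribute `"timing"`.
#' @export
make_design <- function(n_blocks = 4, trials_per_condition = 10,
                        conditions = c("happy", "sad", "neutral", "nonbio"),
                        timing = design_timing(), seed = 1) {
  if (length(conditions) == 0) stop("`conditions` must be non-empty")
  stopifnot(n_blocks >= 1, trials_per_condition >= 1)
  set.seed(seed)
  cond <- unlist(lapply(seq_len(n_blocks), function(b) {
    v <- rep(conditions, each = trials_per_condition)
    sample(v)
  }))
  n <- length(cond)
  trial_len_ms <- timing$fixation_ms + timing$video_ms + timing$padding_ms
  start_ms <- (seq_len(n) - 1) * trial_len_ms
  onset <- as.integer(round((start_ms + timing$fixation_ms) *
                              timing$srate / 1000))
  d <- data.frame(
    block = rep(seq_len(n_blocks),
                each = trials_per_condition * length(conditions)),
    trial = seq_len(n),
    condition = cond,
    onset_sample = onset,
    stringsAsFactors = FALSE
  )
  attr(d, "timing") <- timing
  class(d) <- c("eeg_design", "data.frame")
  d
}
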