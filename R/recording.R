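#' Continuous EEG recording container
#'
#' A lightweight container for a continuous multichannel recording:
#' a channels-by-samples matrix (volts), its sampling rate, channel names,
#' 3-D sensor positions (meters, head-centered) and the reference state.
#'
#' @param data numeric matrix, channels x samples, in volts.
#' @param srate sampling rate in Hz.
#' @param ch_names character vector of channel names, length `nrow(data)`.
#' @param positions numeric matrix, channels x 3, sensor positions in meters.
#' @param reference reference state, `"common"` or `"average"`.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(data, srate, ch_names, positions,
                          reference = c("common", "average")) {
  reference <- match.arg(reference)
  if (!is.matrix(data)) data <- matrix(data, nrow = 1L)
  if (length(ch_names) != nrow(data))
    stop("`ch_names` must have one entry per data row")
  if (!is.matrix(positions) || nrow(positions) != nrow(data) ||
      ncol(positions) != 3L)
    stop("`positions` must be a channels x 3 matrix")
  if (any(!is.finite(data)))
    stop("recording data contains non-finite values")
  structure(
    list(data = data, srate = as.numeric(srate),
         ch_names = as.character(ch_names), positions = positions,
         reference = reference),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %s reference\n",
    nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate, x$reference))
  invisible(x)
}

#' Number of channels / samples of a recording
#' @param rec an `eeg_recording`.
#' @return integer count.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$data)

# internal: replace the data matrix, keeping metadata
update_data <- function(rec, data, srate = rec$srate,
                        reference = rec$reference) {
  rec$data <- data
  rec$srate <- srate
  rec$reference <- reference
  rec
}
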