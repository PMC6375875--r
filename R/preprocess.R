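# Preprocessing: resample -> high-pass -> line-noise removal ->
# bad-channel detection/interpolation -> common average reference.

#' Preprocessing configuration
#'
#' @param target_rate resampling target (Hz).
#' @param highpass_cutoff high-pass cutoff (Hz), > 0.
#' @param line_freq mains base frequency (Hz); notched with its in-band
#'   harmonics.
#' @param bad_channel_z robust kurtosis z-score threshold for bad-channel
#'   flagging.
#' @param quality_reject_frac recordings with more than this fraction of
#'   flagged channels are marked as rejected by the quality gate.
#' @param blink_regress if `TRUE`, a blink estimate from the most anterior
#'   channels is regressed out of all channels (off by default).
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_rate = 250, highpass_cutoff = 0.1,
                              line_freq = 50, bad_channel_z = 5,
                              quality_reject_frac = 0.2,
                              blink_regress = FALSE) {
  stopifnot(highpass_cutoff > 0, target_rate > 0)
  structure(list(target_rate = target_rate,
                 highpass_cutoff = highpass_cutoff, line_freq = line_freq,
                 bad_channel_z = bad_channel_z,
                 quality_reject_frac = quality_reject_frac,
                 blink_regress = blink_regress),
            class = "preprocess_config")
}

# Zero-phase frequency-domain filtering: each channel's spectrum is
# multiplied by a real, non-negative magnitude response (Butterworth
# squared-magnitude prototypes below), i.e. the zero-phase equivalent of a
# forward-backward IIR pass, in 2 FFTs per channel. Channels are demeaned
# and linearly detrended first to limit circular edge effects.
fft_filter_rows <- function(data, srate, response_fun) {
  n <- ncol(data)
  f <- (seq_len(n) - 1) * srate / n
  f <- pmin(f, srate - f)              # two-sided -> folded frequency
  H <- response_fun(f)
  H0 <- response_fun(0)                # DC gain applied to the trend
  t_idx <- seq_len(n)
  out <- data
  for (ch in seq_len(nrow(data))) {
    x <- data[ch, ]
    trend <- stats::lm.fit(cbind(1, t_idx), x)$coefficients
    base <- trend[1] + trend[2] * t_idx
    out[ch, ] <- Re(stats::fft(stats::fft(x - base) * H,
                               inverse = TRUE)) / n + H0 * base
  }
  out
}

# squared-magnitude Butterworth prototypes (zero-phase effective order 2*n)
butter_mag_hp <- function(fc, n = 2) function(f) {
  r <- (f / fc)^(2 * n)
  r / (1 + r)
}
butter_mag_lp <- function(fc, n = 4) function(f) 1 / (1 + (f / fc)^(2 * n))
butter_mag_notch <- function(f0, bw, n = 2) function(f) {
  u <- (bw * f) / (f^2 - f0^2)
  out <- 1 / (1 + u^(2 * n))
  out[!is.finite(u)] <- 0
  out
}

#' Resample a recording (downsampling only)
#'
#' Zero-phase anti-alias low-pass (Butterworth magnitude, cutoff 0.45 x
#' target rate) followed by linear interpolation at the new sample times.
#' Duration is preserved to within one sample.
#'
#' @param rec an `eeg_recording`.
#' @param target_rate new sampling rate (Hz), at most `rec$srate`.
#' @return resampled `eeg_recording`.
#' @export
resample_recording <- function(rec, target_rate) {
  if (target_rate > rec$srate)
    stop("upsampling not supported: target_rate exceeds the input rate")
  if (target_rate == rec$srate) return(rec)
  data <- fft_filter_rows(rec$data, rec$srate,
                          butter_mag_lp(0.45 * target_rate))
  n <- ncol(data)
  t_old <- (seq_len(n) - 1) / rec$srate
  n_new <- floor(t_old[n] * target_rate) + 1L
  t_new <- (seq_len(n_new) - 1) / target_rate
  out <- matrix(0, nrow(data), n_new)
  for (ch in seq_len(nrow(data)))
    out[ch, ] <- stats::approx(t_old, data[ch, ], xout = t_new)$y
  update_data(rec, out, srate = target_rate)
}

#' High-pass filter a recording
#'
#' Zero-phase (forward-backward) second-order Butterworth high-pass;
#' effective order 4. Removes DC and slow drift while leaving the 8-13 Hz
#' band essentially untouched at the default 0.1 Hz cutoff.
#'
#' @param rec an `eeg_recording`.
#' @param cutoff cutoff frequency (Hz), below Nyquist.
#' @return filtered `eeg_recording`.
#' @export
highpass_recording <- function(rec, cutoff = 0.1) {
  nyq <- rec$srate / 2
  if (cutoff >= nyq) stop("cutoff must be below the Nyquist frequency")
  update_data(rec, fft_filter_rows(rec$data, rec$srate,
                                   butter_mag_hp(cutoff)))
}

#' Remove mains line noise and its harmonics
#'
#' Zero-phase Butterworth band-stop notches of `bandwidth` Hz at the base
#' frequency and every harmonic below Nyquist.
#'
#' @param rec an `eeg_recording`.
#' @param base_freq mains frequency (Hz), below Nyquist.
#' @param bandwidth total notch width (Hz).
#' @return filtered `eeg_recording`.
#' @export
remove_line_noise <- function(rec, base_freq = 50, bandwidth = 2) {
  nyq <- rec$srate / 2
  if (base_freq >= nyq) stop("base_freq must be below the Nyquist frequency")
  harmonics <- base_freq * seq_len(floor((nyq * 0.98) / base_freq))
  resp <- function(f) {
    H <- rep(1, length(f))
    for (f0 in harmonics) H <- H * butter_mag_notch(f0, bandwidth)(f)
    H
  }
  update_data(rec, fft_filter_rows(rec$data, rec$srate, resp))
}

excess_kurtosis <- function(x) {
  v <- stats::var(x) * (length(x) - 1) / length(x)
  if (v == 0) return(Inf)  # constant channel: flagged by convention
  mean((x - mean(x))^4) / v^2 - 3
}

#' Detect bad channels by kurtosis
#'
#' Computes each channel's excess kurtosis and converts it to a robust
#' z-score across channels (median / scaled MAD, constant 1.4826); channels
#' with z above `z_thresh` are flagged. Constant channels get infinite
#' kurtosis and are always flagged. Deterministic.
#'
#' @param rec an `eeg_recording` with at least 3 channels.
#' @param z_thresh robust z threshold (default 5).
#' @return data.frame `channel`, `kurtosis`, `z`, `flagged`, in channel
#'   order.
#' @export
detect_bad_channels <- function(rec, z_thresh = 5) {
  if (n_channels(rec) < 3) stop("need at least 3 channels")
  k <- apply(rec$data, 1, excess_kurtosis)
  fin <- is.finite(k)
  med <- stats::median(k[fin])
  s <- 1.4826 * stats::median(abs(k[fin] - med))
  if (!is.finite(s) || s == 0) s <- .Machine$double.eps
  z <- (k - med) / s
  data.frame(channel = rec$ch_names, kurtosis = k, z = z,
             flagged = z > z_thresh, stringsAsFactors = FALSE)
}

#' Interpolate channels from their neighbors
#'
#' Replaces each listed channel by an inverse-distance-weighted average of
#' its `k` nearest good channels; good channels are untouched.
#'
#' @param rec an `eeg_recording`.
#' @param bad character vector of channel names to replace (fewer than half
#'   the montage).
#' @param k number of neighbors.
#' @param clusters optional cluster list; a warning is raised if `bad`
#'   covers an entire cluster.
#' @return `eeg_recording` with interpolated channels.
#' @export
interpolate_channels <- function(rec, bad, k = 4, clusters = NULL) {
  if (length(bad) == 0) return(rec)
  bad_idx <- match(bad, rec$ch_names)
  if (anyNA(bad_idx)) stop("unknown channel name(s) in `bad`")
  if (length(bad_idx) >= n_channels(rec) / 2)
    stop("refusing to interpolate half the montage or more")
  if (!is.null(clusters)) {
    for (nm in c("central", "occipital")) {
      if (!is.null(clusters[[nm]]) && all(clusters[[nm]] %in% bad))
        warning("bad channels cover the entire ", nm, " cluster")
    }
  }
  good <- setdiff(seq_len(n_channels(rec)), bad_idx)
  data <- rec$data
  for (b in bad_idx) {
    d <- sqrt(colSums((t(rec$positions[good, , drop = FALSE]) -
                         rec$positions[b, ])^2))
    nb <- good[order(d)][seq_len(min(k, length(good)))]
    w <- 1 / pmax(d[order(d)][seq_len(length(nb))], 1e-9)
    w <- w / sum(w)
    data[b, ] <- as.vector(w %*% rec$data[nb, , drop = FALSE])
  }
  update_data(rec, data)
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean over channels from every channel, so
#' per-sample channel means are zero. Idempotent; pairwise channel
#' differences are unchanged.
#'
#' @param rec an `eeg_recording`.
#' @return average-referenced `eeg_recording`.
#' @export
average_reference <- function(rec) {
  data <- sweep(rec$data, 2, colMeans(rec$data), "-")
  update_data(rec, data, reference = "average")
}

# Regress a low-frequency frontal blink estimate out of every channel.
blink_regress_recording <- function(rec, n_front = 4) {
  ord <- order(rec$positions[, 2], decreasing = TRUE)
  front <- rec$data[ord[seq_len(min(n_front, n_channels(rec)))], ,
                    drop = FALSE]
  ref <- fft_filter_rows(matrix(colMeans(front), nrow = 1), rec$srate,
                         butter_mag_lp(5, n = 2))[1, ]
  ref <- ref - mean(ref)
  denom <- sum(ref^2)
  if (denom == 0) return(rec)
  beta <- (rec$data %*% ref) / denom
  update_data(rec, rec$data - beta %*% t(ref))
}

#' Run the full preprocessing chain
#'
#' Fixed stage order: resample, high-pass, line-noise removal, bad-channel
#' detection and interpolation, optional blink regression, common average
#' reference. Re-running on identical input is bit-identical (all stages
#' are deterministic). Channel count and names never change; bad channels
#' are replaced, not dropped.
#'
#' @param rec an `eeg_recording`.
#' @param config a [preprocess_config()].
#' @param clusters optional cluster list, passed to the interpolation
#'   warning check.
#' @return The preprocessed `eeg_recording`, with attributes
#'   `"bad_report"` (the [detect_bad_channels()] table), `"rejected"`
#'   (quality gate: fraction of flagged channels above
#'   `quality_reject_frac`) and `"steps"` (ordered stage log).
#' @export
preprocess <- function(rec, config = preprocess_config(), clusters = NULL) {
  steps <- character(0)
  if (config$target_rate < rec$srate) {
    rec <- resample_recording(rec, config$target_rate)
    steps <- c(steps, sprintf("resample:%gHz", config$target_rate))
  } else if (config$target_rate > rec$srate) {
    stop("target_rate exceeds the recording's sampling rate")
  }
  # high-pass and notch responses share one zero-phase filtering pass
  nyq <- rec$srate / 2
  if (config$highpass_cutoff >= nyq)
    stop("highpass cutoff must be below the Nyquist frequency")
  harmonics <- config$line_freq *
    seq_len(floor((nyq * 0.98) / config$line_freq))
  hp <- butter_mag_hp(config$highpass_cutoff)
  resp <- function(f) {
    H <- hp(f)
    for (f0 in harmonics) H <- H * butter_mag_notch(f0, 2)(f)
    H
  }
  rec <- update_data(rec, fft_filter_rows(rec$data, rec$srate, resp))
  steps <- c(steps, sprintf("highpass:%gHz", config$highpass_cutoff),
             sprintf("notch:%gHz", config$line_freq))
  report <- detect_bad_channels(rec, config$bad_channel_z)
  bad <- report$channel[report$flagged]
  rejected <- mean(report$flagged) > config$quality_reject_frac
  if (length(bad) > 0 && !rejected) {
    rec <- interpolate_channels(rec, bad, clusters = clusters)
    steps <- c(steps, sprintf("interpolate:%d", length(bad)))
  }
  if (isTRUE(config$blink_regress)) {
    rec <- blink_regress_recording(rec)
    steps <- c(steps, "blink_regress")
  }
  rec <- average_reference(rec)
  steps <- c(steps, "average_reference")
  attr(rec, "bad_report") <- report
  attr(rec, "rejected") <- rejected
  attr(rec, "steps") <- steps
  rec
}
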