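# Suppression index: per-trial late/early band-power ratios over electrode
# clusters, scaled-MAD trial rejection, cluster averaging, log transform.

#' Early/late epoch windows
#'
#' Windows in milliseconds from video onset, half-open `[start, end)`. The
#' defaults place the 1,100 ms early epoch inside the static phase and the
#' 2,050 ms late epoch over the dynamic phase.
#'
#' @param early `c(start_ms, end_ms)` of the baseline (static) epoch.
#' @param late `c(start_ms, end_ms)` of the dynamic epoch.
#' @return list with `early` and `late`.
#' @export
epoch_windows <- function(early = c(800, 1900), late = c(1950, 4000)) {
  stopifnot(early[1] < early[2], late[1] < late[2], early[2] <= late[1])
  list(early = early, late = late)
}

#' Cut early/late epochs around each trial
#'
#' Window edges are converted to samples by flooring `ms * rate / 1000`
#' (half-open, so an epoch of `w` ms at rate `fs` has
#' `floor(end*fs/1000) - floor(start*fs/1000)` samples: 275 early and 513
#' late samples at 250 Hz with the default windows). Trials whose late
#' window runs past the end of the recording are dropped with a warning.
#'
#' @param rec an `eeg_recording` (any reference state).
#' @param design an `eeg_design`; onset samples are rescaled if the design
#'   and recording rates differ.
#' @param windows an [epoch_windows()] list.
#' @return An `epoch_set`: list with 3-D arrays `early` and `late`
#'   (trial x channel x sample), the retained `design` rows, `srate` and
#'   `ch_names`.
#' @export
extract_epochs <- function(rec, design, windows = epoch_windows()) {
  fs <- rec$srate
  timing <- attr(design, "timing")
  scale <- if (is.null(timing)) 1 else fs / timing$srate
  onsets <- floor(design$onset_sample * scale)
  cut_idx <- function(win) {
    s0 <- floor(win[1] * fs / 1000)
    s1 <- floor(win[2] * fs / 1000)
    list(offset = s0, len = s1 - s0)
  }
  e <- cut_idx(windows$early)
  l <- cut_idx(windows$late)
  last_needed <- onsets + l$offset + l$len
  keep <- last_needed <= n_samples(rec) & onsets + e$offset >= 0
  if (any(!keep))
    warning(sum(!keep), " trial(s) dropped: window outside the recording")
  design_kept <- design[keep, , drop = FALSE]
  onsets <- onsets[keep]
  nt <- length(onsets)
  nch <- n_channels(rec)
  cut <- function(off, len) {
    a <- array(0, dim = c(nt, nch, len))
    for (i in seq_len(nt)) {
      s <- onsets[i] + off
      a[i, , ] <- rec$data[, (s + 1):(s + len)]
    }
    a
  }
  structure(list(early = cut(e$offset, e$len), late = cut(l$offset, l$len),
                 design = design_kept, srate = fs, ch_names = rec$ch_names,
                 windows = windows),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d trials x %d channels; early %d / late %d samples @ %g Hz\n",
    dim(x$early)[1], dim(x$early)[2], dim(x$early)[3], dim(x$late)[3],
    x$srate))
  invisible(x)
}

#' Mean band power spectral density of an epoch
#'
#' Hann-tapered periodogram (or Welch with 1 s segments and 50% overlap),
#' one-sided and density-scaled, averaged over the frequency bins with
#' `band[1] <= f <= band[2]`. Input in microvolts gives microvolts^2/Hz.
#'
#' @param x numeric vector, or channels x samples matrix (per-channel
#'   output).
#' @param rate sampling rate (Hz).
#' @param band `c(low, high)` in Hz.
#' @param method `"periodogram"` (default) or `"welch"`.
#' @param nfft FFT length; epochs are zero-padded (after tapering) to this
#'   length so that epochs of different durations are evaluated on the same
#'   frequency grid. Defaults to the next power of two at or above
#'   `max(n, 4 * rate)`; comparing band PSDs of unequal-length epochs on
#'   their native grids would bias their ratio for band-concentrated
#'   signals.
#' @return band PSD (scalar, or one value per channel row). Constant input
#'   returns 0 with a warning (the ratio is undefined downstream).
#' @export
band_psd <- function(x, rate, band = c(8, 13),
                     method = c("periodogram", "welch"), nfft = NULL) {
  method <- match.arg(method)
  if (is.matrix(x))
    return(apply(x, 1, band_psd, rate = rate, band = band, method = method,
                 nfft = nfft))
  n <- length(x)
  if (n < 2 * rate / band[1])
    stop("epoch shorter than 2 cycles of the band's low edge")
  if (stats::var(x) == 0) {
    warning("constant epoch: band PSD is 0")
    return(0)
  }
  if (is.null(nfft)) nfft <- 2^ceiling(log2(max(n, 4 * rate)))
  one_segment <- function(seg) {
    m <- length(seg)
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, m - 1) / (m - 1))
    padded <- c((seg - mean(seg)) * w, numeric(max(0, nfft - m)))
    nf <- length(padded)
    X <- stats::fft(padded)
    kmax <- floor(nf / 2)
    p <- (2 / (rate * sum(w^2))) * Mod(X[2:(kmax + 1)])^2
    f <- (1:kmax) * rate / nf
    sel <- f >= band[1] & f <= band[2]
    mean(p[sel])
  }
  if (method == "periodogram") return(one_segment(x))
  seg_len <- min(n, round(rate))
  step <- max(1, floor(seg_len / 2))
  starts <- seq(1, n - seg_len + 1, by = step)
  mean(vapply(starts, function(s) one_segment(x[s:(s + seg_len - 1)]),
              numeric(1)))
}

#' Per-trial late/early band-power ratios over electrode clusters
#'
#' For every trial and every channel in the central and occipital clusters,
#' computes the late-epoch and early-epoch band PSD and their ratio. Ratios
#' are formed per trial, before any averaging.
#'
#' @param epochs an `epoch_set`.
#' @param clusters list with `central` and `occipital` channel-name vectors
#'   and optionally `band` (default `c(8, 13)` Hz); see [cluster_config()].
#' @param method PSD estimator passed to [band_psd()].
#' @return A `trial_ratio_table` data.frame: `trial`, `condition`,
#'   `channel`, `region`, `psd_early`, `psd_late` (microvolts^2/Hz for
#'   volt-scaled input), `ratio`, `kept`. Channels with zero early PSD are
#'   marked `kept = FALSE` (invalid).
#' @export
trial_ratios <- function(epochs, clusters, method = "periodogram") {
  band <- if (is.null(clusters$band)) c(8, 13) else clusters$band
  regions <- intersect(c("central", "occipital"), names(clusters))
  out <- list()
  for (rg in regions) {
    chs <- clusters[[rg]]
    idx <- match(chs, epochs$ch_names)
    if (anyNA(idx))
      stop("cluster channel(s) missing from the montage: ",
           paste(chs[is.na(idx)], collapse = ", "))
    nt <- dim(epochs$early)[1]
    for (i in seq_len(nt)) {
      pe <- band_psd(epochs$early[i, idx, , drop = TRUE] * 1e6,
                     epochs$srate, band, method)
      pl <- band_psd(epochs$late[i, idx, , drop = TRUE] * 1e6,
                     epochs$srate, band, method)
      if (length(idx) == 1) { pe <- as.numeric(pe); pl <- as.numeric(pl) }
      out[[length(out) + 1]] <- data.frame(
        trial = epochs$design$trial[i],
        condition = epochs$design$condition[i],
        channel = chs, region = rg,
        psd_early = pe, psd_late = pl,
        ratio = ifelse(pe > 0, pl / pe, NA_real_),
        kept = pe > 0,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  class(tab) <- c("trial_ratio_table", "data.frame")
  tab
}

# scaled-MAD outlier mask on a numeric vector; NA treated as not-outlier
mad_outlier_mask <- function(v, k) {
  med <- stats::median(v, na.rm = TRUE)
  s <- 1.4826 * stats::median(abs(v - med), na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    warning("MAD is zero: no trials rejected")
    return(rep(FALSE, length(v)))
  }
  !is.na(v) & abs(v - med) > k * s
}

#' Scaled-MAD trial rejection
#'
#' Within each region cluster, a trial's value is its cluster-mean ratio;
#' trials whose value deviates from the median by more than `k` scaled
#' MADs (constant 1.4826) are marked `kept = FALSE` for that cluster only,
#' symmetrically on both sides. By default the rule is applied within each
#' condition separately (`"cluster_condition_trials"`): pooling conditions
#' (`"cluster_trials"`) centers the median on the bulk of conditions and,
#' when one condition is much more suppressed than the rest, systematically
#' rejects that condition's genuine low-ratio trials, biasing its mean.
#' `"channel"` applies the rule per channel across trials.
#'
#' @param ratios a `trial_ratio_table`.
#' @param k MAD multiplier (default 3).
#' @param granularity `"cluster_condition_trials"` (default),
#'   `"cluster_trials"` (conditions pooled) or `"channel"`.
#' @return the table with updated `kept` flags.
#' @export
mad_reject <- function(ratios, k = 3,
                       granularity = c("cluster_condition_trials",
                                       "cluster_trials", "channel")) {
  granularity <- match.arg(granularity)
  reject_trials <- function(sel) {
    v <- tapply(ratios$ratio[sel], ratios$trial[sel], mean)
    if (length(v) < 5) stop("need at least 5 kept trials per cluster")
    as.numeric(names(v))[mad_outlier_mask(as.numeric(v), k)]
  }
  for (rg in unique(ratios$region)) {
    sel <- ratios$region == rg & ratios$kept
    if (granularity == "cluster_trials") {
      out_trials <- reject_trials(sel)
      ratios$kept[ratios$region == rg &
                    ratios$trial %in% out_trials] <- FALSE
    } else if (granularity == "cluster_condition_trials") {
      for (cd in unique(ratios$condition)) {
        out_trials <- reject_trials(sel & ratios$condition == cd)
        ratios$kept[ratios$region == rg &
                      ratios$trial %in% out_trials] <- FALSE
      }
    } else {
      for (ch in unique(ratios$channel[sel])) {
        cs <- sel & ratios$channel == ch
        ratios$kept[which(cs)[mad_outlier_mask(ratios$ratio[cs], k)]] <- FALSE
      }
    }
  }
  ratios
}

#' Aggregate trial ratios into per-participant suppression scores
#'
#' Per condition and region: the mean ratio over kept trials and cluster
#' channels, log-transformed. One participant yields one row per
#' condition x region (8 rows for the default 4 x 2 design). Log ratio
#' below zero indicates suppression, zero no change, above zero
#' facilitation.
#'
#' @param ratios a `trial_ratio_table` (after [mad_reject()]).
#' @param log_base 10 (default) or `exp(1)`.
#' @param participant participant label for the output rows.
#' @return A `suppression_table` data.frame: `participant`, `condition`,
#'   `region`, `log_ratio`.
#' @export
aggregate_suppression <- function(ratios, log_base = 10,
                                  participant = "P01") {
  conds <- unique(ratios$condition)
  regions <- unique(ratios$region)
  rows <- list()
  for (rg in regions) for (cd in conds) {
    sel <- ratios$region == rg & ratios$condition == cd & ratios$kept
    if (!any(sel))
      stop("no kept trials for condition '", cd, "' in region '", rg, "'")
    rows[[length(rows) + 1]] <- data.frame(
      participant = participant, condition = cd, region = rg,
      log_ratio = log(mean(ratios$ratio[sel]), base = log_base),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  class(tab) <- c("suppression_table", "data.frame")
  tab
}

#' One participant's suppression scores from a cleaned recording
#'
#' Convenience chain: [extract_epochs()] -> [trial_ratios()] ->
#' [mad_reject()] -> [aggregate_suppression()].
#'
#' @param rec preprocessed `eeg_recording`.
#' @param design the session's `eeg_design`.
#' @param clusters cluster list, see [cluster_config()].
#' @param windows an [epoch_windows()] list.
#' @param mad_k MAD rejection multiplier.
#' @param log_base log base of the scores.
#' @param participant participant label.
#' @param method PSD estimator.
#' @return list with `scores` (a `suppression_table`) and `trials` (the
#'   full `trial_ratio_table`).
#' @export
compute_suppression <- function(rec, design, clusters,
                                windows = epoch_windows(), mad_k = 3,
                                log_base = 10, participant = "P01",
                                method = "periodogram") {
  epochs <- extract_epochs(rec, design, windows)
  tr <- trial_ratios(epochs, clusters, method)
  tr <- mad_reject(tr, k = mad_k)
  list(scores = aggregate_suppression(tr, log_base, participant),
       trials = tr)
}

#' Boxplot of suppression scores by condition and region
#'
#' @param x a `suppression_table`.
#' @param ... passed to [graphics::boxplot()].
#' @return invisibly, `x`.
#' @export
plot.suppression_table <- function(x, ...) {
  graphics::boxplot(log_ratio ~ condition + region, data = x,
                    las = 2, ylab = "log power ratio (late/early)", ...)
  graphics::abline(h = 0, lty = 2, col = "grey40")
  invisible(x)
}
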