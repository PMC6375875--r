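# Synthetic continuous EEG with known injected suppression effects.

# Gaussian noise with a prescribed one-sided PSD, built in the frequency
# domain: coefficient variance P(f) * fs * n / 2 gives a series whose
# periodogram fluctuates around P(f).
colored_noise <- function(n, fs, psd_fun) {
  freqs <- seq(0, fs / 2, by = fs / n)
  kmax <- floor((n - 1) / 2)
  co <- complex(length.out = n)
  sd_k <- sqrt(psd_fun(freqs[2:(kmax + 1)]) * fs * n / 2)
  z <- complex(real = stats::rnorm(kmax), imaginary = stats::rnorm(kmax)) /
    sqrt(2)
  co[2:(kmax + 1)] <- z * sd_k
  co[n:(n - kmax + 1)] <- Conj(co[2:(kmax + 1)])
  Re(stats::fft(co, inverse = TRUE)) / n
}

# Constant-modulus narrowband oscillation: amplitude A, instantaneous
# frequency wandering slowly (< 0.2 Hz modulation) well inside
# [band[1], band[2]]. Band power of any window longer than a few cycles is
# A^2/2 almost exactly; keeping the wander slow and away from the band
# edges makes the in-band capture fraction of the early and late epochs of
# one trial nearly identical, so it cancels from their power ratio.
narrowband_osc <- function(n, fs, band, power) {
  fc <- mean(band)
  half <- (band[2] - band[1]) / 2
  dev_sd <- 0.3 * half
  dev <- colored_noise(n, fs, function(f) ifelse(f <= 0.2, 1, 0))
  s <- stats::sd(dev)
  # series shorter than one modulation period: constant frequency
  dev <- if (s > 0) pmin(pmax(dev / s * dev_sd, -0.6 * half), 0.6 * half)
         else numeric(n)
  phase <- 2 * pi * cumsum(fc + dev) / fs + stats::runif(1, 0, 2 * pi)
  sqrt(2 * power) * cos(phase)
}

# Band-passed Gaussian oscillation: flat PSD inside the band, total
# variance = power.
stochastic_osc <- function(n, fs, band, power) {
  dens <- power / (band[2] - band[1])
  colored_noise(n, fs, function(f)
    ifelse(f >= band[1] & f <= band[2], dens, 0))
}

# Amplitude envelope of one region: 1 at baseline, sqrt(r) during each
# trial's dynamic phase, cosine ramps of ramp_ms at both transitions.
region_envelope <- function(n, fs, design, timing, r_by_cond, ramp_ms) {
  env <- rep(1, n)
  ramp_n <- max(1L, round(ramp_ms * fs / 1000))
  half_cos_down <- 0.5 + 0.5 * cos(pi * seq_len(ramp_n) / ramp_n)
  scale <- fs / timing$srate
  d_on <- round(timing$dynamic_onset_ms * fs / 1000)
  d_off <- round(timing$dynamic_offset_ms * fs / 1000)
  for (i in seq_len(nrow(design))) {
    a <- sqrt(r_by_cond[[design$condition[i]]])
    on <- round(design$onset_sample[i] * scale)
    i0 <- on + d_on + 1L            # first dynamic sample (1-based)
    i1 <- min(on + d_off, n)        # last dynamic sample
    if (i0 > n) next
    idx <- i0:i1
    env[idx] <- a
    dn <- idx[seq_len(min(ramp_n, length(idx)))]
    env[dn] <- a + (1 - a) * half_cos_down[seq_along(dn)]
    up0 <- i1 + 1L
    up <- up0:min(up0 + ramp_n - 1L, n)
    if (up0 <= n)
      env[up] <- 1 + (a - 1) * half_cos_down[seq_along(up)]
  }
  env
}

#' Simulate a continuous EEG recording for a trial design
#'
#' Generates multichannel EEG in which the 8-13 Hz oscillation at the
#' montage's central and occipital clusters retains, during each trial's
#' dynamic phase, the configured fraction `r` of its static-phase band power
#' (condition- and region-specific), on top of 1/f background noise and
#' mains line noise. Optionally plants impulsive high-kurtosis bad channels
#' (chosen outside the scoring clusters so injected effects remain
#' interpretable) and stereotyped frontal blink transients.
#'
#' @param design an `eeg_design` from [make_design()].
#' @param config a [simulation_config()].
#' @param montage an `eeg_montage`; must have `config$n_channels` sensors.
#' @return An `eeg_recording` (volts, common reference), with attributes
#'   `"bad_channels"` (names of planted bad channels) and `"montage"`.
#' @export
simulate_recording <- function(design, config,
                               montage = make_montage(config$n_channels)) {
  if (length(montage$names) != config$n_channels)
    stop("montage size does not match config$n_channels")
  for (rg in names(config$erd)) {
    miss <- setdiff(unique(design$condition), names(config$erd[[rg]]))
    if (length(miss) > 0)
      stop("no retention value for condition(s) ",
           paste(miss, collapse = ", "), " in region ", rg)
  }
  timing <- attr(design, "timing")
  fs <- config$sampling_rate
  scale <- fs / timing$srate
  n <- ceiling((max(design$onset_sample) * scale) +
                 (timing$video_ms + timing$padding_ms) * fs / 1000)
  set.seed(config$seed)
  nch <- config$n_channels
  band <- config$band
  bw <- band[2] - band[1]

  osc_gen <- switch(config$osc_model,
                    narrowband = narrowband_osc,
                    stochastic = stochastic_osc)
  regions <- names(config$erd)
  reg_sig <- lapply(regions, function(rg) {
    u <- osc_gen(n, fs, band, config$osc_power_uv2)
    e <- region_envelope(n, fs, design, timing, config$erd[[rg]],
                         config$erd_ramp_ms)
    u * e
  })
  names(reg_sig) <- regions

  # 1/f background, scaled so its mean in-band PSD is osc in-band PSD / snr
  beta <- config$background_exponent
  f_floor <- 0.5
  mean_pow <- if (abs(beta - 1) < 1e-12) {
    log(band[2] / band[1]) / bw
  } else {
    (band[2]^(1 - beta) - band[1]^(1 - beta)) / ((1 - beta) * bw)
  }
  noise_scale <- (config$osc_power_uv2 / bw) / (config$snr * mean_pow)
  noise_psd <- function(f) noise_scale * pmax(f, f_floor)^(-beta)

  data <- matrix(0, nrow = nch, ncol = n)
  for (ch in seq_len(nch))
    data[ch, ] <- colored_noise(n, fs, noise_psd)
  # dipolar-like topography: +1 on the cluster, a negative return-current
  # annulus on the nearest outside channels so the montage mean is zero
  # (as for a real volume-conducted source under a full sensor cap)
  cluster_all <- match(unlist(montage$groups[regions]), montage$names)
  for (rg in regions) {
    idx <- match(montage$groups[[rg]], montage$names)
    idx <- idx[!is.na(idx)]
    outside <- setdiff(seq_len(nch), cluster_all)
    if (length(outside) > 0) {
      dmin <- vapply(outside, function(ch) {
        min(sqrt(colSums((t(montage$positions[idx, , drop = FALSE]) -
                            montage$positions[ch, ])^2)))
      }, numeric(1))
      ring <- outside[order(dmin)][seq_len(min(round(1.5 * length(idx)),
                                               length(outside)))]
    } else ring <- integer(0)
    gains <- numeric(nch)
    gains[idx] <- 1
    if (length(ring) > 0) gains[ring] <- -length(idx) / length(ring)
    for (ch in which(gains != 0))
      data[ch, ] <- data[ch, ] + gains[ch] * reg_sig[[rg]]
  }

  if (config$line_amp_uv > 0 && config$line_freq < fs / 2) {
    tt <- (seq_len(n) - 1) / fs
    line <- config$line_amp_uv *
      sin(2 * pi * config$line_freq * tt + stats::runif(1, 0, 2 * pi))
    data <- sweep(data, 2, line, "+")
  }

  bad <- character(0)
  if (config$n_bad_channels > 0) {
    cluster_idx <- match(unlist(montage$groups[c("central", "occipital")]),
                         montage$names)
    eligible <- setdiff(seq_len(nch), cluster_idx)
    bad_idx <- sample(eligible, config$n_bad_channels)
    bad <- montage$names[bad_idx]
    sd_bg <- stats::sd(data[bad_idx[1], ])
    for (ch in bad_idx) {
      n_imp <- max(20L, stats::rpois(1, n / fs * 5))
      at <- sample.int(n, n_imp)
      data[ch, at] <- data[ch, at] +
        sample(c(-1, 1), n_imp, replace = TRUE) * 20 * sd_bg
    }
  }

  if (config$blink_rate > 0) {
    n_blink <- stats::rpois(1, config$blink_rate * n / fs / 60)
    if (n_blink > 0) {
      blen <- round(0.3 * fs)
      bump <- 150 * (0.5 - 0.5 * cos(2 * pi * seq_len(blen) / blen))
      front <- colMeans(montage$positions[montage$groups$frontal, ,
                                          drop = FALSE])
      front <- front / sqrt(sum(front^2))
      cosang <- (montage$positions %*% front) / montage$radius
      w <- exp(-(acos(pmin(1, pmax(-1, cosang))) / 0.6)^2)
      for (b in seq_len(n_blink)) {
        at <- sample.int(n - blen, 1)
        seg <- at:(at + blen - 1)
        data[, seg] <- data[, seg] + w %*% t(bump)
      }
    }
  }

  rec <- new_recording(data * 1e-6, fs, montage$names, montage$positions,
                       reference = "common")
  attr(rec, "bad_channels") <- bad
  attr(rec, "montage") <- montage
  rec
}

#' Project source time-courses to the sensors through a lead field
#'
#' Pure forward model: sensor data = lead field x dipole moments, plus
#' optional white sensor noise. With zero noise the output is exactly the
#' linear projection, so single-source data are proportional to that
#' source's lead-field columns and multi-source data superpose.
#'
#' @param source_tc source time-courses: either voxels x samples (fixed
#'   orientation, see `orientations`) or (3 * voxels) x samples free-moment
#'   matrix in lead-field column order.
#' @param leadfield a `leadfield` from [build_leadfield()].
#' @param sensor_noise_sd white sensor noise SD (volts); 0 for noiseless.
#' @param srate sampling rate attached to the output recording.
#' @param orientations voxels x 3 dipole orientations used when
#'   `source_tc` has one row per voxel; default radial (outward).
#' @param seed seed for the sensor noise.
#' @return An `eeg_recording` (average reference, inherited from the
#'   average-referenced lead field).
#' @export
simulate_from_sources <- function(source_tc, leadfield, sensor_noise_sd = 0,
                                  srate = 250, orientations = NULL,
                                  seed = 1) {
  if (is.vector(source_tc)) source_tc <- matrix(source_tc, ncol = 1)
  nv <- nrow(leadfield$grid)
  if (nrow(source_tc) == nv) {
    if (is.null(orientations)) {
      orientations <- leadfield$grid /
        sqrt(rowSums(leadfield$grid^2))
    }
    moments <- matrix(0, 3 * nv, ncol(source_tc))
    for (j in 1:3)
      moments[3 * (seq_len(nv) - 1) + j, ] <- orientations[, j] * source_tc
  } else if (nrow(source_tc) == 3 * nv) {
    moments <- source_tc
  } else {
    stop("source_tc rows must equal the lead field's voxel count ",
         "(or 3x it for free moments)")
  }
  data <- leadfield$gain %*% moments
  if (sensor_noise_sd > 0) {
    set.seed(seed)
    data <- data + matrix(stats::rnorm(length(data), sd = sensor_noise_sd),
                          nrow = nrow(data))
  }
  new_recording(data, srate, leadfield$ch_names, leadfield$ch_positions,
                reference = "average")
}
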