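#' Default injected suppression effects
#'
#' Fractional band-power retention r (late/early; r < 1 = suppression) per
#' condition and region. Defaults emulate the qualitative pattern the
#' pipeline is designed to detect: strongest central suppression for the
#' neutral face, strongest occipital suppression for the non-biological
#' stimulus.
#'
#' @return list with numeric vectors `$central` and `$occipital`, named by
#'   condition.
#' @export
default_erd <- function() {
  list(
    central   = c(happy = 0.90, sad = 0.95, neutral = 0.60, nonbio = 0.90),
    occipital = c(happy = 0.95, sad = 0.95, neutral = 0.95, nonbio = 0.85)
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic-EEG generator. `snr` is the in-band
#' signal-to-noise ratio: the ratio of the oscillation's mean 8-13 Hz PSD to
#' the 1/f background's mean PSD in the same band (the broadband SNR is much
#' lower since 1/f noise concentrates at low frequencies).
#'
#' @param n_channels number of sensors.
#' @param sampling_rate Hz; must be at least twice `band[2]`.
#' @param band oscillation band (Hz), default `c(8, 13)`.
#' @param erd condition -> region fractional power retention map, see
#'   [default_erd()]. All entries must be > 0; r < 1 injects suppression
#'   during the dynamic phase, r > 1 facilitation.
#' @param background_exponent 1/f spectral slope of the background noise.
#' @param line_freq mains frequency (Hz).
#' @param line_amp_uv mains sinusoid amplitude (microvolts); 0 disables.
#' @param snr in-band oscillation/background PSD ratio.
#' @param osc_power_uv2 oscillation band power (microvolts squared) during
#'   the baseline (static) phase.
#' @param erd_ramp_ms cosine ramp length of the power step at dynamic-phase
#'   onset/offset.
#' @param osc_model `"narrowband"` (default): constant-modulus oscillation
#'   with random frequency modulation inside the band, so each epoch's band
#'   power tracks the envelope closely; `"stochastic"`: band-passed Gaussian
#'   noise, whose per-epoch power estimate fluctuates with ~2*B*T degrees of
#'   freedom and therefore biases mean late/early power ratios upward.
#' @param n_bad_channels number of planted bad channels (impulsive,
#'   high-kurtosis; assigned outside the scoring clusters).
#' @param blink_rate blink events per minute (0 disables).
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(n_channels = 128, sampling_rate = 1000,
                              band = c(8, 13), erd = default_erd(),
                              background_exponent = 1, line_freq = 50,
                              line_amp_uv = 5, snr = 20, osc_power_uv2 = 10,
                              erd_ramp_ms = 100,
                              osc_model = c("narrowband", "stochastic"),
                              n_bad_channels = 0, blink_rate = 0, seed = 1) {
  osc_model <- match.arg(osc_model)
  erd <- lapply(erd, unlist)   # accept per-region lists (e.g. from YAML)
  r <- unlist(erd)
  if (any(r <= 0)) stop("all retention values r must be > 0")
  if (sampling_rate < 2 * band[2])
    stop("sampling_rate must be at least twice the band upper edge")
  structure(list(
    n_channels = n_channels, sampling_rate = sampling_rate, band = band,
    erd = erd, background_exponent = background_exponent,
    line_freq = line_freq, line_amp_uv = line_amp_uv, snr = snr,
    osc_power_uv2 = osc_power_uv2, erd_ramp_ms = erd_ramp_ms,
    osc_model = osc_model, n_bad_channels = n_bad_channels,
    blink_rate = blink_rate, seed = seed
  ), class = "sim_config")
}

#' Ground-truth suppression scores of a simulation configuration
#'
#' The log-ratio the analysis pipeline should recover for each condition and
#' region: `log(r)` of the configured fractional power retention, in the
#' chosen log base. Zero means no change, negative values suppression,
#' positive facilitation.
#'
#' @param config a [simulation_config()].
#' @param log_base 10 (default) or `exp(1)`.
#' @return data.frame with columns `condition`, `region`, `log_ratio`.
#' @export
ground_truth <- function(config, log_base = 10) {
  regions <- names(config$erd)
  out <- do.call(rbind, lapply(regions, function(rg) {
    r <- config$erd[[rg]]
    data.frame(condition = names(r), region = rg,
               log_ratio = log(unname(r), base = log_base),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
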