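# Shared fixtures: everything is generated in code at test time.

# a small montage whose clusters are still well-formed
small_montage <- function(n = 16) make_montage(n)

# balanced 4 x 2 score table; `shift` is a named list
# condition -> c(central, occipital) added to the scores
random_scores <- function(n = 22, sd = 0.05, shift = NULL, seed = 1) {
  set.seed(seed)
  g <- expand.grid(participant = sprintf("P%02d", seq_len(n)),
                   condition = c("happy", "sad", "neutral", "nonbio"),
                   region = c("central", "occipital"),
                   stringsAsFactors = FALSE)
  g$log_ratio <- stats::rnorm(nrow(g), sd = sd) +
    rep(stats::rnorm(n, sd = sd), 8)
  if (!is.null(shift)) {
    for (cd in names(shift)) {
      g$log_ratio[g$condition == cd & g$region == "central"] <-
        g$log_ratio[g$condition == cd & g$region == "central"] + shift[[cd]][1]
      g$log_ratio[g$condition == cd & g$region == "occipital"] <-
        g$log_ratio[g$condition == cd & g$region == "occipital"] + shift[[cd]][2]
    }
  }
  class(g) <- c("suppression_table", "data.frame")
  g
}

# hand-built epoch set (trial x channel x sample arrays)
manual_epoch_set <- function(early, late, conditions, srate = 250,
                             ch_names = NULL) {
  nt <- dim(early)[1]
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(dim(early)[2]))
  design <- data.frame(block = 1L, trial = seq_len(nt),
                       condition = conditions,
                       onset_sample = seq_len(nt) * 10000L)
  structure(list(early = early, late = late, design = design,
                 srate = srate, ch_names = ch_names,
                 windows = epoch_windows()),
            class = "epoch_set")
}

# plain rectangular-window periodogram, used as an independent estimator
# (band_psd uses a Hann taper and zero padding; this deliberately does not)
rect_periodogram <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  kmax <- floor(n / 2)
  list(freq = (1:kmax) * fs / n,
       psd = (2 / (fs * n)) * Mod(X[2:(kmax + 1)])^2)
}

band_integral <- function(x, fs, band) {
  pg <- rect_periodogram(x, fs)
  sel <- pg$freq >= band[1] & pg$freq <= band[2]
  sum(pg$psd[sel]) * fs / length(x)
}

# brute-force scaled-MAD outlier mask (sort/median reimplementation)
brute_mad_mask <- function(v, k = 3) {
  s <- sort(v)
  m <- length(s)
  med <- if (m %% 2 == 1) s[(m + 1) / 2] else (s[m / 2] + s[m / 2 + 1]) / 2
  dev <- sort(abs(v - med))
  mad_raw <- if (m %% 2 == 1) dev[(m + 1) / 2] else
    (dev[m / 2] + dev[m / 2 + 1]) / 2
  smad <- 1.4826 * mad_raw
  if (smad == 0) return(rep(FALSE, length(v)))
  abs(v - med) > k * smad
}

# textbook BH closed form: min over j >= i of m * p_(j) / j
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}
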