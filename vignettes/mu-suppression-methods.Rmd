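---
title: "Quantifying mu/alpha suppression: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mu/alpha suppression: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musupp)
```

## The scientific problem

When people execute a movement — or merely watch one — the 8–13 Hz *mu
rhythm* over sensorimotor cortex loses power. This event-related
desynchronization (ERD) is widely used as a scalp-level proxy for mirror
neuron network engagement during action observation, including the
observation of facial expressions. The same frequency band over visual
cortex (*occipital alpha*) desynchronizes with visual attention, so any
credible mu analysis must quantify both regions and show that central and
occipital modulation dissociate.

`musupp` implements the complete analysis chain for this kind of study:

1. **Suppression index.** For every trial, the band power spectral density
   (PSD) of a *late* window (dynamic phase of the stimulus) is divided by
   the PSD of an *early* window (static phase of the same trial). Using a
   within-trial baseline avoids the attention-driven bias that a separate
   baseline stimulus would introduce, and using a ratio rather than a
   difference cancels per-participant scale factors (scalp thickness,
   electrode impedance). Per participant, trial ratios are averaged within
   a central electrode cluster (around C3 and C4) and an occipital cluster
   (O1, Oz, O2), then log10-transformed: a score below 0 is suppression,
   0 is no change, above 0 facilitation. Four conditions times two regions
   yields eight scores per participant.
2. **Group inference.** One-sample t-tests of each score against zero, a
   4 × 2 (condition × region) repeated-measures ANOVA with Mauchly's
   sphericity test, Greenhouse–Geisser correction when sphericity fails,
   partial eta squared effect sizes, and Benjamini–Hochberg FDR-corrected
   pairwise contrasts within each region.
3. **Distributed-source contrast.** A spherical-head lead field, a
   standardized minimum-norm inverse (the sLORETA variance normalization),
   per-condition band-power images, a paired t map with image-wide
   variance smoothing, and family-wise error control by max-statistic
   sign-flip permutation (statistical nonparametric mapping, SnPM).

Because raw data of this kind are rarely shareable, the package is built
around a synthetic-EEG generator whose injected effects are known exactly,
so every stage can be validated against ground truth.

## The synthetic-EEG generator

`simulate_recording()` composes, per channel:

* a **band-limited oscillation** per region (central, occipital) whose
  amplitude envelope steps from 1 to `sqrt(r)` during each trial's dynamic
  phase (2,000–4,000 ms after video onset) with 100 ms cosine ramps, where
  `r` is the configured fractional power retention for that trial's
  condition — the ground truth the pipeline must recover as `log10(r)`;
* **1/f background noise** (exponent configurable, default 1), scaled so
  the in-band SNR — oscillation band PSD over noise band PSD inside
  8–13 Hz — equals `snr` (default 20, about 2.5 dB against the full-band
  noise power: a moderate regime);
* **50 Hz mains noise** (default 5 µV) and, optionally, impulsive
  high-kurtosis bad channels and stereotyped frontal blink transients.

### Why the oscillation is constant-modulus

The default oscillation is a constant-amplitude process whose
instantaneous frequency wanders slowly (modulation below 0.2 Hz, confined
to the inner 60% of the band). Two estimator facts force this choice:

* A fully stochastic band-passed Gaussian oscillation gives the early
  window's PSD estimate only about 2·B·T ≈ 11 degrees of freedom. The mean
  of per-trial ratios then inflates by E[1/x]·E[x] ≈ ν/(ν−2) ≈ 1.25 — a
  +0.09 bias in log10, which would swamp the ±0.05 recovery target that
  makes the generator useful as a verification instrument. The stochastic
  model remains available (`osc_model = "stochastic"`) for studying
  exactly this estimator behavior.
* If the frequency wander is fast or reaches the band edges, the fraction
  of the oscillation's power captured inside 8–13 Hz fluctuates between
  the early and late window of the same trial, re-introducing ratio
  variance (and hence Jensen bias). Slow wander makes the capture fraction
  cancel in the ratio.

Real mu/alpha has waxing-and-waning amplitude that this default does not
emulate; what passing recovery tests show is that the *pipeline arithmetic*
is unbiased, not that real-data estimates have this precision.

### Topographies and the average reference

Injected region signals use a zero-sum topography: gain +1 on the cluster
channels and a compensating negative annulus on the nearest outside
channels, mimicking volume-conduction return currents. A real,
average-referenced EEG topography integrates to approximately zero over a
full sensor cap; a naive monopolar blob would instead let the common
average reference subtract a fraction 12/n of the signal from every
channel and distort the measured ratios at small montages.

## Preprocessing

The stage order is fixed: resample → high-pass → line-noise removal →
bad-channel detection/interpolation → (optional blink regression) →
common average reference. All filters are **zero-phase frequency-domain
filters with Butterworth squared-magnitude responses** (high-pass order 2,
applied forward-backward in effect, so 4th-order magnitude): each channel
is linearly detrended, transformed, multiplied by the real response, and
inverse-transformed. This is numerically equivalent in magnitude to a
forward-backward IIR pass, exactly zero-phase, and fast enough to run
whole sessions in seconds; the high-pass and all notches share a single
pass inside `preprocess()`. Contracts: DC attenuated by more than 40 dB,
the 8–13 Hz band is altered by less than 1%, notches of 2 Hz total width
remove ≥ 99% of mains power while moving neighbors outside ±2 Hz by less
than 5%.

Bad channels are flagged when the robust z-score of their excess kurtosis
(median/1.4826·MAD across channels) exceeds 5; a constant channel has
infinite kurtosis and is always flagged. Flagged channels are replaced by
inverse-distance-weighted averages of their 4 nearest good neighbors —
never dropped, so channel count and names are stable through the chain. A
recording with more than 20% flagged channels is marked rejected
(`attr(rec, "rejected")`), the automated counterpart of excluding
unusably noisy participants. Visual ICA-based artifact rejection is
deliberately not implemented: it is manual and irreproducible; an
optional blink regressor (projecting out a low-pass frontal estimate) is
provided instead, off by default.

## The suppression index, in detail

* **Windows.** Early 800–1,900 ms and late 1,950–4,000 ms from *video*
  onset, half-open `[start, end)`, sample edges by `floor(ms · rate /
  1000)`: at 250 Hz, 275 and 513 samples. Time zero is video onset — the
  reading under which the early window falls entirely inside the static
  phase.
* **PSD.** A Hann-tapered periodogram per epoch (Welch with 1 s segments
  as an option), one-sided, density-scaled, averaged over bins with
  8 ≤ f ≤ 13 Hz. Both windows are zero-padded to a common FFT length
  (next power of two ≥ max(n, 4·rate)). This matters: on their native
  grids a 275-sample and a 513-sample epoch cover the band with different
  effective bin widths (6 × 0.909 Hz vs 10 × 0.487 Hz), which biases the
  late/early ratio of a band-concentrated signal by roughly 10%; a common
  grid removes the artifact.
* **Ratio before averaging.** The ratio is formed per trial and channel,
  *then* averaged — never the ratio of averaged PSDs. A dedicated test
  keeps the order of operations honest.
* **Trial rejection.** Within each cluster, a trial's value is its
  cluster-mean ratio; values more than 3 scaled MADs (constant 1.4826)
  from the median are discarded for that cluster only. The rule is applied
  **within each condition** by default: pooling conditions would center
  the median on the bulk of weakly-modulated conditions and systematically
  reject genuine low-ratio trials of a strongly suppressed condition
  (about +0.007 log10 bias at r = 0.6 in our verification runs). The
  pooled variant (`granularity = "cluster_trials"`) and a per-channel
  variant remain available.
* **Log base.** Base 10, fixed; the base only rescales scores and does not
  affect inference.

## Group statistics

The ANOVA is computed from its sums-of-squares decomposition (subjects,
condition, region, interaction, and the effect-by-subject error strata);
`aov()` with `Error()` strata serves as an independent oracle in the test
suite, to 6 decimals on 100 random tables. Mauchly's test uses the
chi-square approximation (with Box's second-order series term) on the
covariance of orthonormal contrasts; the Greenhouse–Geisser epsilon is
applied only when Mauchly's p < 0.05. Partial eta squared is
SS_effect / (SS_effect + SS_error). All t-tests are two-sided (the
reference analysis does not state sidedness; two-sided is the
conservative reading). The FDR family is the 6 pairwise condition
contrasts within one region, corrected per region. An all-zero cell in
the baseline tests returns t = 0, p = 1 (the 0/0 convention); a
zero-variance cell with nonzero mean is an error.

## The source model

The lead field is a homogeneous conducting sphere (radius 90 mm, sigma
0.33 S/m) evaluated by the Legendre series for radial and tangential
dipole gains, truncated at 60 terms; sources live on a regular grid
(default 12 mm) confined to a shell between 28% and 80% of the head
radius in the upper hemisphere, a desk-scale stand-in for a cortical
template. The inverse is the minimum-norm operator
`M = Lᵀ(LLᵀ + λH)⁺` (`H` the average-reference operator, `λ` a fixed
fraction — default 0.01 — of the mean eigenvalue of `LLᵀ`), standardized
per voxel by its 3 × 3 resolution-matrix block. This standardization is
what gives exact localization of noiseless point sources, which the tests
verify over every grid node with random free orientations.

Condition images are per-voxel standardized band power of the late
epochs, averaged over kept trials, divided by the image mean and
log10-transformed; the normalization makes images invariant to global
sensor scaling. One consequence worth knowing: a source so strong that it
dominates the image mean is normalized away — contrasts are informative
about *relative, focal* modulation over a distributed background, which
is the physiological regime.

The paired contrast smooths each voxel's difference variance with the
image-wide mean, `v' = (v + v̄)/2`, before forming t. The permutation null
sign-flips participant difference images, recomputing the smoothed t map
each time, and records the image-wide extreme statistic. Sign patterns are
drawn *without replacement*, excluding the identity (the `+1` of the
Monte-Carlo p formula `(1 + #{null ≥ stat}) / (1 + N)` stands in for it):
at n = 8 participants the pattern space has only 255 non-trivial
elements, and with-replacement draws would make the test noticeably
conservative (measured family-wise error ≈ 0.033 instead of ≈ 0.044 at a
nominal 0.05). When `n_perm ≥ 2^n − 1` the full pattern space is
enumerated. The default contrast is one-tailed (first condition less
than the second).

## Problem sizes and calibration choices

The heavyweight verification runs use sizes chosen once, as a balance of
statistical resolution against desk-scale runtimes:

* Ground-truth recovery: 22 participants × 40 trials/condition (the
  design of interest), simulated at 64 channels and 250 Hz. Channel count
  and rate are not part of the recovery claim; the a-priori error budget
  (window composition ≈ +0.014 log10 at r = 0.6, taper-length asymmetry
  ≈ +0.007, in-band noise mixing ≈ +0.02 at SNR 20) predicts a worst-cell
  bias around +0.04, within the ±0.05 target; measured: ≈ 0.028.
* Null calibrations: 2,000 simulated null tables for the ANOVA
  interaction; 800 replicates of the SnPM contrast at 100 voxels,
  200 permutations, n = 8.
* Localization: every node of the default 12 mm grid (~440 voxels) with a
  random free orientation.

## Known limitations

* The generator's oscillation has a stable envelope and its 1/f noise is
  stationary and channel-independent; real EEG has amplitude bursts,
  spatially correlated noise, and non-blink artifacts. Recovery results
  bound pipeline bias, not real-data variance.
* The spherical single-shell head model and regular grid do not attempt
  anatomical realism; no registration to a template brain and no
  anatomical labeling are provided.
* The inter-trial interval uses a fixed 2,000 ms stand-in for a
  self-paced response period.
* Cluster membership is configuration, not anatomy: defaults are the 6
  sensors nearest C3 plus 6 nearest C4, and O1/Oz/O2.
* EDF import/export is not implemented; the delimited-matrix + JSON
  sidecar dialect is the canonical, bit-exact format.

## Reproducibility

Every stochastic component accepts a seed; `run_pipeline()` expands one
global seed into per-participant and per-stage seeds via the documented
derivation `(seed · 7919 + index) mod (2³¹ − 1)`, so identical
configurations reproduce artifacts bit for bit, and each stage can be
re-run independently.
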