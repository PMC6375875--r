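# musupp

Analysis of **mu/alpha rhythm suppression** in multichannel EEG, the
scalp-level index of sensorimotor engagement used in action-observation
and face-perception studies — together with a synthetic-EEG generator that
makes every stage of the pipeline verifiable against known ground truth.

## Who this is for, and what it computes

EEG researchers quantifying event-related desynchronization (ERD) of the
8–13 Hz rhythm over central (mu) and occipital (alpha) cortex. For each
trial with a static-then-dynamic stimulus, the package computes the
within-trial suppression index

```
S = log10( PSD_late / PSD_early )
```

where `PSD_early` is the 8–13 Hz band power spectral density of the
static-phase window (800–1,900 ms from video onset) and `PSD_late` that
of the dynamic-phase window (1,950–4,000 ms), per electrode cluster
(12 central sensors around C3/C4; O1, Oz, O2 occipitally). Per-trial
ratios are cleaned by a 3-scaled-MAD outlier rule, averaged, and
log-transformed: `S < 0` is suppression, `S = 0` no change, `S > 0`
facilitation. Four conditions × two regions give eight scores per
participant.

On top of the scores the package provides:

* **Preprocessing**: resampling, 0.1 Hz zero-phase high-pass, 50 Hz
  line-noise notches, kurtosis-based bad-channel detection (robust z > 5)
  with neighbor interpolation, common average reference.
* **Group statistics** (implemented from formulas, with base-R fitters as
  test oracles): baseline t-tests against zero, the 4 × 2
  repeated-measures ANOVA with Mauchly sphericity check,
  Greenhouse–Geisser correction and partial eta squared, and
  Benjamini–Hochberg FDR-corrected pairwise contrasts per region.
* **Distributed-source contrast**: analytic spherical-head lead field,
  sLORETA-style standardized minimum-norm inverse (`M = Lᵀ(LLᵀ+λH)⁺`,
  per-voxel resolution-matrix standardization → exact localization of
  noiseless point sources), per-condition normalized log band-power
  images, a paired t map with image-wide variance smoothing
  `v' = (v + v̄)/2`, and max-statistic sign-flip permutation correction
  (SnPM).
* **Synthetic EEG** (`simulate_recording()`): 1/f background, mains
  noise, optional bad channels and blinks, and a band-limited oscillation
  whose dynamic-phase power retention `r` is configured per condition and
  region — so the pipeline's output can be compared with `log10(r)`
  exactly.

## Worked example

Simulate one participant's session (160 trials: happy, sad, neutral,
non-biological; 4 blocks), preprocess, and score:

```r
library(musupp)

mon <- make_montage(32)                       # spherical-cap montage
cfg <- simulation_config(n_channels = 32, sampling_rate = 250, seed = 11)
des <- make_design(seed = 11)                 # 4 blocks x 40 trials
rec <- simulate_recording(des, cfg, mon)
#> <eeg_recording> 32 channels x 360000 samples @ 250 Hz (1440.0 s), common reference

clean <- preprocess(rec, preprocess_config(target_rate = 250),
                    cluster_config(mon))
sup <- compute_suppression(clean, des, cluster_config(mon),
                           participant = "P01")
print(sup$scores, digits = 3)
#>   participant condition    region log_ratio
#> 1         P01    nonbio   central -0.027971
#> 2         P01   neutral   central -0.191146
#> 3         P01       sad   central -0.002559
#> 4         P01     happy   central -0.028519
#> 5         P01    nonbio occipital -0.055812
#> 6         P01   neutral occipital -0.013973
#> 7         P01       sad occipital  0.006806
#> 8         P01     happy occipital  0.000495
```

The generator injected, e.g., 60% power retention (`log10 0.6 = −0.222`)
for neutral/central and 85% (`−0.071`) for nonbio/occipital
(`ground_truth(cfg)`); the single-participant estimates above sit within
a few hundredths of those targets, and averaging over 22 simulated
participants recovers every cell within ±0.03. Group inference runs on a
stack of such tables:

```r
scores <- do.call(rbind, lapply(...))   # one table per participant
rm_anova_4x2(scores)                    # F, df, p, partial eta squared
pairwise_fdr(scores, "central")         # 6 contrasts, BH-corrected
```

`run_pipeline(run_config(...), out_dir)` executes the whole chain —
simulate → preprocess → score → statistics (→ source contrast) — and
writes CSV tables, `summary.json`, and a provenance log; identical seeds
give bit-identical artifacts. A thin command-line wrapper lives at
`inst/cli/musupp.R` (`simulate`, `preprocess`, `suppress`, `stats`,
`run`).

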