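# mindsig

Signal-processing tools for contrasting **mindfulness meditation** and
**control** recordings of multichannel scalp EEG plus respiration, and for
asking whether those signals carry an objective marker of the meditative
state. The package bundles four analyses that are usually scattered across
toolboxes into one tested pipeline, together with a seeded synthetic-session
generator so that every stage can be exercised and validated without access
to clinical recordings.

## What it computes

Given sessions of 32-channel EEG (microvolts, electrodes Fp1 ... Cz grouped
into six scalp regions) and one respiration-belt channel, each labeled
`meditation` or `control`:

1. **Band-by-region spectral power.** After a 2–35 Hz linear-phase FIR
   bandpass, +/-200/2 uV artifact masking, logistic-infomax ICA ocular
   cleanup and downsampling to 64 Hz, power spectral density is estimated by
   the Bartlett method — averaged periodograms of non-overlapping
   Blackman–Harris-tapered segments:

   `P(w) = (1/K) * sum_k (1/N) | sum_n x_k[n] w[n] e^(-jwn) |^2`

   Power is averaged into theta `[4,8)`, alpha `[8,12)`, beta `[12,30)` Hz by
   region, Box–Cox normalized when non-normal, and tested with a two-way
   within-subject ANOVA (Condition x Location).

2. **Respiration time–frequency contrast.** The Stockwell transform
   (`S(f,n] = sum_m x[m] (|f|/sqrt(2*pi)) e^(-(n-m)^2 f^2 / 2) e^(-i 2 pi f m)`,
   a Gaussian window one signal period wide) resolves the breathing rhythm in
   time and frequency; time-averaged coefficient amplitudes are Box–Cox
   normalized and compared across conditions with a one-factor within-subject
   ANOVA.

3. **Phase synchrony.** Instantaneous phases from the S-transform on a
   4–32 Hz grid give phase differences `theta = phi_i - phi_j` and the
   phase-lock value over 2-second sliding rectangular windows,
   `PLV = (1/L) |sum e^(j theta)|`. A null level is calibrated from 500 pairs
   of phase-randomized surrogates (identical power spectrum, scrambled
   phases); electrode pairs — cross-region only — whose PLV exceeds the
   pooled 90% surrogate quantile are counted per band and condition.

4. **State classification.** Per-time-sample feature vectors concatenate
   S-transform amplitudes across channels (EEG grid `[4,32]` Hz at 0.25 Hz,
   respiration `[0.0625,16]` Hz). A kernel canonical correlation (KCCA)
   dependency index `I(l)` between the sequence and its lag-`l` shift picks
   the downsampling factor (first local minimizer), features are min-max
   normalized, and an RBF-kernel SVM is trained per subject with 10-fold
   cross-validation over a `(sigma, cost)` grid — separately for EEG-only,
   respiration-only, and joint features.

## Worked example

A desk-scale run on a synthetic 4-subject cohort (12 channels, 60-second
sessions, coarsened analysis grids; see the methods vignette for how these
sizes were chosen):

```r
library(mindsig)
cfg <- pipeline_config(
  synthetic = synthetic_config(n_channels = 12, duration = 60, seed = 1),
  n_subjects = 4,
  use_ica = FALSE, phase_highpass = 1,
  resp_bandpass = c(0.05, 2), resp_transition = 0.4,
  n_surrogate_pairs = 60, phase_freqs = seq(4, 32, 2),
  eeg_feature_grid = c(4, 32, 2), resp_feature_grid = c(0.125, 2, 0.0625),
  feature_stride = 16, kcca_max_lag = 4, kcca_max_n = 200,
  svm_sigma_rel = c(0.5, 1, 2), svm_cost_grid = c(1, 10), svm_fold_gap = 20,
  seed = 1)
res <- run_pipeline(cfg)
res
#> <pipeline_result>
#>   simulate     ok
#>   preprocess   ok
#>   spectral     ok
#>   respiration  ok
#>   synchrony    ok
#>   classify     ok
#>   mean CV accuracy: eeg=0.846 resp=0.988 joint=1.000
```

The theta band shows the injected condition effect and its regional
modulation:

```r
res$spectral$anova$theta
#>             effect df1 df2         F            p
#> 1        condition   1   3 402.78171 2.703946e-04
#> 2           region   5  15 419.25301 1.484055e-15
#> 3 condition:region   5  15  13.62195 3.974746e-05
```

Synchrony counting finds the meditation-elevated alpha coupling: almost every
admissible cross-region pair exceeds the surrogate threshold during
meditation, none during control:

```r
res$synchrony$threshold
#> <surrogate_threshold> 0.464 at 90% confidence (60 pairs, 102600 pooled PLVs)
subset(res$synchrony$counts, band == "alpha")
#>    condition  band n_pairs n_admissible
#> 1    control alpha    0.00           60
#> 2 meditation alpha   59.75           60
```

The respiration contrast is strongly significant
(`F(1,3) = 253.9, p = 5.4e-4`), and the classifier ordering is
`joint (1.000) > respiration (0.988) > EEG (0.846)`: respiration rate is the
easier single cue on this cohort, and concatenating modalities loses nothing.

A thin command-line wrapper over the same functions lives in
`inst/cli/mindsig.R`
(`Rscript inst/cli/mindsig.R all --seed 1 --out run_dir`).

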