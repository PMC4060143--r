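---
title: "Spectral, synchrony and classification analysis of meditation EEG and respiration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral, synchrony and classification analysis of meditation EEG and respiration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mindsig)
```

mindsig asks a concrete question of paired physiological sessions: do EEG and
respiration carry an objective signature of the mindfulness-meditation state,
relative to a matched eyes-closed control condition? This vignette documents
the models behind each stage, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the numerical and
design choices that were genuinely open.

## The synthetic session generator

No public recordings exist for this kind of paired-session protocol, so the
generator is a first-class, tested component: it produces cohorts with the
statistical structure the analysis stages assume, and every downstream claim
in the test suite is made against it.

**EEG model.** Each channel is a superposition of independent narrowband
Gaussian processes, one per frequency band (theta 4–8, alpha 8–12, beta
12–30 Hz), built by Fourier-masking white noise — filtered noise rather than
sinusoid sums, so spectral estimates carry realistic estimator variance. Band
variances are a baseline per region (posterior alpha dominance, frontal
theta, modest beta; tens of µV² so that total channel amplitude is tens of
µV) multiplied by `band_power[[condition]][[band]][region]`. The default
multipliers encode the contrast pattern the pipeline targets: beta and theta
raised during meditation in all regions (theta essentially flat frontally,
multiplier 0.98), alpha raised mainly occipitally and right-temporally and
slightly lowered parietally (0.92). A 1/f background (`noise_floor`, default
0.3 of total band amplitude) fills the spectrum between bands.

**Cross-region coupling.** With coupling strength $\rho$, the coupling-band
(default alpha) component of every channel is mixed as
$\sqrt{1-\rho^2}\,\mathrm{own} + \rho\,\mathrm{shared}$, which leaves the
band variance untouched while raising cross-channel phase synchrony. Because
the phase-lock value of two such channels scales roughly as $\rho^2$ against
a null PLV of ~0.3 for fully independent narrowband channels, small
coupling coefficients are statistically invisible. The defaults — meditation
0.90, control 0.20 — were calibrated so that the coupled band's PLV
(~0.55–0.65) sits inside the range typically reported for resting
eyes-closed posterior alpha and above the 90% surrogate null, i.e. so the
generator actually produces the detectable synchrony elevation it exists to
emulate.

**Respiration model.** A quasi-sinusoid at the per-condition breathing rate
(defaults: meditation 0.13 Hz, control 0.25 Hz — the published analyses
report only that breathing is slower during meditation, so these are
placeholders on the right scale, not claims). Variability is dominated by
breath-to-breath fluctuation: amplitude jitter is low-passed at half the
breathing rate (SD 12%) and rate jitter at a third of it (SD 6%), with a
small slow drift (5% and 2%, below 0.03/0.02 Hz) on top. An earlier draft
used purely slow (~30 s correlation) jitter; that watermarks every session
with a quasi-constant level, which — with only one session per condition —
makes session identity, and hence the class label, learnable by any
classifier regardless of condition effects. Cycle-scale variability is both
the physiologically dominant component and free of that artifact.

**Artifacts.** `inject_artifacts()` adds the three artifact classes the
preprocessing stage must catch: 0.5-s raised-cosine blinks (default 120 µV at
the frontal pole, spatial weights decaying toward posterior channels — only
their removability matters), high-voltage segments that exceed the 200 µV
rejection bound on all channels, and channels flattened below the 2 µV bound.

**Determinism.** A session is a pure function of
`(config, subject_id, condition)`; the master seed fans out through a fixed
affine map (`derive_seed()`), so enabling or disabling one pipeline stage
never shifts another stage's random stream.

**What is not emulated:** volume conduction or any head-model realism, ECG or
EOG as separate channels, movement artifacts, non-stationary band power
within a session, and any dependence of respiration amplitude on breathing
rate. Passing tests therefore demonstrate that the algorithms recover the
structure this model injects — not that real recordings contain it.

## Preprocessing

**Filters.** All filters are linear-phase FIR, applied by FFT convolution
with exact group-delay compensation (zero-phase output), the filter-length
transient flagged for `discard_transient()`. Published tap counts for this
kind of pipeline are tied to an unstated native rate, so filters are designed
from band edges plus attenuation targets instead: a Kaiser window sized for
45 dB stopband attenuation (passband ripple far below 0.5 dB) over a
transition of `min(1 Hz, lowest edge)`. Kaiser designs hit these targets at
any length; the equiripple (Parks–McClellan) alternative in this R stack
fails to converge at the several-hundred-tap orders these transitions
require, and the window design's slightly higher order is immaterial here.
The 45 dB target (rather than 40) keeps DC more than 40 dB down even when the
low cut sits right at the stopband edge. A nominal near-zero low edge (the
respiration bandpass is specified as [0.01, 20] Hz) clamps the cutoff at
half the edge rather than inflating the order: at the published filter-length
scale such an edge is nominal — the achievable transition is ~0.25 Hz, which
is the `resp_transition` default.

**Artifact mask.** Samples with |amplitude| > 200 µV are rejected with a
0.25-s guard on both sides; a 1-s sliding window (stride ¼ window) whose peak
is below 2 µV marks flat stretches, and a channel flat for more than half the
session is dropped entirely. The mask travels with the recording; Bartlett
segments containing any rejected sample are excluded from the average — the
test suite checks this exclusion is exact, not approximate.

**Ocular ICA.** Logistic-infomax ICA (natural-gradient updates over shuffled
sample blocks, learning rate annealed harder whenever the weight change stops
shrinking, seeded initialization) is implemented in the package since no ICA
implementation ships with the supported stack. Components whose time course
correlates with an ocular reference above |r| = 0.7 are zeroed; with no EOG
channel available the reference is the frontal-channel mean low-passed below
5 Hz. The 0.7 threshold is an operational choice — the source analyses state
no criterion — validated by the requirement that a 15-blinks/minute session
loses ≥80% of its frontal low-frequency blink power while alpha power moves
by <10%, and that a blink-free session passes through bit-near-identically.

**Downsampling.** Integer-factor decimation to 64 Hz, guarded by an alias
check: content above the target Nyquist may carry at most `alias_tol` of
total power (default 1%). The published recipes place filter edges *at* the
target Nyquist (32 Hz lowpass, 2–35 Hz bandpass), knowingly folding the
transition band, so the pipeline paths use a 5% tolerance; a flatly
unfiltered 40 Hz component still errors.

## Spectral analysis

The Bartlett estimator divides each channel into consecutive non-overlapping
segments of `N` samples, tapers each with the four-term (−92 dB)
Blackman–Harris window, and averages `(1/N)|FFT|²` periodograms. `N` is not
stated in the source analyses; the default is 4 s at 64 Hz (`N = 256`),
giving 0.25 Hz resolution — matching the classifier's EEG grid — and ~225
segments in a 15-minute session. The FFT implementation is tested to equal
the direct summation at machine precision.

Band-by-region power is the mean over the region's channels of the mean PSD
over the band's frequencies (left-closed, right-open intervals). Per band,
the table is Shapiro–Wilk tested (α = 0.05) and Box–Cox transformed when
non-normal (exponent by profile maximum likelihood over λ ∈ [−2, 2]), then
tested by a two-way within-subject ANOVA with Condition and Location, each
effect against its own interaction with subjects. With `n` subjects the
condition effect has df (1, n−1) and the interaction (5, 5(n−1)) — both
consistent with subject-level cell means at the published cohort size. For
balanced replicates (e.g. frequencies inside a band) the replicate-level F is
algebraically identical to the cell-mean F, so the single implementation
serves both aggregation readings; the toy-table oracle tests are written
against hand-computed sums of squares.

## The Stockwell transform and the respiration contrast

The transform uses a Gaussian analysis window whose standard deviation is one
signal period (frequency in cycles/sample internally; the user-facing grid is
Hz, converted as `f/fs`), normalized by $|f|/\sqrt{2\pi}$. Each frequency row
is a linear convolution of the modulated signal with the sampled Gaussian,
computed on a zero-padded FFT grid (8 Gaussian widths of padding, so circular
wrap-around is below double precision); when the grid sits on DFT bins the
modulation is a spectrum rotation and the padded forward transform is
computed once. The FFT route is tested against the direct double summation
(≤1e−8), as are linearity, the time-marginal property, and the
frequency-dependent resolution.

The respiration contrast averages coefficient amplitudes over time and
frequency into one value per subject and condition, Box–Cox transforms those
cell values, and runs the one-factor within-subject ANOVA. Two readings of
the unstated aggregation give identical F ratios (see above), so the only
substantive choice is where the Box–Cox acts: applied to the raw per-bin
amplitudes, the profile likelihood is dominated by the quiet bins between
spectral peaks (λ driven to ≈ −0.8 across a ~4-decade amplitude range) and
the transform buries the condition effect in noise-floor variance; applied to
the cell values — the distribution that actually enters the ANOVA, and the
same placement the spectral module uses — it behaves as intended. The
per-condition mean amplitude spectra are returned alongside for the
slower-breathing comparison (meditation-greater below 0.2 Hz, control-greater
above, on the default rates).

## Phase synchrony and the surrogate threshold

Phases come from the S-transform on a 4–32 Hz grid (1 Hz steps); phase
differences are wrapped to (−π, π]; the PLV uses 2-s rectangular windows
sliding one sample at a time (cumulative-sum implementation, tested against
naive recomputation at 1e−12). Counting is restricted to cross-region
electrode pairs — same-region pairs are synchronous from proximity alone —
and a pair counts once per band when its median-over-windows PLV exceeds the
threshold; the per-window exceedance fraction is exported as well, since the
published reduction over time is unstated. The montage's region grouping
(9 frontal, 7 central, 7 parietal, 5 occipital, 2+2 temporal) is one
reasonable reading of a six-region layout; the pair set is fully
configurable, since no natural reading reproduces the published "76 pairs"
for 32 electrodes.

The significance threshold pools PLVs from `n_pairs` (default 500)
independent pairs of phase-randomized surrogates — exact conjugate-symmetric
phase scrambling, so each surrogate's periodogram equals the reference's to
machine precision — and takes the empirical 0.9 quantile. One pooled
threshold across frequencies is the default (a per-frequency option exists);
pooling uses non-overlapping windows, which sample the same distribution as
the fully sliding set at a fraction of the memory. The pipeline's reference
is the subjects' own control-condition EEG (channel Cz, concatenated, capped
at 15 minutes).

A property worth understanding before comparing this threshold to published
values: the surrogate PLV null is governed almost entirely by the product of
the PLV window length and the analysis bandwidth (the number of independent
phase samples per window), and hardly at all by the reference spectrum — we
measured pooled 90% quantiles of 0.43–0.53 across 1/f exponents from 1.0 to
2.5, narrow-alpha-peak references, and the generator's block-band EEG. With
2-s windows and the S-transform's bandwidth (∝ f/2π) on a 4–32 Hz grid, the
pooled 90% quantile is ≈0.45–0.52. Thresholds near 0.8 arise only when the
window–bandwidth product is about a quarter of that — for instance windows
parameterized at a 4× higher sampling rate than the 64 Hz phase series, a
slip that exactly matches a 256→64 Hz downsampling factor. The package keeps
the self-consistent parameterization: 2-s windows on the 64 Hz series, the
Gaussian width the transform's definition implies.

## Feature extraction and classification

Features are S-transform amplitudes (the SVM needs real inputs), one vector
per time sample, channel-major and frequency-ordered within each channel
block: EEG on `[4,32]` Hz at 0.25 Hz (32 × 113 = 3616 dimensions at full
scale), respiration on `[0.0625,16]` Hz.

**KCCA downsampling.** Writing the dependency criterion's denominator
`var[g(x)] + κ‖g‖²` in Gram-matrix form shows the ridge enters as `n·κ`
(the variance carries a 1/n); the index is the square root of the largest
eigenvalue of `(Kx + nκI)⁻¹Ky(Ky + nκI)⁻¹Kx` on centered Gaussian Grams,
with κ = 0.02, kernel widths from the median pairwise distance, and a
deterministic even subsample of at most 500 points per lag. The test suite
verifies this against an independent SVD formulation in the Gram eigenbasis.
The downsampling factor is the smallest `L > 0` with `I(L−1) > I(L)` and
`I(L) ≤ I(L+1) + tol`: the published strict local-minimum rule plus a tie
tolerance of one tenth of the curve's initial drop `I(0) − I(1)`, because a
finite-sample estimate of an exactly flat curve is crossed at a random lag —
without the tolerance, independent features would be assigned `L = 1` only
half the time. The joint classifier concatenates the two modalities'
full-rate features and re-selects `L` on the joint sequence.

**Normalization.** Min–max per feature. The published recipe normalizes each
group (train/test/validation) by its own extremes; that variant is kept
(`method = "per_group"`), but the default applies training-set bounds to the
held-out data (`"train_bounds"`), because a held-out block that is nearly
pure one class normalizes its own class level away under the per-group rule.

**Cross-validation.** Folds are contiguous temporal blocks *stratified by
class* — fold k holds block k of each session — so temporal-adjacency effects
act on both classes symmetrically, with an optional embargo (`fold_gap`)
excluding training samples within a gap of the held-out block, the standard
guard for autocorrelated features. Plain random folds are available to mimic
the published protocol, but on features sampled 64 times per second they
leak: each held-out sample sits milliseconds from its training neighbours.
With one session per condition, any session-level fingerprint in the features
is confounded with the class label, and no fold geometry fully separates
them; the generator's breath-to-breath jitter model plus stratified blocks
plus an embargo keeps a no-effect cohort at chance-level accuracy, which is
the property a trustworthy accuracy estimate must have. Hyperparameters
(RBF width relative to the median pairwise distance, cost) are selected by CV
accuracy on the grid; per-subject accuracies at the optimum are averaged
across subjects, and the final model's decision-function values are exported
as the candidate depth-of-meditation score.

## Problem sizes used by the tests

The test and acceptance runs scale the published 34-subject, 15-minute,
32-channel protocol to a single CPU: sessions of 40–120 s, 6–12 channels
(region-balanced montage subsets), phase grids at 2–4 Hz spacing, EEG feature
grid `[4,32]` at 2 Hz, respiration grid `[0.125,2]` at 0.0625 Hz, feature
vectors every 16–32 samples, 10-fold CV with a 3 × 2 hyperparameter grid, and
60–500 surrogate pairs. The surrogate-threshold computation in
`scripts/acceptance.R` keeps the full 15-minute reference, 500 pairs and the
1 Hz phase grid. Classifier cohorts use 20 subjects. The respiration feature
grid's lower edge matters at these durations: at 0.0625 Hz the analysis
window is 16 s wide, so on a one-minute session that feature row is a
session-global constant — a fingerprint no cross-validation can embargo —
hence the 0.125 Hz floor in the desk-scale classifier configurations.

## Known limitations

- EDF/BDF support is a minimal codec (16-bit EDF write/read, 24-bit BDF
  read, homogeneous per-signal rates, 1-s records) sufficient for
  round-tripping sessions, not a general biosignal I/O layer.
- The two-session design limits what any classifier accuracy can mean;
  within-subject accuracies here quantify separability of these two
  recordings, not generalization across days.
- The generator's band processes are stationary within a session; drowsiness
  drift, posture changes and electrode impedance drift are out of scope.
- Real scalp EEG shares sources across channels through volume conduction;
  here channels are independent except for the explicit coupling component,
  so absolute PLV levels are lower than on real montages.
- No gamma band anywhere: scalp gamma is dominated by muscle activity.
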