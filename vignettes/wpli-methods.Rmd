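---
title: "Phase-lag connectivity with wpliconn: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-lag connectivity with wpliconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wpliconn)
```

## The problem

Resting EEG electrodes record mixtures of cortical sources. Because tissue
conduction is effectively instantaneous at EEG frequencies, a single source
reaching two electrodes produces strong *zero-lag* correlation between them
that has nothing to do with inter-regional communication. Connectivity
measures built on the full cross-spectrum (coherence, phase-locking value)
inherit this artifact. The weighted phase lag index (WPLI) family avoids it
by using only the *imaginary* part of the cross-spectrum, which is exactly
zero for instantaneous mixing: only lagged, and therefore plausibly neural,
coupling contributes.

wpliconn implements a complete pipeline around these estimators: synthetic
cohort generation, preprocessing, per-pair spectral connectivity, surrogate
empirical nulls, and the group-level statistics used in case-control
resting-EEG studies (here oriented to a mild-traumatic-brain-injury style
design with a linked white-matter fractional-anisotropy table).

## Estimators

For one channel pair, epoch $j$ contributes a cross-spectrum
$S_j(f) = X_{1,j}(f)\,\overline{X_{2,j}(f)}$ from the discrete Fourier
transforms of its two 1-s segments (rectangular window, 1 Hz resolution).
With $I_j = \mathrm{Im}\,S_j$:

* **WPLI** $= |\sum_j I_j| \,/\, \sum_j |I_j|$ — sign consistency of the
  lead/lag relation, weighted by the magnitude of the imaginary
  cross-spectrum, so that epochs whose cross-spectrum lies near the real
  axis (sign easily flipped by noise) count less.
* **PLI** $= |\tfrac1N \sum_j \mathrm{sign}(I_j)|$ — the unweighted sign
  asymmetry.
* **Debiased WPLI-square**
  $= \sum_{j \ne k} I_j I_k \,/\, \sum_{j \ne k} |I_j I_k|$ — an
  asymptotically unbiased estimator of WPLI$^2$, computed in its algebraic
  $O(N)$ form. Unlike WPLI it is not positively biased at small $N$, at the
  price of being able to go negative in finite samples.

Numerical conventions: the $0/0$ case (all $I_j = 0$, e.g. two identical
channels) is defined as 0 for all three measures, since strictly zero-lag
coupling is what these estimators are built to ignore; negative debiased
values are *not* clipped to zero — clipping would re-introduce bias and the
surrogate normalization below expects a signed statistic. Band summaries
are arithmetic means over inclusive integer bins (theta 4–7, alpha 8–13,
beta 15–23, low-gamma 25–40 Hz); the "global" statistic is the across-pairs
mean of a band mean.

## Preprocessing

The pipeline order is fixed: ocular regression, band-limiting, resampling,
epoching, amplitude rejection. Each stage is deterministic.

* **Ocular regression.** Every scalp channel is replaced by its
  least-squares residual after regressing (with intercept) on all EOG
  channels over the full continuous recording. Resting data has no events,
  so no trial-averaged refinement is attempted. Zero-variance EOG channels
  are dropped with a warning.
* **Band-limiting** (defaults 0.5–50 Hz). Phase estimators demand zero-phase
  filtering, so both filters are applied forward–backward with
  odd-reflection padding to suppress end transients. The high-pass is a
  4th-order Butterworth. For the low-pass, a Butterworth of practical order
  cannot deliver strong attenuation only 20% above its cutoff, and the
  pipeline's contract is ≥ 40 dB by 1.2× the cutoff (60 Hz mains for the
  50 Hz default); a Chebyshev type-II design (order 7, 30 dB per pass,
  stopband edge at 1.2× cutoff) meets that with a maximally flat passband,
  which is what matters for amplitude-weighted phase measures. Measured on
  150-s tones: ≤ 1.2% passband error at 2–40 Hz, 60 Hz tone reduced below
  1% RMS, phase shift < 10⁻⁴ rad.
* **Resampling** (default to 256 Hz) uses a windowed-sinc FIR anti-alias
  filter applied by centred (zero-phase) convolution followed by
  decimation; gain error < 0.1% at 10 Hz. Only downsampling is permitted.
* **Epoching** cuts consecutive non-overlapping 1-s windows from the first
  sample; a trailing partial window is dropped (150 s at 256 Hz → 150
  pseudotrials of 256 samples). No detrending or tapering: with 1-s epochs
  the rectangular-window DFT gives exactly 1 Hz bins, and the surrogate
  null shares whatever leakage the observed statistic has.
* **Rejection.** A trial is rejected iff any scalp-EEG sample exceeds the
  threshold (default 75 µV) in absolute value. "Activity exceeding" a
  threshold is read as instantaneous absolute amplitude rather than
  peak-to-peak — the simplest reading; the threshold is a config knob, and
  EOG channels deliberately do not count (they carry the regressor, not
  the signal under test). At least 2 retained epochs are required
  downstream, since the debiased estimator needs $j \ne k$ pairs.

## Surrogate nulls

Per subject, the no-synchronization reference is built by permuting each
channel's samples independently (uniformly at random over all retained
samples, concatenated across epochs, then re-segmented). Sample-level
permutation is chosen over epoch-level because the point is to destroy
*all* temporal structure while preserving each channel's amplitude
distribution exactly. Shuffling happens after preprocessing and rejection
so the null is computed from exactly the epochs that produced the observed
statistic.

With $B$ surrogate statistics (default 1000), the one-sided empirical
p-value uses the add-one rule $p = (1 + \#\{\text{null} \ge
\text{obs}\})/(1 + B)$, which is never zero and has valid permutation-test
coverage; a two-sided variant doubles the smaller tail. The normalized
statistic is $z = (\text{obs} - \hat\mu_{\text{null}})/\hat\sigma_{\text{null}}$
(sample SD, $B-1$ denominator), which absorbs per-subject differences in
the null scale before between-subject correlation. Each replicate runs
under a seed derived from the master seed by a counter, so nulls are
reproducible and replicates independent of execution order.

## Group statistics

* **Band-then-pair hierarchy.** Stage 1 runs a two-sided Wilcoxon rank-sum
  test per band on the global (across-pairs) band mean, uncorrected; stage
  2 tests each pair only inside bands that pass stage 1 at α, reported
  uncorrected by default with a Holm flag. The hierarchy confines the
  multiplicity of pair-level testing to bands with evidence of an effect.
* **Wilcoxon convention**: exact null when the combined sample is ≤ 12
  without ties, else normal approximation with tie and continuity
  corrections (the exact path is validated against full enumeration in the
  tests).
* **Pooled t** for demographic/FA contrasts, oriented control − case so a
  deficit in cases appears as a positive t for scores where controls are
  higher; accepts summary statistics (means/SDs/ns) as published tables
  provide, or raw vectors.
* **Fisher's exact test** for 2×2 categorical tables reports the standard
  two-sided sum of hypergeometric probabilities ≤ the observed table's,
  *and* the observed table's point probability, because published tables
  sometimes quote the latter.
* **FA screening**: pooled t per (tract, side) with Holm–Bonferroni across
  all rows (28 in the default vocabulary).
* **Structure–function correlation**: Pearson r between null-normalized
  global band synchrony and a chosen tract's FA, within one group.
  Significance defaults to the Student-t form
  $t = r\sqrt{(n-2)/(1-r^2)}$, df $= n - 2$; the Fisher-z form
  ($z = \mathrm{atanh}(r)\sqrt{n-3}$) is available by flag. The t form is
  the default because at the sample sizes this design involves
  (n ≈ 12–22) it is the convention whose printed p-values such studies
  actually match.

## The synthetic cohort generator

No public EEG/DTI data accompany this design, so the generator produces
cohorts with the statistical structure the analysis assumes; it is
first-class, tested code, not a fixture.

Per subject, each scalp channel carries a 10 µV carrier at `f0_hz`
(default 32 Hz, inside low-gamma) whose phase is redrawn uniformly each
second — a common block phase shared by all channels — plus a fixed
per-channel lag and von Mises jitter with concentration κ. Large κ means
reliable cross-channel lags (strong lagged synchrony); κ = 0 means
independent phases. On top of this: a broadband component added
*identically and instantaneously* to all scalp channels (volume conduction
under the quasistatic approximation is zero-lag mixing, so this component
must be invisible to the estimators); a low-frequency (< 4 Hz) smoothed
ocular signal leaked into scalp channels with fixed per-channel gains and
emitted unmixed (noiselessly) on the EOG channels, making regression
correction exactly solvable; and independent Gaussian sensor noise
(default 5 µV). With these amplitudes the 75 µV rejection rate is
essentially zero unless artifacts are injected deliberately via
`artifact_rate`, which adds 100-ms, 150 µV pulses to randomly chosen
blocks and records them as ground truth for rejection tests.

Cohorts draw per-subject κ from group-specific normals truncated at zero
(defaults: cases mean 0, controls mean 4, SD 1 — a deficit regime in which
case-level synchrony is statistically indistinguishable from the null,
mirroring the contrast the pipeline is meant to detect). Fractional
anisotropy for the designated tract (default right inferior cerebellar
peduncle) is `baseline + fa_slope * (kappa - mean kappa) + noise`; all
other tracts are baseline + noise. Baselines are typical adult FA values
per tract; slope 0.003 and FA noise 0.004 put the within-group κ–FA
correlation near 0.7, the regime of interest for sign-recovery tests.

The block-phase von Mises model was chosen because it admits an exact
population value: for a pair whose phase difference is δ plus a single von
Mises(0, κ) draw, the population WPLI is
$|\mathrm{E}\sin(\delta + \eta)| / \mathrm{E}|\sin(\delta + \eta)|$,
evaluated by quadrature in `expected_wpli()`. Note the phase difference of
a pair whose *both* channels are jittered is a difference of two von Mises
draws, which is not von Mises; recovery and convergence tests therefore
use a per-channel κ of `c(Inf, kappa)` (a jitter-free reference channel),
for which the quadrature oracle is exact. Cohort simulation jitters all
channels; there the quantity of interest is the group contrast, not the
absolute value.

What the generator does **not** emulate: 1/f background spectra beyond the
single broadband term, realistic head-model topographies, non-stationary
artifacts (movement, electrode pops), or line noise. Passing tests
therefore certify the estimators and statistics under the assumed model,
not robustness to every pathology of real recordings.

## Problem sizes in the test suite

Monte-Carlo tests simulate at the 256 Hz analysis rate with 2–4 scalp
channels and feed 1-s epochs directly to the estimators; the
preprocessing stages are deterministic and are validated separately at the
full 2048 Hz acquisition rate. Calibration runs use 200 subjects (B = 199
surrogates) for p-value uniformity, 200 cohort replicates for group-test
power at the study's arm sizes (15 vs 22), 30 cohorts (B = 32) for
structure–function sign recovery on the 4-channel montage, and 20,000
epochs for the convergence check of the debiased estimator — sizes chosen
so Monte-Carlo error is small relative to each tolerance. The user-facing
surrogate default remains B = 1000.

## Known limitations

* Only unordered scalp-channel pairs at the sensor level; no source
  localization, coherence/PLV/ImC variants, or time-resolved estimates.
* EDF support is a minimal 16-bit reader/writer (1-s records, single
  sampling rate across signals), intended for interchange rather than full
  EDF+ compliance.
* The Wilcoxon exact path is limited to combined samples of 12 to keep the
  enumeration cheap; larger samples use the corrected normal
  approximation, which the tests show agrees to < 0.02 already at 6 + 6.
* FA enters only as a per-subject per-tract table; diffusion processing is
  out of scope.
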