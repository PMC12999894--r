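---
title: "Methods: VMD-based EEG classification in vmdEEG"
author: "vmdEEG maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VMD-based EEG classification in vmdEEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the pipeline

Schizophrenia alters resting-state cortical dynamics in ways that are
visible in scalp EEG: elevated low-frequency (delta/theta) power, reduced
broadband complexity, and disturbed frontal-temporal organization.
`vmdEEG` implements a complete detection pipeline around those markers:

1. **Preprocessing** — 0.5–45 Hz band-pass, 50 Hz notch, common average
   reference, segmentation into non-overlapping 8-s windows.
2. **Decomposition** — each window channel is split by variational mode
   decomposition (VMD) into `K = 10` band-limited intrinsic mode
   functions (IMFs).
3. **Features** — eight measures per IMF: mean Welch PSD, skewness,
   kurtosis, differential entropy, approximate entropy, sample entropy,
   Tsallis entropy, and the Higuchi fractal dimension. For a 16-channel
   montage this yields 16 × 10 × 8 = 1,280 features per segment, for the
   full 19-channel 10–20 montage 1,520.
4. **Classification** — a registry of classical learners whose
   hyperparameters are tuned by Gaussian-process Bayesian optimization of
   the 10-fold cross-validated misclassification rate.
5. **Evaluation** — stratified segment-level k-fold CV, strict
   subject-wise leave-one-out CV (LOOCV), lobe-wise sweeps over the
   10–20 montage, and paired t-test / Cohen's d comparisons.

# The VMD model

VMD decomposes a signal $f(t)$ into $K$ modes $u_k(t)$ with center
frequencies $\omega_k$ by minimizing the summed bandwidth of the modes'
analytic signals subject to $\sum_k u_k = f$. The solver works entirely
in the frequency domain (ADMM): each mode is updated by a Wiener-style
filter on the one-sided spectrum,

$$\hat u_k \leftarrow \frac{\hat f - \sum_{i \ne k}\hat u_i +
\hat\lambda/2}{1 + 2\alpha(\omega - \omega_k)^2},
\qquad
\omega_k \leftarrow \frac{\int_0^\infty \omega\,|\hat u_k|^2\,d\omega}
{\int_0^\infty |\hat u_k|^2\,d\omega},$$

with the dual ascent $\hat\lambda \leftarrow \hat\lambda +
\tau(\hat f - \sum_k \hat u_k)$ and the stopping rule
$\sum_k \|\hat u_k^{n+1}-\hat u_k^n\|_2^2 / \|\hat u_k^n\|_2^2 <
\mathrm{tol}$.

Defaults: $\alpha = 2000$ (the lower end of the commonly used
2000–3000 range; exposed in `vmdConfig()`), $\tau = 0$ (no strict
reconstruction, which tolerates residual noise), $K = 10$,
tol $= 10^{-6}$, at most 500 iterations.

Numerical choices worth knowing:

* **Initialization.** Center frequencies start uniformly spaced from DC,
  $\omega_k^{(0)} = (k-1)/2K$ (deterministic); `zero` and seeded
  `random` initializations are available.
* **Boundary handling.** The window is mirror-extended by half its
  length on each side before the FFT and cropped after inversion. This
  suppresses edge ringing but does not eliminate it: on a pure 8-s tone
  the mode-to-input correlation is ~0.997 over the full window and
  >0.999 over the central 80%.
* **Constant offsets.** The mode update is pointwise in frequency, so
  the signal mean is removed before the iteration and added back to the
  lowest mode afterwards. A DC shift therefore changes mode 1 only —
  modes 2..K are bitwise invariant — without pinning any mode to DC.
* **Mode order.** Modes are returned sorted by ascending center
  frequency, reported in Hz.

# Feature battery

All logarithms are natural (entropies in nats).

* **Mean PSD** — Welch estimate (periodic Hann window, segment length
  `min(256, n)`, 50% overlap), averaged over 0.5–45 Hz bins
  (µV²/Hz).
* **Skewness / kurtosis** — standardized third/fourth central moments;
  kurtosis is the Pearson (non-excess) form, so a Gaussian scores 3.
* **Differential entropy** — Gaussian closed form
  $\tfrac12\ln(2\pi e\sigma^2)$ with the unbiased sample variance;
  behaves as a log-band-power feature for near-Gaussian IMFs.
* **ApEn / SampEn** — template matching with embedding `m = 2` and
  tolerance `0.2·SD`, the universal EEG convention. ApEn includes the
  self-match; SampEn excludes it ($-\ln(A/B)$ over the $N-m$ common
  templates). Both share one O(N²) counting pass (C++, with sorted
  first-coordinate pruning); a pure-R brute-force oracle verifies count
  equality in the tests.
* **Tsallis entropy** — $(1-\sum_i p_i^q)/(q-1)$ with `q = 2` and a
  64-bin equal-width amplitude histogram (both configurable); the
  `q → 1` limit recovers Shannon entropy, which the tests check.
* **Higuchi FD** — curve-length slope over delays `k = 1..10`;
  `kmax = 10` is standard for windows of ~1–2k samples.

**Sentinel policy.** Undefined values (zero variance, no SampEn template
matches) become 0 accompanied by a classed warning
(`vmdEEG_sentinel`); `extractFeatures()` counts them in an
`n_sentinel` attribute. Matrices therefore stay rectangular and finite,
and tests can assert how often the policy fired.

Feature columns are named `CH{label}_IMF{k}_{feature}` in fixed
channel-major order, so any table is reconstructible from its header
alone.

# Classifiers and Bayesian optimization

The registry mirrors the familiar app-style variants: fine/medium/coarse
trees, linear discriminant, binary GLM, Gaussian naive Bayes, SVMs
(linear, quadratic, cubic, Gaussian with kernel scale
$\sqrt d/4,\ \sqrt d,\ 4\sqrt d$), k-NN (several k, cityblock/cosine
metrics, distance weighting), ensembles (bagged trees, AdaBoost.M1 over
stumps, random-subspace 1-NN/LDA), and a single-hidden-layer MLP
(narrow/medium/wide = 10/25/100 units; the underlying `nnet` engine
supports one hidden layer, so deeper variants are deliberately out of
the registry).

Hyperparameters $\theta$ minimize the cross-validated loss
$L_{cv}(\theta)$, the mean misclassification over 10 stratified folds
with fold-internal z-score normalization (leakage-safe: train-fold
statistics only; zero-variance columns are centered, not scaled). The
optimizer is a Gaussian-process surrogate (squared-exponential kernel on
the unit cube; length scale and noise picked from a small grid by
marginal likelihood) with the expected-improvement acquisition
($\xi = 0.01$), a 5-point Latin-hypercube initial design, and 30 total
objective evaluations. The same folds are reused for every evaluation,
so settings are compared paired; ties in the final arg-min go to the
earliest evaluation, making runs deterministic under a seed.

# Evaluation protocols

* **k-fold CV** operates at segment level with stratified folds
  (when a class is smaller than `k` — e.g. leave-one-segment-out —
  plain seeded folds are used). Predictions pool into one confusion
  matrix; SCH is the positive class throughout
  (`Ac`, `SE`, `SP`, `PR`, `F1`, ROC/AUC).
* **Subject-wise LOOCV** holds out all segments of one subject,
  fits the normalizer and classifier on the rest, and scores the
  fraction of the held-out subject's segments classified correctly.
  The summary is the *unweighted mean over subjects* (not the pooled
  segment accuracy), with the sample SD across subjects — the same
  aggregation the published per-subject tables use, which the tests
  reproduce (means 81.55% and 83.97%). By default a single optimized
  configuration is reused across folds; `optimizePerFold = TRUE`
  re-runs the Bayesian optimization inside every training fold at
  considerable cost.
* **Lobe-wise sweeps** group channels as frontal
  {Fp1, Fp2, F3, F4, F7, F8, Fz}, central {C3, C4, Cz}, parietal
  {P3, P4, Pz}, temporal {T3, T4, T5, T6}, occipital {O1, O2}. Midline
  electrodes go to the lobe of their line — standard 10–20 anatomy.
  All specs share folds (common seed) so comparisons are paired.
* **Paired comparison** is the textbook paired t-test (two-sided) with
  paired Cohen's d = mean(d)/sd(d). Zero-variance differences are
  degenerate: identical vectors give t = 0, p = 1; a constant nonzero
  shift yields NA with a warning rather than an invented p-value.

# The synthetic generator

`generateRecordings()` emulates the statistical structure the pipeline
assumes: per channel, a sum of amplitude-modulated narrowband
oscillations in the delta (0.5–4), theta (4–8), alpha (8–13) and beta
(13–30 Hz) bands — random-walk phase, slow sinusoidal envelopes — plus
1/f background noise (exponent 1.0, RMS 10 µV against band RMS
amplitudes of 20/15/25/10 µV, alpha-dominant as in relaxed eyes-closed
recordings). The patient class multiplies delta/theta power by
`delta_theta_power_ratio` (default 2.0), beta power by
`high_band_attenuation` (default 0.5), and reduces oscillatory phase
noise by `regularity_boost` (default 0.5), on the channels of
`affected_lobes`. Band power in 0.5–8 Hz consequently differs between
classes by close to the configured ratio (the 1/f floor dilutes it
mildly), which a generator test verifies by Welch analysis.

Oscillation parameters are **redrawn for every 8-s window**, so windows
— and therefore subjects — of a class are exchangeable. This is a
deliberate design choice: early testing showed that holding amplitudes
and center frequencies fixed per subject creates subject-identity
fingerprints that segment-level CV exploits (~95% "accuracy" under a
*null* class contrast — precisely the leakage phenomenon subject-wise
LOOCV exists to prevent). With exchangeable windows a null contrast is
genuinely indistinguishable and segment-CV sits at chance.

What the generator does **not** emulate: ocular/muscle artifacts,
inter-channel covariance structure, nonstationarity across a session,
and — by the choice above — stable subject-level variability. Passing
the end-to-end tests therefore shows the pipeline recovers planted
band-power/complexity contrasts; it does not certify performance on
real recordings, where subject effects make segment-level CV optimistic
relative to LOOCV.

Default cohort sizes mirror the datasets the pipeline targets: 8-s
windows at 128 Hz on the 16-channel montage, 7 windows per subject (a
1-minute recording), 10 subjects per class.

# Problem sizes and determinism

The test suite and the acceptance script run the full pipeline at
10 + 10 subjects × 7 segments (strong contrast; 140 segments of
16-channel VMD at K = 10) and 8 + 8 subjects × 4 segments × 5 seeds for
the null contrast — sizes chosen so the class-recovery claims are
testable with comfortable statistical margins on a single CPU. All
randomness flows through explicit seeds (generator, fold assignment,
optimizer, stochastic learners); identical configurations reproduce
byte-identical artifacts, which the pipeline tests assert.

# Known limitations

* With $\tau = 0$ reconstruction is approximate; the residual carries
  whatever the Wiener filters reject (tests assert correlation ≥ 0.95
  against the band-passed input on synthetic EEG, and monotone residual
  decay over early iterations).
* ApEn/SampEn equal the naive O(N²) definition exactly at the level of
  template-match counts; the accumulated log-sums can differ from a
  naive evaluation near machine precision (~1e-14) because the pruned
  implementation sums in a different order.
* The MLP family is single-hidden-layer.
* No artifact rejection beyond filtering (the upstream datasets are
  resting-state, eyes closed); no automatic selection of K.
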