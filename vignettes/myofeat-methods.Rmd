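---
title: "Nonlinear time-domain EMG features: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear time-domain EMG features: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myofeat)
```

## The problem

Myoelectric pattern recognition classifies intended movements from surface
electromyogram (sEMG) recordings, typically to drive a prosthetic hand. With
few electrode channels, the hardest errors concentrate on movements with weak
signal strengths: their amplitude differences are small in absolute terms,
so classifiers dominated by strong contractions confuse them. `myofeat`
implements a feature-extraction pipeline built around two nonlinear-scaling
time-domain features designed to attack exactly this failure mode, together
with everything needed to evaluate them end to end: classical feature
baselines, uncorrelated LDA reduction, a classifier stage, a
cluster-separability index, forward feature selection, and robustness sweeps
over window size and SNR.

## The two core features

For a single-channel analysis window $x_1, \dots, x_N$:

**LMAV** (log mean absolute value) is
$\mathrm{LMAV} = \ln\!\big(\tfrac{1}{N}\sum_i |x_i|\big)$.
The logarithm compresses dynamic range: a fixed *ratio* of amplitudes maps to
a fixed *difference* of feature values, so two weak contractions differing by
a factor of 1.5 are as far apart as two strong ones differing by the same
factor. Equivalently, `lmav(a*x) = log(a) + lmav(x)` — a property the test
suite asserts.

**NSV** (nonlinear scaled value) is
$\mathrm{NSV} = \ln\!\big(\tfrac{1}{N}\sum_i \big((\bar{x} - x_i)^{1/3}\big)^2\big)$
where $\bar{x}$ is the window's mean absolute value and the cube root is the
real signed cube root, so each term equals $|\bar{x} - x_i|^{2/3}$. It
measures the spread of raw samples around the rectified amplitude level,
with a fractional power that emphasizes small deviations.

Two typeset readings of the NSV bracketing — cube root then square, or
square then cube root — are algebraically identical
($((\bar{x}-x_i)^2)^{1/3} = |\bar{x}-x_i|^{2/3}$), so no option separates
them. Whether the deviation should use the raw or the rectified sample is
genuinely open; the default uses the raw sample and `nsv(x, rectify = TRUE)`
provides the alternative.

Both features take a logarithm, so an internal floor of $10^{-12}$ keeps
all-zero or constant windows finite; without it a single silent window would
poison the downstream scatter matrices.

## Feature sets

Per channel: `FS1` is six autoregressive coefficients plus RMS (7), `FS2` is
{IEMG, WL, WAMP, ZC, SSC, VAR} (6), `FS3` is the six time-dependent
power-spectrum descriptors, `FS4` the seven temporal-spatial descriptors,
and `PROPOSED` is {LMAV, NSV, WL, WAMP, SSC, ZC, MOB, COM, SKW, AR1–AR4}
(13). Channels are computed independently and concatenated — with two
channels the proposed set yields 26 columns. No cross-channel features are
formed.

The moment descriptors (FS3/FS4) use time-domain surrogates
$m_0 = \sqrt{\sum x^2}$, $m_2 = \sqrt{\sum (\Delta x)^2}$,
$m_4 = \sqrt{\sum (\Delta^2 x)^2}$. The three moment magnitudes are
power-transformed ($m^{\lambda}/\lambda$, $\lambda = 0.1$) before the log,
following the cited constructions for these descriptor families; the
irregularity factor $m_2/\sqrt{m_0 m_4}$ and sparseness
$m_0/\sqrt{|(m_0-m_2)(m_0-m_4)|}$ are deliberately computed from the *raw*
moments so that they are exactly invariant to amplitude scaling (the
narrowband limit of the irregularity factor is 1, which the tests verify on
a pure sinusoid). The coefficient of variation in FS4 is taken on the
rectified signal because raw sEMG is zero-mean, which makes the usual
`sd/mean` unstable; the Teager–Kaiser term is the log of the mean absolute
operator output.

Thresholds default to 0 for ZC and SSC, 0.01 for WAMP and 0.016 for MYOP (in
the signal's amplitude units, i.e. 10 mV- and 16 mV-equivalents for
volt-scaled data); none are dictated by the method itself, all are exposed in
`feature_params()`. AR coefficients are Yule–Walker estimates of the linear
prediction $x_i \approx \sum_k a_k x_{i-k}$, order 4 in the proposed set and
6 in FS1.

## Pipeline

Trials are filtered before segmentation — a 4th-order Butterworth band-pass
(20–500 Hz) and a second-order IIR notch (50 Hz, quality factor 30,
closed-form biquad coefficients) — both applied forward–backward for zero
phase. Zero-phase filtering costs a doubled magnitude response but removes
phase distortion at window boundaries; filtering whole trials first means
windows carry no per-window filter transients. The cut-offs are the method's;
the order and design are this package's choice and are arguments to
`emg_bandpass()`/`emg_notch()`.

Windowing is disjoint: `floor(n_samples / window_len)` contiguous windows
anchored at the first sample, remainder discarded. A 5 s trial at 2000 Hz
with 250 ms windows gives exactly 20 segments.

Dimensionality is reduced with uncorrelated LDA to at most $K-1$ dimensions
for $K$ classes (9 for the ten-movement setting). The implementation whitens
with the SVD of the centred data matrix and takes the leading left singular
vectors of the whitened between-class scatter; this is robust to singular
within-class scatter from small folds, and guarantees
$G^\top S_t G = I$ (asserted to $10^{-6}$, observed at $10^{-12}$). Rank
truncation drops singular values below $10^{-10}$ of the maximum. Inside
cross-validation the projection is refitted on each fold's training windows
only, so no test information leaks into the reduction.

Classifiers: a Gaussian discriminant with per-class covariance (quadratic
boundary) as the default "LDA" reading, with a pooled-covariance linear
variant behind `lda_pooled = TRUE`; an RBF SVM with kernel width
$\sigma = 1$ (inputs are not re-standardized — the ULDA features are already
whitened against total scatter); and a $k{=}3$ nearest-neighbour vote under
the cityblock (L1) metric, with vote ties broken by the smaller summed
distance. Metrics are one-vs-rest per movement (accuracy, sensitivity,
specificity, precision, F1, all in percent), macro-averaged; a
zero-denominator metric is reported as 0 with a warning so sweep aggregation
stays total. Cross-validation is trial-wise: fold $t$ tests on trial $t$ of
every movement and trains on the rest, repeated over all trials.

The RES separability index is the mean pairwise Euclidean distance between
class means on a 2-D embedding divided by the mean within-class standard
deviation (sample SD, $N-1$ denominator — the conventional $s$; the
definition does not specify it). It is restricted to exactly two embedding
columns rather than silently generalized, because its distance term is
defined on coordinate pairs. The scatter export takes ULDA dimensions 1–2,
min–max normalizes each to $[0,1]$, and in `paper_points = TRUE` mode keeps
every 4th window, i.e. 5 points per 5 s trial — the conventional 300-point
display for 10 movements × 6 trials — while normal use keeps all windows.
For visualization the projection is fitted on all data; for classification
it is always fitted per training fold.

Forward selection greedily grows a feature set from a 32-candidate pool,
accepting the best extension only when it improves the cross-validated score
by at least 0.25 percentage points. The scored metric is macro F1 by default
(accuracy is a flag): F1 is the quantity the evaluation reports emphasize,
and the gain unit is percentage points either way. The pool is the full
registry — 18 classical statistics, LMAV and NSV, AR1–AR4 individually, the
six power-spectrum descriptors, and the two extra temporal-spatial
descriptors — because the historical 32-feature pool membership is not
enumerated anywhere; `forward_select()` accepts any pool so the experiment
stays reproducible under other choices. Ties break by pool order,
deterministically.

## The synthetic generator

`generate_dataset()` emulates two-channel, ten-movement, six-trial, 5 s
steady-state recordings at 2000 Hz. Each channel is band-limited Gaussian
noise (the same 20–500 Hz band-pass used by the preprocessing front end),
standardized to unit RMS and scaled by a per-movement, per-channel
amplitude, plus additive white Gaussian electrode noise. Amplitude is the
dominant property distinguishing movements in real two-channel forearm
recordings, so amplitude-coded classes are the right synthetic structure.
The default amplitude table gives every movement a distinct two-channel
signature spanning 0.10–1.60 with two deliberately weak movements near the
noise floor; the default noise RMS of 0.1 places the movements in roughly
the 5–23 dB SNR band reported for wet-electrode recordings. Seeding is one
master seed with per-trial streams derived by counter, so a single trial can
be regenerated without perturbing the rest, and identical configs are
bit-identical.

Optionally, `force_jitter_sd > 0` multiplies the physiological carrier (not
the electrode noise) by a slow lognormal envelope band-limited to
`force_jitter_hz` (default 2 Hz), emulating force fluctuation during a held
contraction. The default is 0 — perfectly constant steady-state envelopes.
This knob exists because the weak-signal mechanism is only observable under
multiplicative within-class variability: with perfectly constant envelopes,
windowed amplitude statistics concentrate so sharply (hundreds of samples
per window) that even near-noise-floor classes separate perfectly, and a
log transform of a one-dimensional statistic cannot change a ceiling. Under
force jitter, linear amplitude features acquire within-class variance
proportional to amplitude squared — strong movements dominate pooled
scatter and crowd the weak ones — whereas log-scaled features have
approximately constant within-class variance. That variance stabilization
is the mechanism by which LMAV and NSV help weak movements, and it is a
linear-model property, which is why the weak-movement property tests score
with the pooled-covariance discriminant.

What the generator does *not* emulate: motor-unit action potential shapes
and firing statistics, force-level recruitment nonlinearity, movement onset
transients, electrode shift, power-line harmonics, or cross-channel
correlation. Tests passing on this generator therefore demonstrate the
pipeline's arithmetic, its statistical contracts, and the variance
-stabilization mechanism — not performance on real recordings.

## Numerical choices and degenerate inputs

* Log floors at $10^{-12}$ (LMAV, NSV, log detector, MFL, descriptor logs).
* Constant windows: variance-ratio features (MOB, COM, SKW, KURT) return 0;
  AR coefficients return zeros; `extract_features()` refuses non-finite
  cells, naming the window and feature.
* `minmax_normalize()` errors on constant features (or drops them by flag);
  `res_index()` errors on degenerate clusters with zero mean SD.
* `snr_db()` requires the raw RMS to exceed the noise RMS — otherwise there
  is no real signal component to report.
* `add_awgn()` measures signal power per channel and errors on zero-power
  input.
* ULDA rank truncation at $10^{-10}$ relative; transforms refuse mismatched
  feature columns.
* Sample SDs use the $N-1$ denominator throughout.

## Problem sizes used in the test-suite experiments

The bundled experiments run on deliberately small instances chosen to
exercise each property: full-geometry datasets (10 movements × 6 trials ×
5 s) where the check is about the standard arithmetic (20 windows/trial,
1000/200 fold splits, 300 scatter points), and reduced ones (fewer
movements, 1–2 s trials) for the permutation null and the sweep grids. The
weak-movement experiments use 4 movements (two strong, two weak at 0.06 and
0.10 against noise RMS 0.05), 6 trials of 5 s, force jitter SD 0.5, at three
fixed seeds.

## Known limitations

* The descriptor constants for FS3/FS4 (power transform $\lambda$, the
  rectified-signal CV, the absolute-value Teager–Kaiser mean) pin down
  constructions their literature leaves partially open; they are documented
  arguments, not hidden constants.
* The quadratic-boundary discriminant needs more training windows per class
  than reduced dimensions; tiny fixtures should use `lda_pooled = TRUE`.
* The RES index is defined only for 2-D embeddings by construction.
* Synthetic results do not transfer to human recordings; the generator's
  purpose is verification, not simulation fidelity.
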