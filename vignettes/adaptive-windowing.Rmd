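---
title: "Adaptive time-windowing for surface-EMG pattern recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive time-windowing for surface-EMG pattern recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgadapt)
```

## The problem

Myoelectric prosthesis controllers classify overlapped windows of
multi-channel surface EMG (sEMG) into intended movement classes. The window
length is a latency/accuracy dial: short windows react quickly but their
features are noisy; long windows average that noise away at the cost of
delay. Conventional controllers fix one short window (here 150 ms, advancing
in 50 ms steps) and accept whatever the classifier says — including
low-confidence guesses that, in daily prosthesis use, translate into dropped
objects.

`emgadapt` implements the alternative this package is built around: make the
window length *adaptive per decision*. A probabilistic classifier scores
each window; when the largest class posterior $Pr_{\max}$ reaches a
confidence threshold $\theta$ the class is emitted immediately, otherwise
the controller waits for more signal — the same window start is extended by
50 ms and re-classified — up to a 350 ms maximum, after which the decision
is *rejected* (the prosthesis holds state). Only the difficult decisions pay
extra latency.

## The processing chain

1. **Band-pass filtering.** 20–450 Hz, 4th-order Butterworth, zero phase
   (`bandpass()`). This is the standard sEMG analysis band.
2. **Windowing.** Anchors advance by 50 ms; only starts that can host the
   full 350 ms schedule are enumerated, so every threshold is evaluated on
   an identical decision set (`window_schedule()`, `enumerate_anchors()`).
   The window *start* is fixed and its *end* grows — extension means waiting
   for future samples, so the decision latency equals the final window size.
   (Whether extension should consume past samples instead is a genuinely
   open choice; fixed-start/forward-growth matches the deployment story of a
   real-time controller, and we adopt it throughout.)
3. **Features.** Three per-channel families, concatenated channel-major:
   Hudgins-style time-domain features (IAV, WL, ZC, SSC; 4/channel),
   wavelet-packet energies (order-8 symlet, 5 levels, 32 terminal nodes per
   channel), and time-domain power-spectral descriptors (TD-PSD, 6/channel).
4. **Reduction.** Spectral-regression discriminant analysis maps features to
   exactly $c-1$ dimensions, $c$ the number of classes (`fit_sr()`).
   Training pools features from *all five* window sizes so one model serves
   every size at decision time.
5. **Classification.** Gaussian LDA with pooled covariance and posterior
   output, evaluated in log space (`fit_lda()`, `posteriors()`).
6. **Adaptive decision loop.** `decide()` / `run_session()` implement the
   accept-extend-reject iteration; features are recomputed from scratch at
   every size (they are nonlinear in the window, so no incremental update is
   attempted).
7. **Threshold tuning.** `sweep_thresholds()` traces validation error and
   the percentage of extended windows over the 16-value grid
   $\theta \in \{0.70, 0.72, \ldots, 0.98, 0.99\}$;
   `select_tradeoff_threshold()` picks the operating point.

The evaluation metric is the classification error rate,
$100 \times$ (incorrect decisions)/(total decisions), computed over accepted
decisions only; rejected windows are excluded from numerator and denominator
and reported separately as a rejection rate, so no information is hidden.
The percentage of increased windows counts *all* enumerated anchors in its
denominator, rejected ones included (a rejected window was extended to the
maximum, so it counts as increased).

## The two-phase protocol

`run_experiment()` executes the full design/evaluation protocol on one
subject:

* **Design phase** — train the projection + LDA on 2 trials per class, sweep
  the threshold grid on 2 further validation trials per class, and select
  the subject-specific trade-off threshold.
* **Evaluation phase** — retrain on the pooled 4 trials per class and run
  the adaptive loop once, at the selected $\theta$, on the held-out
  remaining trials.

Baselines computed on the same test decisions: classical fixed-150 ms LDA
(argmax, no confidence gate), majority vote over the current and 8 previous
decisions (`majority_vote()`), and Bayesian fusion — summed log posteriors
over the same span (`bayes_fusion()`). MV/BF streams are kept per trial, as
a deployed controller's decision history would be.

### The trade-off threshold rule

The original procedure selects $\theta$ by visual inspection of a dual-axis
plot whose axes are scaled to each curve's own range. To make results
reproducible we formalize exactly that reading: min–max normalize the error
curve and the %-increased curve to $[0,1]$, find the first crossing of the
two piecewise-linear curves, and return the smallest grid value strictly
greater than the crossing abscissa. If the curves never cross, the grid
value minimizing the normalized gap is used; if a curve is constant (e.g. a
ceiling-performance subject), the grid midpoint is returned with a warning.
These fallbacks matter on easy synthetic subjects whose validation error is
identically zero.

## The synthetic-data generator

The recordings the method was designed for (amputee sEMG) are not publicly
deposited, so the package ships a generator that emulates the *statistical
structure the chain assumes* rather than the physiology:

* each channel of a trial is an independent zero-mean Gaussian carrier,
  band-limited to 20–450 Hz and normalized to unit RMS;
* a class is an amplitude pattern: a non-negative gain per (class, channel)
  from `make_activation_matrix()`. Class 1 is rest (zero gain). Active
  patterns scale with a `separability` knob; pairwise distances between
  class rows grow linearly in it, and at 0 every class collapses onto rest,
  pinning downstream accuracy to chance;
* a white sensor-noise floor is added; its default SD is 5% of the mean
  active-channel gain *at unit separability* (floored at 0.01), so it acts
  as an absolute sensor property: lowering `separability` genuinely sinks
  the classes into the noise rather than rescaling signal and noise
  together;
* rep-to-rep motor variability is modelled as a lognormal per-trial,
  per-channel gain multiplier with SD 0.2 on the log scale (`gain_jitter`),
  a realistic ~20% amplitude variability between repetitions of the same
  contraction. Without it the generator is unrealistically repeatable and
  every configuration is trivially separable; with it, errors cluster in
  unlucky trials, which is also how errors arrive in real decision streams;
* trial durations are uniform in 8–12 s by default (`duration_range_s`),
  with five or more trials per class so the 2/2/rest split is possible. An
  optional linear amplitude `drift` knob exists but is off by default
  (constant, non-fatiguing holds).

One master seed drives everything; per-trial substreams are derived by a
counter hash, so generation order is irrelevant and datasets reproduce
bit-for-bit.

What the generator does **not** model: motor-unit physiology, electrode
geometry and crosstalk, force and posture variation, electrode shift, or
any spectral difference between classes (classes differ in amplitude
pattern only). Passing tests therefore certify the *decision machinery* —
loop mechanics, threshold behaviour, protocol fidelity, metric arithmetic —
not performance on amputee recordings.

## Numerical choices

* **TD-PSD.** Root spectral moments $m_0, m_2, m_4$ of the window and its
  first/second differences are power-normalized as $m^{\lambda}/\lambda$
  with $\lambda = 0.1$; the six descriptors take the log of the *magnitude*
  of their arguments ($m_2 > m_0$ is routine for wideband windows, so a
  signed log would be undefined on perfectly valid input); a zero argument
  (e.g. a constant window) raises a descriptive error rather than being
  clamped. The dual-representation fusion — descriptors of the raw window
  and of its log-squared counterpart combined by the orientation measure
  $-2 a_i b_i / (a_i^2 + b_i^2)$ — is on by default and configurable.
* **Wavelet packets.** "Energy at each node" is read as the 32 terminal
  nodes of the 5-level packet tree; all-tree-nodes and plain-DWT variants
  are available behind `feature_config()`. Boundaries are periodized, so
  the transform is orthonormal and terminal energies sum to the window's
  energy (exactly for window lengths divisible by $2^5$; odd intermediate
  lengths are extended by one sample).
* **Zero-crossing / slope-sign dead zone** defaults to 0: reproducible, and
  the synthetic signals carry an explicit noise floor rather than
  quantization artefacts. It is configurable for noisier data.
* **Standardization before SR.** Raw IAV/WL and band energies scale with
  window length, and the training set pools five lengths; features are
  z-scored on the training set. The ridge penalty defaults to
  $\alpha = 0.01$, which stabilizes collinear wavelet energies while
  leaving the spanned subspace within numerical agreement of a Fisher
  eigen-solution on well-conditioned problems.
* **LDA shrinkage** $\gamma = 10^{-6}$ is a positive-definiteness floor
  only; after SR the space is just $c-1$-dimensional and needs no real
  regularization. Priors are uniform (the synthetic design is balanced).
* **Ties** in the argmax are broken toward the first (lowest-index) class;
  majority-vote ties are broken toward the most recently seen tied class.

## Problem sizes used in the shipped tests

The package's own test suite and acceptance script run the full protocol on
scaled-down subjects — typically 3–9 classes, 2–7 channels, 5 trials per
class of 1–3 s each — which keeps a complete two-phase experiment in the
tens of seconds while exercising every stage identically to a full-size
run. The replicated-ordering study (adaptive vs classical vs MV/BF) uses 20
seeded subjects at 9 classes × 7 channels with `separability = 0.06`, a
value calibrated once so that classical fixed-window error lands in the
10–30% band, i.e. a realistically difficult subject; at that operating
point the adaptive loop's advantage is visible and the post-processing
baselines fall between the adaptive and classical error rates in
expectation.

## Known limitations

* The generator's classes differ only in amplitude pattern; feature
  families that react to spectral shape (wavelet, TD-PSD) are exercised
  numerically but their discriminative advantage over TD features on real
  EMG cannot be reproduced here.
* Rejection quality is only as good as LDA's calibration; on synthetic data
  posteriors can saturate at 1.0 in floating point for very separable
  classes, which is why a confidence threshold of exactly 1 is exercised on
  stub posteriors in the tests.
* The trade-off rule is one defensible formalization of a visual
  procedure; alternatives (e.g. knee-point detection) would select slightly
  different thresholds on the same curves.
* Offline analysis only: the engine models latency as final window size and
  does not simulate wall-clock streaming.
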