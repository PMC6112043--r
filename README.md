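# emgadapt

Adaptive time-windowing for surface-EMG (sEMG) pattern-recognition control
of upper-limb prostheses.

A conventional myoelectric controller classifies overlapped, fixed-length
EMG windows and outputs the winning class no matter how uncertain the
classifier is. `emgadapt` implements the adaptive alternative: the
classifier emits per-class posterior probabilities, and a window is only
answered when the largest posterior clears a subject-specific confidence
threshold,

$$ Pr_{\max} = \max_k \Pr(k \mid \text{window}) \geq \theta . $$

When confidence is insufficient, the same window start is extended — 150 ms
→ 200 → 250 → 300 → 350 ms in 50 ms steps — and features are recomputed,
trading a little latency for accuracy on exactly the hard decisions. If the
maximal window is reached without confidence, the decision is **rejected**
and the prosthesis holds state. The supporting chain is the full pipeline
such a controller needs:

* a synthetic multi-channel sEMG generator (band-limited Gaussian carriers
  amplitude-modulated per class/channel, sensor noise floor, rep-to-rep
  gain variability, one-seed reproducibility);
* 20–450 Hz zero-phase Butterworth filtering and overlapped windowing;
* three feature families: Hudgins time-domain (IAV, WL, ZC, SSC),
  wavelet-packet energies (sym8, 5 levels, 32 nodes/channel), and
  time-domain power-spectral descriptors (TD-PSD);
* spectral-regression discriminant reduction to c − 1 dimensions, trained
  on features pooled over all five window sizes;
* Gaussian LDA with calibrated posteriors;
* design-phase threshold tuning over the 16-value grid
  θ ∈ {0.70, 0.72, …, 0.98, 0.99} via error / %-extended-windows trade-off
  curves, then unbiased evaluation on held-out trials;
* classical fixed-window LDA, majority-vote (MV) and Bayesian-fusion (BF)
  post-processing baselines over the current + 8 previous decisions.

## Worked example

```r
library(emgadapt)

cfg <- experiment_config(
  n_classes = 9, n_channels = 7, trials_per_class = 5,
  duration_range_s = c(2, 3),  # short holds keep the example quick
  separability = 0.06,         # a realistically difficult subject
  family = "TD", seed = 2)
report <- run_experiment(cfg)
print(report)
```

```
Adaptive-windowing experiment report
  trade-off threshold (theta): 0.92
  adaptive error rate:         8.1%
  classical LDA (150 ms):      26.3%
  LDA + majority vote:         25.2%
  LDA + Bayesian fusion:       25.2%
  rejection rate:              4.8%
  increased windows:           43.0%
  final window size:           195.1 +/- 62.5 ms
```

Reading this: the design phase picked θ = 0.92 for this synthetic subject
from the validation trade-off curves. On the unseen test trials, the
fixed-150 ms classifier errs on 26.3% of windows; gating decisions at
θ = 0.92 cuts the error to 8.1% while declining to answer 4.8% of windows
and extending 43% of them (mean latency 195 ms instead of 150 ms).
Decision-stream smoothing (MV/BF) helps much less because errors arrive in
bursts within hard trials. `write_report(report, "out/")` saves
`report.json`, `curves.csv`, `decisions.csv` and `confusion.csv`; a thin
command-line wrapper with `synth` and `experiment` subcommands is installed
at `inst/scripts/emgadapt`.

Lower-level entry points mirror the processing stages: `generate_dataset()`,
`bandpass()`, `enumerate_anchors()`, `td_features()` /
`wavelet_energy_features()` / `td_psd_features()`, `fit_sr()`, `fit_lda()`,
`posteriors()`, `decide()`, `run_session()`, `sweep_thresholds()`,
`select_tradeoff_threshold()`, `majority_vote()`, `bayes_fusion()`. The
vignette (`vignettes/adaptive-windowing.Rmd`) documents the model, the
generator's assumptions and every numerical choice.

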