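---
title: "Suppressing motion artifacts in insulated surface EMG"
author: "emgartifact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suppressing motion artifacts in insulated surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgartifact)
```

## The problem

Capacitively coupled ("insulated") surface EMG sensors make myoelectric
prosthesis control independent of sweat and skin condition, but they are
sensitive to motion artifacts: sensor lift-off, mechanical shocks and
vibration produce excursions that can dwarf the muscle signal and reach into
the EMG band, so band filtering alone cannot remove them. An artifact that
reaches the prosthesis drive activates the hand when the user did not
contract — the single most disruptive failure mode in daily use.

This package implements a real-time artifact suppression pipeline for a
single EMG channel: a bank of 26 streaming time-domain feature state
machines feeds a shallow classifier (ridge logistic regression, Gini
decision tree, satlins/purelin feed-forward net, or a delay-1 recurrent
net); the debounced binary decision then gates a delayed EMG envelope, so
the drive is only powered during true contractions. Everything downstream of
the filters is specified in fixed-point integer arithmetic so that the same
computation runs on a 32-bit microcontroller without a floating-point unit.

## Signal path and the feature bank

The raw channel (10 kHz) passes a simulated analog band-pass (11–1064 Hz),
averaging decimation to 2 kHz, a comb filter with zeros at 50 Hz and its
harmonics, and a first-order 531 Hz lowpass. The resulting integer carrier
$x_i$ drives every feature and, rectified and EMA-smoothed (51 ms), the
output envelope.

Each feature is an exponentially decaying moving average (EMA) over a
per-sample event or magnitude function $f(x_i)$:

$$\mathrm{feat}_i = \big(\mathrm{feat}_{i-1} + f(x_i)\big)\, b,
\qquad T = \frac{b}{(1-b)\,f_s},$$

with $b$ a dyadic coefficient ($m/2^k$, applied as one multiply and one
arithmetic right shift). At 2 kHz, $b = 254/256$ gives $T = 63.5$ ms and
$b = 255/256$ gives $T = 127.5$ ms — `ema_time_constant()` reproduces both.
The families are: zero-crossing rate (ZCR, with a hysteresis dead-band),
mean-crossing rate (MCR — crossings through the signal's own smoothed
version, which tracks slow baseline), slope-sign change (SSC, with minimum
and maximum run lengths `dmin`/`dmax`), waveform length (WFL), mean absolute
value (MAV), Willison amplitude (WAM — threshold exceedances) and variance
(VAR). Several variants carry saturation bounds `lb`/`ub` that stop the
accumulator from drifting far from its operating region, which is what makes
class transitions fast. `feature_table()` lists all 26 parameter rows;
`run_feature()` and `feature_bank()` expose the streaming state machines
(chunked execution is bit-identical to a batch call).

Two arithmetic paths exist. The `"fixed"` path is the hardware contract:
integer state, dyadic coefficients, truncating shifts, saturation. The
`"float"` reference path keeps the real-valued design coefficients for the
EMA stages but models the same truncation, mirroring the original design
flow in which the desktop reference and the embedded code shared value
ranges and truncation; a truncation-free reference would sit a constant
$\approx 0.5/(1-b)$ counts above the integer path, which for low-rate event
features is far outside any useful comparison band. The input scales `d` and
`e` are *defined* as shifts (1/128, 1/64, 1/32 — the printed decimals are
4-digit displays), so both paths use their exact dyadic values.

The feature bank consumes the comb/lowpass carrier directly, without the
60 Hz feature-path highpass, which remains available
(`compute_features(..., highpass = TRUE)`). The sub-60 Hz band is where
artifacts live; feeding the bank a signal stripped of it blinds exactly the
features (MCR's smoothed references, amplitude thresholds) that are designed
to see and reject artifacts. With the full-band input the pipeline operates
in the published accuracy regime; with the highpass it saturates several
points lower.

## The synthetic corpus

The original single-subject recordings are not publicly deposited, so a
seeded generator (`gen_corpus()`) emulates the study conditions: 381 s of
contractions and 489 s of artifacts by default, at 10 kHz, assembled from
strong/weak isometric holds, random sequences of short (≤ 0.4 s)
contractions, and lift-off / shock / vibration artifacts. Choices a user
should know about:

* **Amplitude calibration.** A strong contraction has RMS 300 ADC counts,
  which puts the published integer thresholds (hysteresis 242, Willison
  threshold 44 ≈ 3 SD of the noise floor, …) on a meaningful scale; the
  noise floor is 5% of that. Weak contractions scale by 0.3 — deliberately
  below the ZCR hysteresis, so weak detection must come from
  lower-threshold and amplitude features.
* **Contraction realism.** Band-limited (60–500 Hz) Gaussian noise under a
  trapezoidal envelope (rise/fall 50–150 ms), with a per-contraction
  spectral knee (100–350 Hz) and a slow ±25% effort drift: surface-EMG
  spectra are peaked and non-stationary, and without that variation the
  feature bank's rate features would be a deterministic function of
  amplitude, collapsing the corpus' correlation structure. Strong and weak
  holds are drawn as 8–12 s takes, matching a 10 s recording protocol;
  shorter takes would create artificial envelope dips wherever two segments
  abut in a window pool.
* **Artifact realism.** Lift-off is a 0.5–5 Hz excursion at 3–10× the
  contraction RMS; a shock is an exponentially damped 10–40 Hz ring-down
  (soft tissue and a flexible sensor resonate low); vibration is a 5–30 Hz
  tone with decaying harmonics. Every artifact also carries
  motion-correlated broadband hash inside the EMG band, log-uniformly
  scaled per segment up to roughly half the weak-contraction amplitude —
  enough that in-band filtering cannot remove artifacts, not so much that
  artifacts out-power the contractions in their own band.
* **What it does not model.** Motor-unit physiology, electrode geometry,
  inter-subject variability, and real co-contraction patterns. Passing
  tests on this corpus show that the pipeline recovers class structure the
  generator puts in; they do not certify performance on any individual's
  physiology.

A sanity property is asserted in the tests: on a default-seed corpus at
least one feature separates the classes by more than 3 pooled standard
deviations, measured on steady-state samples (the 250 ms after each class
transition is skipped, mirroring the transition tolerance used everywhere in
the evaluation).

## Dataset assembly and training

Pre-processed segments are pooled per subtype, cut into windows (1 s fixed,
or 0.5–1.5 s when `vary = TRUE` so a recurrent model cannot learn the window
period), interleaved so classes alternate and subtypes cycle proportionally,
and windows whose envelope never reaches the activation threshold (3× the
noise-floor envelope) are removed. Features run continuously across window
boundaries, are decimated to 40 Hz (logistic regression, tree, feed-forward
net) or 250 Hz (recurrent net), and split 70/15/15 into contiguous,
subtype-stratified window runs (`stratified_contiguous_split()`): drawing
individual samples would leak the strong serial correlation of smoothed
features across partitions.

On the training partition, features with pairwise $|r| > 0.9$ are pruned
(the earlier feature in canonical order is kept; constant columns are also
dropped since Pearson correlation is undefined for them and min-max
normalization would divide by zero). Remaining features are min-max
normalized to $[-1, 1]$ (±1024 in fixed point) for all families except the
tree, which splits raw integer values. Out-of-range test values extrapolate
linearly; the quantized representation saturates at the signed 16-bit range.

`cv_train()` selects features and hyper-parameters by 5-fold
cross-validation on contiguous window folds, scoring debounced decisions
with a 100 ms transition tolerance. Selection follows the family: the
binomial lasso path for the logistic regression; sequential backward
elimination scored by fold-CV accuracy with the tree trainer for the tree;
and backward elimination with a fast linear proxy trainer for the networks
(running the full network trainer inside the elimination loop is supported
via `sbs_select()` but costs orders of magnitude more). The networks train
by full-batch iRprop⁻ on the squared error to 0/1 targets with the
reference stopping rule — at most 1000 epochs (100 for the recurrent net)
and six consecutive validation failures; a noisy first-order optimizer such
as Adam trips that stopping rule long before convergence, whereas resilient
backpropagation's near-monotone batch progress preserves its meaning. Final
network fits keep the best of three random initializations by validation
loss. The recurrent net trains by backpropagation through time over whole
windows (≤ 375 steps at 250 Hz, no truncation), with the hidden state reset
at each window start and a single delay-1 hidden-to-hidden path.

Quantization (`quantize_model()`) multiplies all real parameters by 1024
and rounds; the integer forward pass uses floor division by 1024, a ±1024
satlins clamp and a decision threshold of 512 on the purelin output. Tree
thresholds are rounded on the raw feature scale, which is exact for integer
features.

## Runtime post-processing

A single misclassified sample must not flip the prosthesis: `debounce()`
lets the output switch only after strictly more than `n_slope` equal
consecutive decisions (offline: 2, or 3 for the recurrent net; online, where
the feed-forward families decide at the full 2 kHz rate, 20 — the recurrent
net keeps 250 Hz and 3). The reading "more than `n_slope`" follows the
reference description; the "exactly `n_slope`" variant is available via
`rule = "geq"`. The envelope is delayed 100 ms so it lines up with the
(lagging) decision, and `gate_output()` either zeroes the output during
artifacts (`"off"`) or holds the last contraction-phase value (`"hold"`).
`decision_trace()` runs the whole online chain and records the per-step raw
decision, debounced decision, delayed envelope and gated output.

## Evaluation

`tolerant_accuracy()` excludes the `round(tol_ms * rate / 1000)` samples
after each target transition (100 ms during training and validation, 150 ms
on test data — matching the designed signal delay) and tallies the rest into
a confusion matrix with contraction as the positive class; accuracies are
rounded half-up to two decimals. `sweep_models()` reproduces the model ×
feature-count accuracy grid layout.

## Numerical choices and limitations

* Filters are designed by bilinear transform with pre-warping and run in
  double precision, with one rounding to integer counts at the chain output;
  the comb is integer-exact and the envelope EMA runs in fixed point. The
  bit-exact fixed-point contract covers features, envelope and models — the
  stages the parameter tables specify numerically.
* The envelope smoother uses the dyadic coefficient whose time constant is
  closest to 51 ms at 2 kHz: $b = 253/256$ (42.2 ms; the next candidate,
  254/256, lies further away at 63.5 ms).
* Feature state starts at the variant's lower bound with cleared buffers;
  start-up transients are absorbed by the transition tolerance.
* All recursion state is integer-valued and round-trips through R without
  precision loss, so chunked (streaming) and batch execution agree
  bit-exactly; this is asserted for all 26 variants.
* Test-suite problem sizes: the end-to-end check trains the 3-feature /
  4-split-capped tree and the 9-feature / 9-hidden-unit recurrent net on a
  180 s-per-class corpus (scaled down from the reference 870 s) and expects
  both to exceed 95% tolerant test accuracy with the recurrent net ahead of
  the tree, the ordering the reference results report.
* Known limitations: single channel; no amputee or multi-subject data; the
  lasso path on strongly collinear saturated features can stall below the
  requested support size (the nearest available size is used); and the
  published tree runtime/energy figures are hardware measurements outside
  the scope of a software reimplementation.
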