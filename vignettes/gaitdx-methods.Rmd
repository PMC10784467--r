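---
title: "Methods: acceleration-based gait classification in gaitdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acceleration-based gait classification in gaitdx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gaitdx)
```

## The problem

Peripheral artery disease (PAD) alters gait: strides lengthen in time,
step-to-step timing becomes more variable, and left/right asymmetry grows.
These signatures live in the body's acceleration, which can be obtained two
ways: precisely, in a laboratory, by double-differentiating the position of
a reflective sacral marker tracked by cameras at 60 Hz; or conveniently, in
the field, from a waist-worn accelerometer sampling at 100 Hz. `gaitdx`
implements a pipeline that trains diagnostic classifiers on the precise
modality and applies them to the convenient one, together with a synthetic
walking-data generator that makes every stage testable.

## From marker positions to acceleration

Displacement between consecutive position samples divided by the sampling
interval gives velocity; repeating the operation gives acceleration. The
two passes combine algebraically into the central second difference

$$a_i = (p_{i+2} - 2\,p_{i+1} + p_i)\,f^2,$$

which `derive_acceleration()` computes directly — identical arithmetic,
simpler timestamp bookkeeping: the output is aligned to the centre sample
and is two samples shorter than the input. The second difference is exact
on quadratic motion and attenuates a sinusoid of frequency $\nu$ by
$\mathrm{sinc}^2(\pi\nu/f)$ — under 0.1% at 1 Hz and 60 Hz sampling, which
is why the pipeline differentiates first and asks questions later.

Noise is then removed with a fourth-order Butterworth low-pass at 15 Hz
(`butterworth_lowpass()`). Two choices here are the package's own, since
the phase handling of the original procedure is unstated:

* **Zero-phase filtering** (a forward and a backward pass of the order-4
  design). Causal filtering would delay every gait event by a
  frequency-dependent lag and bias the timing features; zero-phase is the
  biomechanics norm. The effective amplitude response is therefore the
  *squared* one-pass magnitude — a 15 Hz tone emerges at gain 0.5, not at
  the one-pass −3 dB point. The tests assert this against the transfer
  function of the designed digital filter.
* **Filtering acceleration, not position.** The derivation lists filtering
  as the final step, so positions are differentiated raw and only the
  acceleration is smoothed.

Edges are padded by reflection (1 s, or the signal length if shorter)
before filtering; short walking bouts otherwise show large transients.
Marker dropouts are handled before differentiation: interior gaps of at
most `max_gap = 6` samples (0.1 s at 60 Hz, a typical brief occlusion) are
linearly interpolated per axis, longer gaps split the trajectory into
independently processed segments (`fill_marker_gaps()`).

Cross-modality work needs rate conversion (100 Hz wearable data against
60 Hz marker models). `resample_signal()` applies a zero-phase Butterworth
anti-alias filter at 90% of the new Nyquist frequency and interpolates at
the new sample times. A polyphase resampler was rejected because the
available implementation leaves a ~5.5-sample group delay uncompensated,
which would shift every detected event by ~55 ms.

## Gait-event detection

The vertical acceleration is transformed with a first-derivative-of-
Gaussian wavelet (`gaus1`) at a single scale (`wavelet_transform()`). With
the sign convention $\psi(u) = u\,e^{-u^2/2}$, the transform `s1` behaves
as a smoothed derivative whose local minima mark sharp upward transients —
heel strikes (initial contacts, IC). Its numerical derivative `s2` peaks at
toe-off-like events (final contacts, FC). The wavelet has zero mean, so a
constant gravity offset on the wearable's vertical axis is invisible to
detection (asserted in the tests).

Numerical choices:

* **Scale.** The working scale is 10 *defined at 60 Hz* and rescaled
  proportionally with the sampling rate (`effective = 10 · rate/60`), so
  both modalities see the same ~0.17 s physical smoothing width.
* **Peak picking.** The extrema definitions alone admit every noise
  wiggle. Candidates are filtered by topographic prominence of at least
  0.2 × SD of the respective series — an amplitude-relative threshold, so
  scaling the signal by any positive constant leaves event times unchanged
  — and by a minimum separation of 0.4 s (about half a fast stride),
  resolved greedily in order of decreasing prominence.
* **Matching.** Each IC is matched to the earliest FC after it; ICs whose
  matched stance falls outside (0.1 s, 2 s), or that have no FC before the
  next-but-one IC, are dropped as implausible. Event times are reported at
  sample resolution; no sub-sample interpolation is attempted.
* **Degenerate inputs.** A flat signal yields an empty event series (not
  an error); series shorter than twice the effective scale are refused.

Side labels are unobservable from a single sensor: the first IC is assumed
left (configurable) and sides alternate strictly (`assign_sides()`).

## Temporal gait features

From side-labeled events, `extract_cycles()` computes per-cycle step,
stride, stance and swing times by the interval definitions above;
`compute_gait_features()` aggregates them into the canonical 16-feature
vector: four per-subject means plus, for each parameter, MV (population SD
over all cycles), SV ($\sqrt{(\mathrm{Var}_L + \mathrm{Var}_R)/2}$ with
population variances per side) and SA ($|\bar{x}_L - \bar{x}_R|$).

Population (divisor $n$) rather than sample variance is used throughout:
it keeps MV and SV mutually consistent and is well defined at two cycles
per side. MV pools both sides; SA compares per-side means. All three are
invariant to relabeling which side is "first", and every feature scales
linearly with time (positive homogeneity), both asserted as properties.

Missing values in multi-bout feature tables are imputed by the subject's
own mean for that feature (`impute_gait_features()`); a feature missing in
all of a subject's rows stays missing and is reported. Wearable bouts
rarely provide enough consistent cycles for the variability features: with
fewer than 10 complete cycles per side, wearable-modality extraction emits
only the four base means (`core4`), mirroring field practice.

Canonical subsets ship with the package: `logit8` (the eight
variability/asymmetry features retained by the logistic model), `rf4` (the
top four by mean absolute Shapley value) and `core4`.

## Classifiers and evaluation

Two model families operate on the two data representations:

* **Sequence model on raw windows.** Signals are cut into non-overlapping
  100-sample windows on the chosen axes (mediolateral + vertical by
  default), each z-normalized per axis within the window. Per-window
  normalization is the minimal raw-signal analogue of feature-space
  standardization and is what lets marker-trained models see wearable
  amplitudes at all. The classifier is two stacked LSTM layers of 4 units
  and a sigmoid head, trained with Adam on binary cross-entropy. No deep
  learning framework is assumed: the LSTM and the DNN below are
  implemented natively in vectorised R, and their
  backpropagation(-through-time) is verified against finite-difference
  gradients in the test suite. The shipped preset trains one epoch with
  batch size 4; synthetic experiments override `epochs` (the preset is a
  faithful record of the tuned configuration, not a straitjacket).
* **Feature models.** Logistic regression (`glm`), a random forest of 78
  depth-1 trees with `log2` feature sampling and fractional leaf/split
  minima (via `ranger`; its classification splitrule offers gini but not
  entropy — with stumps the two select near-identical splits, and the
  remaining preset values map exactly), a polynomial SVM of degree 4 with
  C = 65 (via `e1071`; the kernel offset is set to 1 because the
  homogeneous even-degree kernel is blind to the sign of standardized
  features), and a 64-256-64-1 sigmoid DNN with dropout 0.7 and batch 44.
  The DNN's tuned epoch count was never published; the package defaults to
  100. Features are always standardized with training-set statistics,
  frozen for test and transfer.

Window probabilities aggregate to subjects by the mean, thresholded at
0.5 with ties classified as positive — the simplest calibrated rule, made
explicit because the original aggregation is unstated. Evaluation reports
carry an explicit `level` tag (`subject` or `window`) for the same reason.
Metrics use PAD as the positive class; ratios with zero denominators are
reported missing rather than zero. Splits are always subject-level
(`split_cohort()` matches exact per-label counts deterministically under a
seed), and hyperparameter search is out of scope: the presets are fixed.

Exact Shapley attribution (`shapley_rank()`) enumerates all $2^d$
coalitions, valuing a coalition as the mean prediction over a background
set with absent features marginalized. Efficiency and dummy axioms hold to
numerical precision by construction and are asserted. Enumeration is
limited to $d \le 16$.

### The seven modality paths

`run_path()` wires the combinations end to end: (1) raw marker→marker,
(2) raw marker→wearable, (3) raw wearable→wearable, (4) 16-feature
marker→marker, (5) core-4 marker→marker, (6) core-4 wearable→wearable,
(7) core-4 marker→wearable. Paths 2 and 7 are the deployment scenario —
lab-trained, field-tested.

## The synthetic walking generator

`simulate_subject()` draws side-alternating step intervals as truncated
Gaussians (floor 0.2 s) with the configured asymmetry split ± half between
sides (so the stride mean is preserved), and builds vertical acceleration
as three components: step-locked harmonics, a first-derivative-of-Gaussian
transient at each IC, and a second-derivative-of-Gaussian transient at
each FC. The transient shapes are chosen analytically so that the
detector's `s1` minimum and `s2` maximum land on the true events, and both
have zero integral, which prevents velocity drift from accumulating in
marker mode. A raised-cosine envelope starts and stops the gait inside the
recording so no spurious steps exist outside the annotated span.

Two generator conventions deserve emphasis:

* **The fundamental harmonic is phase-locked to the ICs** (phase π), as in
  real gait where the dominant step-frequency component is synchronous
  with heel strike. With ~0.17 s of wavelet smoothing, only the
  fundamental survives into `s1`/`s2`, and its own derivative extrema then
  reinforce rather than displace the transient-driven ones.
* **Stance fraction defaults to 0.15 of the stride.** A single smoothed
  sacral signal cannot localize the ipsilateral stance end (~60% of the
  stride); the `s2` maximum of a step-periodic signal naturally falls near
  the quarter-step point. The simulated FC is therefore defined as a
  within-step toe-off-like event at that location, which also keeps each
  IC's matched FC unambiguous (the earliest FC after an IC is its own).
  Stance and swing times are consequently internally consistent rather
  than physiologically scaled; stride and step timing — the quantities the
  disease signatures live in — are unaffected.

Marker mode integrates the 60 Hz-sampled acceleration twice with the
cumulative-sum phased as the exact discrete inverse of the centre-aligned
second difference, then removes sub-0.1 Hz drift (a high-pass detrend,
internal to the simulator). The round trip — positions, double difference,
15 Hz filter, compare with the true acceleration — is asserted to better
than 5% normalized RMS error excluding 0.5 s edges, and in practice sits
near 0.3%. Wearable mode samples the same waveform at 100 Hz, adds white
noise (default SD 5% of each axis' signal SD) and optionally the 1 g
gravity offset.

Group presets (`sim_preset()`) encode claudication gait: at effect size 1,
PAD-like subjects have +0.12 s stride time, 2.3× stride variability and
+15 ms step asymmetry against healthy baselines of 1.05 s, 22 ms and 5 ms,
with between-subject spreads of roughly 4% (means) and 20% (variabilities,
log-normal). Where the underlying study reports no number — the simulator
emulates data that were never deposited — values were chosen once to match
typical older-adult treadmill walking and are not revisited. The `effect`
argument scales the group differences (0 collapses them; classifier
accuracy at effect 0 is asserted to sit at chance).

**What the simulator does not emulate:** spatial gait parameters,
musculoskeletal dynamics, sensor placement artifacts, treadmill-vs-
overground differences, non-walking activity, or real mocap noise spectra
(marker noise defaults to zero; the double-differencing noise
amplification that motivates the 15 Hz filter can be studied by setting
`marker_noise_sd`, but no claim is made that its spectrum matches a
camera system). Passing tests therefore demonstrate correctness of the
pipeline's arithmetic and its behaviour under the modeled signal class,
not clinical performance on real cohorts.

## Problem sizes and numerical tolerances in the test suite

The suite runs 40-subject cohorts at 60 s per subject for the end-to-end
classification checks (five seeds at three effect levels), 28-subject
cohorts at 40 s for the raw-signal transfer comparison (three seeds,
window-level evaluation, since 10 held-out subjects quantize subject-level
accuracy in steps of 0.1), and 60 s single subjects for event-detection
and parameter-recovery checks (initial contacts matched within 40 ms;
stride mean within 2% and stride variability within 15% of configuration
on five-seed averages — the variability band absorbs the ~3% downward bias
of the population SD at ~27 cycles per side and the ~7% regularization the
wavelet smoothing imposes on detected event times). Finite-difference
gradient checks run at tolerance 1e-5 relative; Shapley axioms at 1e-10.

## Known limitations

* FC localization is method-limited: with scale-10 smoothing the `s2`
  maximum carries an inherent quarter-step attraction, so stance/swing
  timing is noisier than step/stride timing and systematically biased at
  extreme stride lengths (≳1.6 s). Features built on stance/swing remain
  usable because biases act on both groups alike.
* The logistic-regression feature elimination and Bayesian hyperparameter
  searches behind the shipped presets are not re-run; the presets are
  fixed records.
* `ranger` provides no entropy splitrule for classification; the RF preset
  substitutes gini (see above).
* Real-cohort accuracies cannot be reproduced — the clinical data are not
  public — so all quantitative claims are about simulated cohorts.
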