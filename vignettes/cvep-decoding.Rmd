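---
title: "Decoding code-modulated visual evoked potentials with spatiotemporal LCMV beamformers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding code-modulated visual evoked potentials with spatiotemporal LCMV beamformers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decoding problem

In a code-modulated visual evoked potential (cVEP) speller, every selectable
target flickers with the same pseudorandom binary luminance code, but each
target starts the code at a different circular lag. Gazing at a target
imprints that target's lagged code onto the EEG over the occipital pole, so
identifying the gazed target reduces to identifying the lag of the evoked
response. The code is an *m-sequence* — a maximal-length linear-feedback
shift-register (LFSR) sequence of period $2^d - 1$ — because its circular
autocorrelation is two-valued ($L$ at lag zero, $-1$ everywhere else),
which makes differently lagged copies nearly orthogonal and therefore
maximally distinguishable. The package ships the 63-bit code used by the
reference protocol as `CVEP_CODE63` and a generic LFSR generator plus
validators (`generate_m_sequence()`, `validate_m_sequence()`,
`circular_autocorrelation()`).

Two presentation regimes are supported, both on a 120 Hz display: the
traditional 60 Hz effective rate (each bit held for two frames, code cycle
$c = 1.05$ s, 5 repetitions per 5.25 s trial, analysis at 100 Hz) and the
full-rate 120 Hz presentation ($c = 0.525$ s, 10 repetitions, analysis at
200 Hz). The doubled analysis rate of the fast session makes segments of
both regimes 105 samples long, so the classifiers of the two sessions have
identical dimensionality. Targets are lagged in steps of two display
frames; note that on the fast session's 63-frame cycle, 32 two-frame lags
fit *because* 63 is odd — the lags $0, 2, \dots, 62$ are pairwise distinct
modulo 63. The package validates lag collisions rather than a lag-budget
inequality for exactly this reason.

## The decoder

### Segments, patterns, and the pooled covariance

After preprocessing (below), each 5.25 s epoch is cut into the maximal
number of consecutive non-overlapping segments of one code presentation
($n = \mathrm{round}(c \cdot f_s)$ samples). For target $i$, the
**activation pattern** $A_i \in \mathbb{R}^{m \times n}$ is the element-wise
mean of that target's training segments: a spatiotemporal template of the
evoked response at that target's lag. Patterns are estimated independently
per target rather than as circular shifts of a single template; shifts
introduce wrap-around discontinuities and ignore template differences
between targets, and with per-target training data there is no need for
them.

All $r$ training segments (all targets pooled) are flattened channel-major
into $E \in \mathbb{R}^{r \times mn}$, and $\Sigma = \mathrm{cov}(E)$ is the
shared spatiotemporal covariance. Flattening order is fixed everywhere
(patterns, weights, scored inputs); a silent mismatch would destroy
performance, so `unflatten_segments()` exists purely to round-trip-test it.

### LCMV weights

The linearly-constrained minimum-variance beamformer for target $i$
minimises expected output power subject to unit response to the target's
own pattern:

$$
\mathbf{w}_i = \frac{\Sigma^{+}\mathbf{a}_i}
                   {\mathbf{a}_i^{\mathsf T}\Sigma^{+}\mathbf{a}_i},
\qquad \text{s.t.}\; \mathbf{a}_i^{\mathsf T}\mathbf{w}_i = 1 ,
$$

where $\mathbf{a}_i$ is the flattened pattern and $\Sigma^{+}$ the
Moore–Penrose pseudoinverse. The pseudoinverse matters: with $m$ channels
the dimension $mn$ (3360 for the full 32-channel montage) routinely exceeds
the number of training segments, so $\Sigma$ is singular by construction.
A segment is scored by the plain weighted sum $y_i = \mathbf{s}\mathbf{w}_i$;
a segment equal to the pattern itself scores exactly 1.

Two numerical choices here:

* **Singular-value cutoff.** Singular values below
  $\max(\dim) \cdot \varepsilon \cdot \sigma_{\max}$ are zeroed — the
  conventional pseudoinverse default (`pracma::pinv`), recorded here because
  only the pseudoinverse itself, not a tolerance, is part of the method's
  definition.
* **Factored pseudoinverse.** During model fitting, $\Sigma^{+}$ is computed
  from the economy SVD of the centered segment matrix $E$
  (`covariance_pinv()`): if $E - \bar E = UDV^{\mathsf T}$ then
  $\Sigma^{+} = V (D^2/(r{-}1))^{+} V^{\mathsf T}$. This is algebraically
  identical to decomposing the $(mn) \times (mn)$ covariance (unit-tested
  against `pracma::pinv(cov(E))`) but scales with $r \times mn$, which keeps
  full-montage training tractable. One pseudoinverse is shared by all 32
  targets.

The closed form is verified in the test suite against an independent
null-space solver of the same constrained quadratic programme on random
low-dimensional instances ($mn \le 12$, agreement $\le 10^{-8}$).

### One-vs-all thresholds via ROC analysis

Each target also receives a decision threshold $\theta_i$, tuned by an
inner stratified 4-fold cross-validation over the *training* epochs: three
folds train a beamformer bank, the held-out fold's segments are scored by
it, and the held-out scores of all folds are pooled into one ROC per
target, where a segment is positive iff its cue equals that target.
Candidate thresholds are the midpoints between consecutive sorted unique
scores plus below-all/above-all sentinels; the performance metric is raw
classification accuracy of the rule $y > \theta$ (balanced accuracy is
available via `roc_metric = "balanced"` given the 1:31 class imbalance, but
raw accuracy is the default). Since many thresholds typically attain the
maximum, the *median* of the maximising candidates is selected. The
sentinels are implemented as $\min(y) - 1$ and $\max(y) + 1$ rather than
$\pm\infty$; they classify identically, and the median of maximisers stays
well-defined in the degenerate case where every candidate performs equally
(the report flags this tie).

Two points were genuinely open and are resolved as follows. The inner-fold
scores are **pooled at the segment level** rather than epoch-averaged
first: pooling yields four times as many operating points for the ROC and
matches the segment-level definition of the threshold's job. And the
covariance (with everything else) is **re-estimated inside each
cross-validation training split** — never from data the fold will be
evaluated on — which is the leakage-safe reading of an ambiguous procedure
and, if anything, slightly pessimistic.

### Epoch prediction

To classify an epoch with an `n_repetitions` budget, the first
`n_repetitions` segments are averaged, the average is filtered by all 32
beamformers, and among the targets whose score exceeds their threshold the
highest score wins. If no score exceeds its threshold the highest
sub-threshold score wins — the decoder always answers. Exact score ties
break to the lowest target id, a documented determinism rule.

## Preprocessing

The chain, in canonical order on the continuous recording
(`preprocess_recording()`):

1. **Re-reference** to the average of the mastoid channels TP9/TP10.
2. **Band-pass 4–31 Hz**, 4th-order Butterworth, applied forward and
   backward. Phase handling is not part of the method's definition; offline
   analyses conventionally use zero-phase filtering to keep template
   latencies interpretable, so the effective attenuation is the squared
   magnitude of the order-4 design. The implementation pads with odd
   reflection at both ends so the filter transients decay inside the
   padding.
3. **Epoch** into 5.25 s windows starting at each stimulation-onset marker
   (half-open sample intervals, 0-based onsets), labelled with the cued
   target.
4. **Decimate** to the analysis rate (100 or 200 Hz). Pure decimation is
   sufficient: the 31 Hz band edge is already below the 50 Hz Nyquist
   frequency of the lowest analysis rate, so no additional anti-alias
   filter is required.

No artefact rejection, ICA or channel interpolation is performed — the
pipeline deliberately stays free of data-dependent cleaning.

### The 150 ms transition exclusion

Visually evoked responses need on the order of 100–150 ms to stabilise
after stimulation onset. `extract_segments(..., exclude_initial_s = 0.150)`
therefore optionally discards the first 150 ms of every epoch before
tiling segments. The cost is asymmetric between sessions: the trailing
incomplete code presentation is lost, which removes 1 of 5 training
segments per epoch (20%) at the 60 Hz presentation but only 1 of 10 (10%)
at 120 Hz. The exclusion also lengthens every selection by 0.150 s
(a first full code then needs $0.150 + 1.05 = 1.2$ s at 60 Hz), which
`selection_time()` accounts for in the ITR.

## Evaluation

`stratified_cv()` runs the outer stratified 5-fold protocol: with 5 cues
per target, each fold holds exactly one epoch per target (epochs assigned
in recording order, deterministic). Accuracy is reported per repetition
count, alongside the information transfer rate

$$
\mathrm{ITR} = \frac{\log_2 N + p\log_2 p
               + (1-p)\log_2\!\frac{1-p}{N-1}}{t/60}
\quad \text{bits/min},
$$

with $N = 32$, $p$ the accuracy and $t$ the selection time: stimulation
time plus the exclusion (when active) plus a 0.5 s gaze-shift allowance.
The $p \to 1$ and $p \to 1/N$ limits are taken by continuity
($0\log 0 := 0$); below-chance accuracies are clamped to chance with a
warning rather than reporting negative bits — a case the protocol never
produces but a library function must define. The same stratified CV is
used both for reporting and inside `greedy_channel_selection()` (forward
selection on 2-repetition accuracy, stopping at no strict improvement or
100%; improvement ties break to the earliest-listed candidate). Using one
CV for both selection and reporting mirrors the reference procedure but is
optimistically biased — channel selection has seen the evaluation folds —
and should be read as such.

`paired_signed_rank()` wraps the two-tailed Wilcoxon signed-rank test for
paired per-subject contrasts (exact null for $\le 25$ untied nonzero
differences, normal approximation with continuity correction otherwise,
zeros dropped, all-zero differences defined as $p = 1$).

## The simulator

`simulate_session()` exists so that every stage above is testable without
recorded EEG. Per trial, the cued target's lagged code (one entry per
display frame, mapped $0 \to -1, 1 \to +1$, zero between trials) is
expanded to the acquisition rate, convolved with a biphasic
difference-of-gammas kernel (~0.25 s support, peaks near 75 and 120 ms —
any stable band-limited kernel serves the purpose; no claim of
physiological fidelity is attached to this shape), scaled to a ~5 µV
response, and projected through an occipital-dominant topography onto the
montage. Noise is EEG-like in spectrum only: $1/f^\beta$ background
(β = 1), a 10 Hz alpha sinusoid with per-channel random phase, and white
sensor noise, all per-channel. Defaults mirror the protocol: 32 targets ×
5 cues, 5.25 s stimulation, 1 s inter-trial gaps, 2000 Hz acquisition,
a 32-channel parieto-occipital montage (the label set is a package
convention — the montage of record exists only as a figure). Options add a
150 ms onset-latency ramp (`transition_s`, emulating the unstable
post-onset response) and per-target gain jitter (`target_gain_sd`, making
templates heterogeneous rather than exact circular shifts).

What the simulator does *not* model — eye movements, blinks, non-stationary
alpha, volume-conduction correlations between noise sources, electrode
drift — bounds what passing tests show: they validate the *pipeline*
(shapes, algebra, protocol arithmetic, qualitative noise behaviour), not
cohort-level decoding performance. The reported cohort numbers (median ITR
up to ~173 bits/min) depend on recorded 17-subject data and are out of
scope here.

Lags are assigned to targets in reading order of the grid
(target $i$ gets lag $2(i-1)$ frames); whether the original interface used
exactly this order is unstated, and nothing in the decoder depends on it —
it is a simulator convention.

## Problem sizes and conditions used by the test suite

The acceptance checks run on synthetic sessions at the protocol's trial
structure (32 targets × 5 cues, 5.25 s epochs, 200 Hz analysis) with
reduced montages and acquisition rates chosen as the package's own test
sizes:

* **Noise-free recovery**: 8 occipital channels at the full 2000 Hz
  acquisition rate, 160 trials; expected stratified-CV accuracy 1.0 at one
  repetition.
* **Moderate noise** (white 12 µV, alpha 40 µV, pink 40 µV against a 5 µV
  response; 4 channels at 1000 Hz): single-repetition accuracy lands
  mid-range (~0.8), leaving room to detect the repetition-averaging gain
  over 20 seeded replicates. This level was fixed by a one-off
  signal-to-noise sweep during development; the simulator *defaults*
  (3/10/10 µV) represent clean laboratory EEG and decode at ≈0.99 even
  from 6 channels.
* **Extreme noise** (200× the default amplitudes): accuracy statistically
  indistinguishable from the 1/32 chance floor.
* **Transition contrast**: 16 targets, 150 ms onset ramp, 20 seeds;
  excluding the first 150 ms should raise 1-repetition accuracy on
  average.

## Known limitations

* No SVM comparator is implemented. Instead, `stratified_cv()` accepts a
  pluggable classifier interface (a `fit(epochs, config)` /
  `predict(model, epoch, n_repetitions)` pair,
  `beamformer_classifier()` being the default), so any external
  comparator can be benchmarked under the identical evaluation protocol.
* Online/streaming operation, stimulus rendering and display timing are out
  of scope; the package is an offline analysis and simulation toolkit.
* EDF support covers the common continuous-recording subset (equal
  per-signal rates, 16-bit, EDF+C annotations); BrainVision support covers
  binary multiplexed IEEE-float/int16 files.
* With very few segments the covariance is rank-deficient and the
  beamformer leans entirely on the pseudoinverse's implicit regularisation;
  no shrinkage estimator is provided because none is part of the method's
  definition.
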