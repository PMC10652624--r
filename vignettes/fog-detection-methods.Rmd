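---
title: "Methods: real-time freezing-of-gait detection and gait metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: real-time freezing-of-gait detection and gait metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fogdetect)
```

## The problem

Freezing of gait (FOG) in Parkinson's disease is an episodic inability to
start or continue walking. Rhythmic somatosensory cueing delivered at FOG
onset can help a wearer resume walking, but closing that loop requires a
detector that runs per-sample on a battery-powered microcontroller reading a
lower-leg IMU. `fogdetect` implements that detection stack — spectral window
features, a streaming sliding-DFT feature path, a cost-weighted
random-forest classifier with leave-one-subject-out (LOSO) evaluation — plus
the gait metrics used to assess cueing (step frequency, step symmetry,
stride length, freeze counts and durations), a simulated responsive-cue
controller, and a synthetic gait generator that provides labeled test data
with exact ground truth.

## Window features

All spectral quantities are computed on 256-sample windows of each
accelerometer axis. At the default 100 Hz sampling rate a window spans about
2.56 s — long enough for a few gait cycles, short enough for responsive
cueing. The sampling rate is configurable because real devices differ (the
class of hardware this targets acquires near 82 Hz, and the published
annotated benchmark data are 64 Hz).

Six features per axis:

* **Freeze index** — the ratio of power in the freeze band (3–8 Hz, where
  FOG trembling concentrates) to power in the walking band (0.5–3 Hz, where
  locomotion concentrates). During stillness both powers are tiny and the
  raw ratio explodes, so the denominator is floored at
  `epsilon_power = 1e-8 (m/s²)²` — below any accelerometer noise floor. The
  guard caps, but does not hide, stillness: the band-power feature carries
  that information.
* **Band power** — total power over 0.5–8 Hz, the stillness disambiguator.
* **Variance** (divisor *N*), **L1 norm**, **L2 norm** of the raw window.
* **Spectral entropy** — Shannon entropy (nats) of the periodogram
  normalized over the total-band bins. The entropy variant was an open
  choice; spectral entropy was selected because it is computable from the
  same DFT bins the other features already need, which matters on an
  embedded budget. It is isolated behind its own function so a sample-
  entropy alternative could be added. An all-zero window returns the maximum
  `log(n_bins)` by convention (an empty spectrum is uninformative). Note
  that a tone that falls between DFT bin centres (e.g. 5 Hz at
  fs = 100, N = 256) leaks under the rectangular window and yields ≈ 0.6
  nats rather than ≈ 0; only on-bin tones reach near zero.

Numerical conventions, fixed once: rectangular window (the sliding-DFT
recurrence assumes no taper — that is the cost of per-sample updates);
one-sided periodogram normalized so the full-spectrum sum equals the window
mean square (Parseval, asserted to 1e-9 in the tests); band edges half-open
`[f1, f2)` so 3 Hz belongs to the freeze band and nothing is double-counted,
with the 8 Hz upper edge of the total band inclusive.

## Streaming computation

A per-sample FFT is the bottleneck for embedded deployment. Because only one
of the 256 window samples changes per acquisition cycle, the tracked DFT
coefficients are updated recursively instead:

$$X_k \leftarrow (X_k - x_{\text{oldest}} + x_{\text{new}})\,e^{2\pi i k/N}$$

for the 19 bins whose centre frequency lies in 0.5–8 Hz (at fs = 100,
N = 256). The per-sample cost is proportional to the tracked-bin count and
independent of $N \log N$; the package asserts this by operation counts, not
wall-clock, since microsecond timings are hardware-dependent. Floating-point
drift of the recursion is bounded by recomputing the coefficients by direct
DFT every 4096 samples; tests hold streaming-vs-FFT agreement to 1e-6
relative at every step of a 10,000-sample random stream, and the
batch/streaming feature paths agree window-for-window to 1e-9 relative.
`replay_equivalence()` re-checks this on any recording and flags the first
divergent window; its fault-injection hook verifies the check can actually
detect a corrupted state.

## Classifier

FOG detection is heavily imbalanced — walking time dwarfs freezing time —
and a missed freeze is far costlier than a false alarm, so the
misclassification cost of a false negative is set 10× that of a false
positive. The classifier is an ensemble of 25 cost-sensitive classification
trees, each grown on a bootstrap resample with a random feature subspace
(`mtry = floor(sqrt(p))`), depth-capped and cost-complexity pruned
(`cp = 0.001`), with the asymmetric loss carried in each tree's split and
vote decisions. Tree ensembles were chosen over margin-based learners
because evaluating 25 shallow trees fits a per-sample embedded budget.

Two configuration readings were open and are resolved as follows: the
tree-size cap of 15 is interpreted as **maximum depth** (the natural size
limit for fast binary trees; it is configurable so a leaf-count reading can
be tested), and the 10× cost is implemented through the tree **loss
matrix** (an equivalent expected-loss formulation to reweighting). The
window probability is the fraction of trees voting FOG; the default decision
threshold is 0.5.

Evaluation is **leave-one-subject-out**: all windows of one subject are held
out per fold, because adjacent windows overlap and window-level
cross-validation would leak. Sensitivity `TP/(TP+FN)` and specificity
`TN/(TN+FP)` are reported per subject and averaged; a held-out subject
without FOG windows has sensitivity flagged undefined (`NA`) and is excluded
from that average rather than zero-filled. The ROC sweeps the threshold over
the pooled held-out probabilities; AUC is the trapezoid rule. Training rows
are canonically ordered before bootstrapping so per-subject results do not
depend on how the other subjects' data were concatenated. Window-level
scoring is the primary metric; episode-level summaries are available through
`freeze_metrics()` on a prediction track.

## Gait metrics

* **Step detection**: peaks of a moving-average-smoothed gyroscope axis
  (largest-variance axis by default) above 50 deg/s, at least 0.25 s apart
  (a 240 steps/min cadence cap). The thresholds are configuration with
  stated defaults — no canonical values exist.
* **Step frequency**: strikes summed over the segment, divided by its
  duration, per minute; both sides' devices pooled.
* **Step symmetry index**: the verbal definition — "difference in timing
  between alternating steps, zero when perfectly symmetrical" — admits many
  formulas. Implemented as
  `|mean(left-initiated intervals) − mean(right-initiated intervals)| /
  mean(all intervals)`, where an interval runs from a strike to the next
  opposite-side strike. This form is dimensionless, exactly zero at perfect
  alternation, and lands in the 0–0.2 range typical of observer data.
* **Stride length**: per gait cycle (consecutive same-side strikes), the
  horizontal acceleration is integrated twice by the trapezoid rule with a
  zero-velocity update (ZUPT) at each cycle boundary: velocity is anchored
  to zero at the cycle start and the linear trend implied by the
  should-be-zero end velocity is subtracted before the second integration.
  "Correcting for velocity drift" was otherwise unspecified; ZUPT with
  linear detrend is the standard inertial dead-reckoning correction and
  removes any constant accelerometer bias exactly. For real data the
  horizontal axis is unknown, so an opt-in heuristic (`axis = "auto"`)
  subtracts a 0.1 Hz low-pass gravity estimate and takes the dominant
  remaining axis; synthetic work uses the known forward axis.
* **Freeze metrics** count episodes and cumulative freeze time (also as %
  of completion time) from either an annotated event log or a prediction
  track, merging consecutive FOG windows with a one-window gap tolerance.
* **Observer %CV**: `100·sd/mean` across observers, averaged over trials.

## Cue controller

Responsive cueing turns the vibration on after `min_consecutive_fog_windows`
(default 3) consecutive FOG predictions and off `stop_delay` (default 3 s)
after the first subsequent non-FOG prediction, provided FOG does not recur
in the meantime; continuous cueing runs from warm-up to the end of the
stream. In the original closed-loop protocol a human triggered the cue on
observing freezing and stopped it "a few seconds" after walking resumed; the
debounce rule is this package's own false-positive guard for the automated
trigger, and both parameters are configurable. The controller is strictly
causal, and its expected latency decomposes as: the window majority label
flips ~N/2 samples into an episode, plus debounce × hop samples.

## The synthetic generator

`generate_recording()` emulates exactly the statistical structure the
detector relies on: walking bouts whose acceleration is a locomotor
fundamental at the step frequency plus two harmonics with geometrically
decaying amplitude (decay 0.25, keeping ≥ 90% of 0.5–8 Hz power inside the
walking band); FOG episodes from a renewal process (Poisson onsets on
walking time, log-normal durations — positive and heavy-tailed, as no
generative FOG model is established); trembling episodes as a 3–8 Hz
oscillation and akinetic episodes as near-zero movement, mixed 0.7/0.3 and
both labeled FOG (annotation practice does not distinguish the modes);
half-sine gyroscope bursts at each foot strike; and white Gaussian sensor
noise. Defaults — 100 Hz, 10 min, 100 steps/min, walking amplitude
2 m/s², trembling 1.5 m/s² at 5 Hz, 2 episodes per walking minute lasting
8 ± 4 s, noise 0.3 m/s², gyro peaks 200 deg/s — describe a moderately
impaired walker with frequent freezing; they are plausibility choices, since
no quantitative FOG signal morphology is published for this population.

`generate_trajectory()` is the stride-length test bed: a piecewise
quintic-smoothstep displacement profile with known per-cycle strides,
differentiated analytically so double integration recovers the truth up to
quadrature error, with optional constant accelerometer bias to exercise
drift correction. The smoothstep has zero velocity at every cycle boundary,
making the ZUPT assumption exactly true. `generate_event_log()` converts
ground truth into the observer keystroke stream, with optional Gaussian
latency jitter.

What passing on synthetic data does **not** show: the generator has no
turning, posture change, gait variability across a session, festination, or
subject-specific morphology, and its class structure is much cleaner than
clinical recordings — LOSO sensitivity/specificity near 99% here, versus
80–90% reported on real annotated cohorts. Synthetic results validate the
machinery (features, streaming equivalence, cost weighting, evaluation
protocol), not clinical accuracy.

## Problem sizes and runtime

The shipped evaluation uses a 6-subject cohort of 10-minute recordings
(seeds 1–6, ~11,000 windows at hop 32, 18 features), a 50-cycle biased
trajectory for stride error, and 10,000-sample streams for the sliding-DFT
equivalence checks; the whole test suite and the acceptance script each run
in well under a minute on one CPU. Batch feature extraction uses one
`mvfft` per axis over the window matrix; training windows use hop 32 to
decorrelate overlapping windows (the training hop is not canonical and is a
documented default), while streaming uses hop 1.

## Known limitations

* The native recording format is plain CSV; the on-device binary format and
  radio protocol are out of scope.
* Only the lower-leg accelerometer channels of the benchmark dialect are
  used; channel choice beyond that is a configuration default, not a claim
  about any particular dataset.
* The stride-length "auto" horizontal-axis heuristic is a pragmatic
  gravity-subtraction rule, not a validated orientation estimator.
* Operation counts stand in for latency guarantees; wall-clock depends on
  hardware.
* Model persistence for the CLI uses RDS files; a portable JSON export of
  the tree structures is not implemented.
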