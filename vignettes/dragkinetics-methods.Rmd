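---
title: "Drag-and-drop touch kinetics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drag-and-drop touch kinetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dragkinetics)
```

## The problem

Young children playing drag-and-drop games on a tablet leave a dense motor
trace: every touch sample carries a timestamp, a screen coordinate, and a
phase (`down`, `move`, `up`). Fine-motor control differs between children
with typical development and children with developmental disabilities, so
statistics of these traces — how long a child plays, how many strokes
("lines") they draw, how much of the screen they cover, and above all how
often the per-axis velocity and acceleration of the finger reverse sign —
are candidate digital biomarkers for developmental screening.

`dragkinetics` implements the full analysis chain around that idea:

1. a line-delimited event-log model (`touchlog_io` functions),
2. a two-cohort synthetic session generator (`generate_cohorts()`),
3. kinetic feature extraction (`extract_features()`, `build_sequence_input()`),
4. a routed two-group comparison protocol (`route_and_test()`,
   `compare_all_features()`),
5. a joint-fusion 1D convolutional classifier with stratified grouped
   cross-validation (`build_model()`, `run_cv()`), and
6. Grad-CAM attribution mapped back onto touch coordinates
   (`grad_cam()`, `overlay_export()`).

Real clinical touch logs of this kind are not publicly available, so the
package treats the synthetic generator as a first-class module: every
downstream method is exercised, and its statistical behaviour verified, on
data whose ground truth is known by construction.

## The event-log model

A *stroke* is one continuous touch: a `down` event, zero or more `move`
events, and an `up` event. A tap is a two-event stroke; a drag interrupted
by an app shutdown is closed at its last event and flagged `truncated`. A
*session* is one child's play of one drag-and-drop subgame (the `second`,
`third`, or `sixth` subgame of the game's first chapter — the three
drag-and-drop games; tapping games are out of scope).

Logs are stored as JSON Lines: one `session` header record (device
geometry, label, age) followed by one `event` record per touch sample.
The format is append-friendly and order-insensitive — events are re-sorted
by timestamp at parse time, with ties broken by file order — and
`read_sessions(write_sessions(x))` is the identity. Coordinates are raw
pixels with the mobile display convention (origin top-left, y downward);
all normalization is deferred to feature extraction.

## The synthetic cohorts

Each stroke is simulated as a straight drift from a start point to a goal
point in the unit square, plus a per-axis sinusoidal micro-oscillation of
amplitude $A$ (normalized units) and frequency $r$ (cycles/s), plus
Gaussian per-sample noise, sampled at a configurable logging rate
(default 30 events/s):

$$x(t) = x_0 + (x_1 - x_0)\tfrac{t}{d} + A\sin(2\pi r t + \phi) + \epsilon_t.$$

A sinusoid at $r$ cycles/s reverses direction twice per cycle, so a stroke
of duration $d$ contributes about $2rd$ velocity sign changes per axis —
and, because the drift contributes no acceleration, the same count of
acceleration sign changes. The group contrasts reported for real cohorts
are built in through the defaults: the typical-development group oscillates
faster (3 vs 1.5 cycles/s) and plays longer, while the disability group
more often prepends an off-target "wander" stroke before the direct path
(probability 0.35 vs 0.05). Age distributions default to medians of 40 vs
72 months with IQRs of 12 and 32.5 months. Per-stroke durations are
lognormal with defaults chosen so that whole-session playtime medians land
near 7.9 s (typical) and 4.9 s (disability) for a sixth-subgame-like task.
These anchors make the synthetic world plausible; they are calibration
targets, not estimates of any real cohort.

Two numerical choices matter here:

* **Sample noise is kept small** (`noise_sd = 5e-4` normalized units).
  Second-differencing amplifies white noise by the square of the sampling
  rate, so a noise floor that looks tiny on screen can mint spurious
  acceleration sign reversals at almost every sample and drown the
  oscillation contrast the cohorts are supposed to carry. With the default
  rates the oscillatory acceleration amplitude exceeds the noise-induced
  acceleration spread several-fold in both groups.
* **One RNG substream per child**, derived from the master seed and a hash
  of the child's ID. Identical configurations are byte-identical across
  runs, and enlarging one cohort never reshuffles the other children.

`cohort_config_for_cles()` supports parameter-recovery studies: given a
target common language effect size for the acceleration sign-change count,
it solves the required oscillation-rate ratio against the duration model.
Since a session's count is approximately $2r \times (\text{total
duration})$, the CLES between groups is
$P(\log D_1 - \log D_2 > \log(r_D/r_T))$ over independent session pairs.
The total duration — a zero-truncated-Poisson number of lognormal stroke
durations — has no closed form, so the quantile of the $\log D$ difference
is evaluated by an internally seeded Monte Carlo draw (200 000 sessions),
making the calibration a deterministic function of its arguments. The
configuration it returns is symmetric between groups in everything except
the oscillation rate, which also makes it the right fixture for
sequence-ablation experiments.

What the generator does *not* model: real finger-jitter spectra (the
sinusoid is a declared stand-in), pressure/contact area, game-specific
target layouts, or learning effects across sessions. Tests that pass on
these cohorts demonstrate that the pipeline measures what it claims to
measure — not that the classifier would reach any particular performance
on clinical data.

## Kinetic features

For each axis, positions are normalized by the device dimension, velocity
is the first divided difference, and acceleration the divided difference
of velocities over velocity-midpoint times; samples sharing a timestamp are
collapsed (last sample wins) before differencing, and derivatives are
computed within strokes only — never across a finger lift. The *sign-change
count* of a series is the number of adjacent nonzero-sign reversals with
zeros transparent: the last nonzero sign carries across a stationary hold,
so a pause does not mint reversals.

The per-session feature battery:

| feature | definition |
|---|---|
| `playtime_s` | last event time − first event time |
| `line_number` | stroke count |
| `line_length_mean` | mean over strokes of path length, in screen-diagonal units |
| `release_to_touch_s` | summed gap between each `up` and the next `down` |
| `height_mean_ratio`, `height_max_ratio` | mean/max over strokes of per-stroke vertical extent / screen height |
| `width_max_ratio` | max per-stroke horizontal extent / screen width |
| `vel_sign_changes_x/y`, `acc_sign_changes_x/y` | summed per-axis sign-change counts, plus `_per_line` variants (count / stroke count) |

Region ratios are per-stroke extents aggregated over strokes (rather than
whole-session bounding boxes), and release-to-touch is the per-session sum
of inter-stroke gaps; both readings are stated here because the reporting
convention for such tables is ambiguous, and the chosen one is fixed in
the output schema. Gaps following a truncated stroke are excluded — no
true release time was observed. Sign is taken on the raw axis, not
relative to the direction of progress toward a target; the
target-relative alternative would need knowledge of the goal position,
which the log does not carry.

These definitions satisfy checkable invariants, enforced in the test
suite: exact agreement with an independent brute-force loop implementation;
invariance of all ratio features under uniform pixel rescaling; monotone
growth of sign-change counts when an oscillating stroke is appended; and
invariance of sign-change counts under time reversal of every stroke on a
uniform sampling grid. (On an uneven grid the acceleration's divided
differences change magnitude asymmetrically under reversal, so the
acceleration part of the reversal property is a fixed-rate property.)

The sequence representation for the classifier stacks seven channels per
event — normalized x and y, per-axis velocity and acceleration (zero-padded
at stroke heads so all channels share the event grid), and a
stroke-boundary indicator — over the session's concatenated strokes,
truncated or zero-padded to a fixed length `L` with an accompanying mask
(default `L = 64`, about the first two seconds of play at 30 events/s,
which retains the oscillation signature while keeping the model small).

## The comparison protocol

Every feature is compared between cohorts with the screening protocol used
in this literature: Kolmogorov–Smirnov normality screening of each group
against a normal with the group's own mean and SD; if both groups pass at
$\alpha = .05$, an F test for homoscedasticity routes to a pooled-variance
or Welch two-sided t test with Cohen's d; otherwise a two-sided
Mann–Whitney test with the common language effect size

$$\mathrm{CLES}(A, B) = \frac{\#\{a > b\} + \tfrac12\#\{a = b\}}{n_A n_B},$$

computed by full pairwise enumeration. Categorical contrasts use the
Pearson chi-square with an $\eta^2$-style effect size $\chi^2 / N$.

Decisions fixed here because the protocol leaves them open: *both* groups
must pass normality for the t route; the KS test uses estimated parameters
(the Lilliefors caveat — nominal p values are conservative — is accepted);
no multiplicity correction is applied, matching the protocol's
raw-p-plus-effect-size reporting style; Mann–Whitney uses mid-ranks, with
the exact null distribution enumerated over all group assignments of the
pooled values when $n_A + n_B \le 20$ (valid under ties) and a
tie-corrected, continuity-corrected normal approximation otherwise.
Samples smaller than 8 are routed nonparametric without testing normality.
The routed protocol's realized type-I error at $\alpha = .05$ is checked
empirically in the acceptance suite (500 null replicates, mixing normal
and lognormal nulls) against a 0.07 ceiling.

## The joint-fusion classifier

The classifier mirrors the two-input design the screening literature uses:
a *time-variant* branch — stacked 1D convolutions (ReLU, same-padding)
over the channel sequence followed by mask-aware global average pooling —
and a *time-fixed* branch carrying the kinetic feature battery plus age
and device diagonal. The branch outputs are concatenated per child and
passed through a dense ReLU head to a single sigmoid output (probability
of the disability class). The network, backpropagation, and Adam optimizer
are implemented natively in R with batched matrix operations (im2col
convolutions), keeping the package dependency-free; binary cross-entropy
loss with L2 weight decay; dropout on the dense head during training only.

Defaults (one conv block of 16 filters, kernel 5; dense width 16; dropout
0.1; learning rate 0.01; batch 32; 30 epochs; `L = 64`) are deliberately
small — the problems this package trains on are desk-scale — and every one
of them is surfaced in `model_config()`; `grid_search()` scores candidate
configurations by inner-CV mean AUROC with ties broken by parameter count
then grid order.

Evaluation is stratified 10-fold cross-validation *grouped by child*, so
no child contributes to both a training and a test split; fixed features
are standardized with training-fold statistics only (no leakage — asserted
by test); each fold trains from a fold-specific seed. The metric panel —
AUROC (mid-rank Mann–Whitney statistic, tie-aware), AUPRC (step
interpolation), and accuracy/F/precision/recall/specificity at threshold
0.5 — is aggregated as mean (SD) over folds. Separate models are intended
per subgame; `build_fused_dataset()` enforces a single subgame per
dataset. Training is single-threaded and deterministic given seeds, so
repeated runs on one machine reproduce scores bit-for-bit.

## Grad-CAM attribution

For a chosen convolutional layer (default: the last), the gradient of the
positive-class logit with respect to the layer's post-ReLU feature maps is
averaged over valid time steps to give per-channel weights $\alpha_c$; the
map is $\mathrm{ReLU}(\sum_c \alpha_c A_c)$, linearly interpolated from
the layer's time resolution to the unmasked input length, and min-max
normalized per sample to $[0, 1]$ (skipped for an all-zero map, which
stays all-zero). Masked padding steps are excluded throughout. Because the
map is normalized per sample, scaling the logit by a positive constant
leaves it unchanged — a property the tests assert, along with exact
agreement with the hand-derived closed form on a one-filter identity
network.

`overlay_export()` joins the step weights back onto pixel coordinates,
giving the per-step `(t, x, y, weight)` table used to inspect *which part
of a drag* the network keyed on, with an optional blue-to-red rendering
(high weight = red). On synthetic disability sessions whose discriminative
signal is a planted erratic "wander" stroke, a trained model's weight
concentrates on the wander steps — the package's analogue of inspecting
off-path gestures in real sessions.

## Problem sizes and limitations

The test and acceptance workloads use cohorts of up to 200 children per
group for statistical properties and 150 per group for the
cross-validation bounds, with 10-fold CV and 20–30 training epochs; these
sizes give stable estimates (seed-to-seed CLES spread about $\pm 0.02$ at
$n = 200$/group) while keeping a full run in the low tens of seconds on
one CPU.

Known limitations: the generator's jitter model is a sinusoid, not an
empirical tremor spectrum; the classifier's performance numbers on
synthetic cohorts say nothing quantitative about clinical data; sequences
are truncated to the first `L` steps rather than summarized hierarchically;
and the native-R network is suitable for desk-scale experiments, not for
large architectures or datasets.
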