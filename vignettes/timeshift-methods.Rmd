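---
title: "Models and methods behind tojshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tojshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tojshift)
```

## The scientific question

When two brief tactile stimuli are delivered in rapid succession, one to
each hand, observers often misreport which hand was stimulated first —
dramatically more often when the arms are crossed. If the misjudging
observer is then asked to point at the external location of the first
stimulus, *where* they point adjudicates between three accounts of how
touch is localized:

* **Space-to-limb reconstruction** — the first stimulus' external location
  is computed correctly, but the wrong limb is assigned to it. Prediction:
  on error trials the (wrong) response hand points at a location on the
  *correct* hand's movement path.
* **Stimulus switch** — both stimuli are localized correctly but their
  order is confused; the observer reports the second stimulus at its own
  location. Prediction: error-trial reports track the response hand's
  position at the *second* stimulus time.
* **Time reconstruction** — the observer first commits to a hand and only
  then constructs a location, by combining the (correct) first-stimulus
  time with the chosen hand's movement trajectory. Prediction: error-trial
  reports track the response hand's position at the *first* stimulus time —
  a location where no stimulus ever occurred.

Delivering the stimuli *during* a bimanual reach makes the predictions
separable, because the hands' positions change lawfully with time. The
package implements the complete analysis chain for such experiments and a
synthetic-data generator for all three accounts, so that every stage is
testable by parameter recovery.

## Localization error and its curve

For each trial the analysis projects the reported location onto the
reporting hand's movement axis (the straight line from its movement-onset
position to its movement-offset position) and subtracts the projected true
hand position at the referenced stimulus time:

$$
e \;=\; \big(\mathbf{r} - \mathbf{x}(t_{\mathrm{ref}})\big)^\top
\hat{\mathbf{u}}, \qquad
\hat{\mathbf{u}} = \frac{\mathbf{x}_{\mathrm{off}} -
\mathbf{x}_{\mathrm{on}}}{\lVert \mathbf{x}_{\mathrm{off}} -
\mathbf{x}_{\mathrm{on}} \rVert},
$$

positive in movement direction. Plotted against stimulus time relative to
movement onset, these errors form the classic movement-locked bias curve:
positive before and early in the movement, negative late and after it.
`estimate_curve()` smooths the scattered samples with a Nadaraya–Watson
moving-Gaussian average on a 1-ms grid from −200 to 600 ms,

$$
\hat{c}(g) = \frac{\sum_i K\!\left(g - t_i\right) e_i}
{\sum_i K\!\left(g - t_i\right)}, \qquad
K(d) = \exp\!\left(-\tfrac{d^2}{2\sigma_k^2}\right),
$$

with `kernel_width` $\sigma_k$ = 75 ms by default. A "75-ms Gaussian
window" could denote the SD, the FWHM, or a full width; we take it as the
SD (the convention of the prior work this estimator descends from) and
expose it as a config knob. The kernel mass reaching a grid point, in units
of one co-located sample, is reported as *support*; where support falls
below `min_support` (default 2) the curve is undefined rather than
extrapolated into data-free regions.

### The two template curves

From correct trials the analysis derives two templates: errors referenced
to the hand position at the first stimulus time ($t_1$) and, hypothetically,
at the second ($t_2 = t_1 + \mathrm{SOA}$). Both keep the *same* time
coordinate ($t_1$ relative to movement onset); only the reference position
changes. Because the $t_2$ reference lies further along the path, the
time-2 curve is displaced leftward/downward: its features occur earlier and
its movement-phase values are more negative. This is the convention under
which the error curves behave as the hypothesis predictions require; had we
instead also re-based the time axis to $t_2$, the time-2 curve would be
displaced rightward and no account's predictions would come out.

## The time-shift statistic

The statistic asks: *by how much must the incorrect trials' reference
timing be displaced for their errors to look like draws from the template
curve?* `estimate_time_shift()` scans $s$ from −300 to +300 ms in 1-ms
steps; at each $s$ it pools the template samples with the shift-adjusted
incorrect samples, fits one common moving-Gaussian curve to the pool, and
sums the squared deviations of *all* pooled samples from that common curve.
The estimate is the arg-min, ties breaking toward $|s| = 0$; cells with
fewer than `min_incorrect_trials` (default 5) incorrect trials are treated
as missing.

Two notions of "shift-adjusting" the incorrect samples are implemented:

* **`reference` (default).** Each incorrect trial's error is *re-derived*
  against its own hand's position at the displaced reference time:
  $e_i(s) = r_i - D_i(t_i - s)$, where $D_i(\cdot)$ is the trial's
  along-path position profile (clamped to the endpoints outside the
  movement) and $t_i$ is the first-stimulus time re movement onset. Sample
  times never move. The family $s \mapsto e(s)$ passes *exactly* through
  both constructions: $s = 0$ reproduces the time-1 errors and
  $s = -\mathrm{SOA}$ reproduces the time-2 errors. Consequently, for data
  generated under time reconstruction the expected estimates are $0$
  against the time-1 template and $-\mathrm{SOA}$ against the time-2
  template, with no asymptotic bias — the distribution of re-derived
  incorrect samples at the true $s$ is identical to the template's.
* **`sliding`.** The incorrect samples' time coordinates are displaced by
  $+s$ with errors untouched — the literal "slide the curve horizontally"
  reading. This variant is retained because it is the natural reading of a
  moving-window alignment and is the right tool when two conditions'
  curves are genuine time translations of one another. For the
  template-comparison problem, however, it is ill-behaved: the
  kernel-smoothed pool lets a displaced sample cloud partially fit
  *itself*, so extreme shifts spuriously lower the cost (hence the
  `min_overlap` guard, default 0.8, disallowing shifts that strand more
  than 20% of pooled samples off supported regions), and because the
  time-2 template is not a pure translation of the time-1 curve (the
  perceived-position component does not move with the reference), its
  arg-min over-shoots the SOA substantially and does not track it. Our
  simulations show the reference method recovers $-\mathrm{SOA}$ to within
  a few ms across SOAs 60–135 with per-cell SDs around 15 ms, while the
  sliding method misses by 40–150 ms with SDs several times larger; we
  therefore made the reference method the default.

With the reference method, the sign convention matches the curve picture:
negative $s$ moves the incorrect-trial curve leftward/downward (toward the
time-2 construction).

### Hypothesis signatures

Writing the estimate against the time-1 and time-2 templates as the pair
$(\hat{s}_1, \hat{s}_2)$:

* **time reconstruction** generates incorrect reports anchored at $t_1$,
  so $(\hat{s}_1, \hat{s}_2) \approx (0, -\mathrm{SOA})$ — exactly the
  pattern the empirical literature reports for human data.
* **stimulus switch** generates incorrect reports anchored at $t_2$,
  i.e. aimed one SOA *later* than the $t_1$ label. The reference-method
  statistic reads this as a reference delayed by one SOA against either
  template: $(\hat{s}_1, \hat{s}_2) \approx (-\mathrm{SOA},
  -2\,\mathrm{SOA})$ (the second component saturates somewhat short of
  $-2\,\mathrm{SOA}$ in practice because the two mismatched curve shapes
  share their tails).

A frequently stated idealization has the stimulus-switch pattern
"reversed": $(+\mathrm{SOA}, 0)$. That idealization presumes the incorrect
trials' error values can coincide with the time-2 template after a pure
time displacement. They cannot: on a stimulus-switch error trial the error
referenced to $t_1$ contains the path segment the hand covers during the
SOA (a positive bump of order peak-speed × SOA during the movement),
whereas every correct-trial-derived template contains the *negative* of
such a segment or none — no time displacement maps one onto the other.
This is a geometric fact about the error definitions, not an estimator
deficiency, and it holds for the sliding method too.
`classify_hypothesis()` therefore scores a shift pair against the
signatures consistent with the statistic that produced it (nearest in
Euclidean distance; equidistant pairs are `ambiguous`). In recovery
simulations at realistic scale the two generators separate essentially
perfectly. The space-to-limb account is not classified from shifts at all:
its diagnostic is `lateral_distance_test()`, which checks — by a sign-flip
permutation test on paired perpendicular distances — whether incorrect
reports lie nearer the correct hand's movement line than the chosen
hand's.

### Inference

The study-level question "is the mean shift zero (or equal to the SOA)?"
is answered by `bootstrap_shift_test()`: participants are resampled with
replacement, each contributing the mean of their valid per-cell shifts;
percentile confidence intervals and a two-sided bootstrap p-value are
reported. This keeps the package dependency-light and deterministic; the
exported tidy shift table equally supports external mixed-model analysis.

## The synthetic-data generator

`generate_dataset()` simulates the full two-task design:

* **Kinematics.** Both hands reach ~300 mm toward the body
  (`movement_distance`), from lateral positions ±100 mm, along
  minimum-jerk chords; crossed postures swap the lateral signs, so
  uncrossed↔crossed conditions cross mid-movement. Movement duration is
  N(500, 80²) ms truncated to (210, 990) — a realistic speeded 30-cm
  reach, safely inside the 200–1000 ms admissibility window — with onset
  latency N(250, 50) ms after the cue and small per-hand jitter (SD
  10 ms) so the hands are near- but not perfectly synchronous. With the
  50–800 ms stimulus window this timing places stimuli before, during and
  after the movement, as the design requires.
* **TOJ choice.** A logistic model
  $p(\text{correct}) = \mathrm{logit}^{-1}(\beta_0 + \beta_{\mathrm{soa}}
  \cdot \mathrm{SOA} - \beta_\times \cdot \text{crossed at } t_1)$ with
  defaults $(0.3, 0.01/\text{ms}, 1.0)$, giving ≈20% errors uncrossed and
  ≈40% crossed at SOA 110 — comfortably above the 15% error floor that
  makes incorrect-trial analysis feasible, with the posture dependence the
  crossing literature shows. This is a descriptive choice model, not a
  process model: the pipeline only needs realistic error proportions.
* **Reports.** All hypotheses share the temporal-uncertainty machinery: a
  perceived stimulus time $\hat{t} = t_{\mathrm{aim}} + \delta +
  \mathcal{N}(0, \sigma_t^2)$ evaluated on a hand's (clamped) trajectory,
  plus isotropic spatial noise $\sigma_x$. Defaults $\sigma_t = 90$ ms,
  $\delta = 0$, $\sigma_x = 6$ mm. The clamping is what produces the
  signature bias curve: early stimuli draw perceived times from before the
  onset, where the hand still rests at the start point, skewing reports
  forward; late stimuli mirror this.
* **Participant heterogeneity.** Small between-participant variation in
  mean movement duration (SD 30 ms) and choice bias (SD 0.2 log-odds),
  so participant-level resampling is meaningful.
* **Markers.** Optionally, trials are rendered as 250-Hz marker tables
  with Gaussian marker noise (SD 0.2 mm) and, if requested, random
  drop-outs, to exercise the preprocessing chain.

What the generator does *not* emulate: perceived (as opposed to physical)
arm trajectories, velocity-dependent curve asymmetries, non-Gaussian or
skewed temporal uncertainty, response-hand biases, marker occlusion
patterns that correlate with posture, and drift over the session. Passing
recovery tests therefore demonstrates that the estimator chain is correct
and well-calibrated *under the stated generative model*, not that real
data meet that model.

## Kinematic preprocessing

Raw marker tables are preprocessed per trial and hand: cubic-spline
interpolation of marker gaps (failing, and excluding the trial, when a gap
reaches `max_gap` = 50 ms or touches either end of the recording); spline
resampling to 1000 Hz; zero-phase (forward–backward) second-order
Butterworth low-pass at 6 Hz with reflection padding, so onsets are not
delayed by filter lag; movement onset/offset at the first/last crossing of
a 5 cm/s resultant-velocity threshold (offset searched after the velocity
peak), with central-difference velocities; and the postural change of
crossing reaches as the linearly interpolated sign change of
$x_{\mathrm{left}} - x_{\mathrm{right}}$. "Smooth, continuous" is
operationalized as a single suprathreshold velocity episode (bursts
separated by >200 ms fail); "synchronous" as onset difference ≤
`sync_tolerance` = 150 ms. Every trial receives exactly one label from
{valid, interpolation, response, duration, asynchrony, smoothness} —
finger-lift response detection is hardware-bound and is not
re-implemented; the `response` rule fires on a missing reported location.

For simulated data the generator's ground-truth annotations can be used
directly (`preprocess = "annotations"`), which is how the large recovery
studies run; the preprocessing chain is exercised by its own unit tests
and by small end-to-end runs, where detected onsets, offsets and crossing
times match the generator's ground truth to within a few ms.

## Movement-phase binning

TOJ accuracy is tabulated across four phases of the bimanual movement:
before movement, during start posture, during end posture, after movement.
The movement interval is the mean of the two hands' onsets/offsets (the
hands are near-synchronous by the exclusion rule); no-change conditions
split the interval at its temporal midpoint, change conditions at the
postural change. Boundary ties resolve to the later phase — an arbitrary
rule, fixed and documented. Proportions come with Wilson score intervals.

## Numerical choices and degenerate inputs

* Units are mm and ms everywhere; x is lateral (rightward positive), y
  along the table with the movement direction toward the body.
* The shift grid (−300…300 × 1 ms) and curve grid (−200…600 × 1 ms) are
  exact; no interpolation of the cost minimum is performed.
* Cost ties within a relative 10⁻¹² of the minimum are treated as exact
  ties and resolved toward the smallest |s| — conservative toward the
  null.
* A zero-length movement axis, an empty sample set, an unknown hypothesis
  label, and a posture-change trial without a crossing time raise typed
  conditions (`tojshift_degenerate_axis`, `tojshift_no_data`, …) rather
  than propagating NaNs.
* With all noise terms at zero and forced-correct choices, every error is
  exactly 0 and every defined curve value is exactly 0 — a regression
  anchor for the whole chain.
* Re-derivation evaluates the along-path position with the minimum-jerk
  profile between the detected onset/offset positions. For real data whose
  paths deviate strongly from that family, the `sliding` method — which
  needs no path model — is the fallback, with the caveats above.

## Problem sizes

The recovery studies run at the scale of the designs they emulate: the
four-posture design with 12 participants × 4 conditions × 300 trials
(SOA 110 ms), and the SOA-sweep design with 18 participants × 2 postures ×
4 SOAs × 224 trials. At these sizes the participant-mean shift against the
time-1 template recovers 0 within ±5 ms and the time-2 shift recovers
−SOA within ≈10% (slightly shrunk toward zero, as kernel-smoothed
alignment of noisy, nonlinear curves is expected to be), with seed-to-seed
variation of a few ms. Classification of the generating account is correct
in every seeded replicate we run.

## Known limitations

* The re-derivation path model is minimum-jerk; strongly curved or
  double-peaked real reaches violate it.
* The statistic compares *pooled* samples to one common curve; it does not
  model per-trial error correlation (one trial contributes one sample, so
  this matters only across cells).
* The bootstrap treats cells within a participant as exchangeable
  replicates of that participant's shift.
* The stimulus-switch account's shift signature is statistic-dependent
  (see above); cross-study comparison of raw signature values requires
  knowing which alignment notion was used.
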