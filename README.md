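# tojshift

Analysis pipeline and synthetic-data generator for tactile temporal-order
judgment (TOJ) experiments during bimanual movement — for sensorimotor and
psychophysics researchers who ask not only *which hand* an observer believes
was touched first, but *where in space* they localize that touch.

## The problem and the statistic

Two brief tactile stimuli, one per hand, are delivered at a short stimulus
onset asynchrony (SOA) while both hands reach ~30 cm toward the body from
uncrossed or crossed postures. The observer then points, with the hand they
believe was stimulated first, at the first stimulus' external location.
Because the hands move, the reported location is informative about *which
time point* the observer's localization used. Three accounts of
hand-assignment errors make distinct predictions: reports on the correct
hand's path (**space-to-limb reconstruction**), reports at the chosen
hand's position at the second stimulus time (**stimulus switch**), or
reports at the chosen hand's position at the *first* stimulus time — a
location where no stimulus ever occurred (**time reconstruction**).

The package's core is a time-shift curve-alignment statistic. Signed
localization errors

*e* = (**r** − **x**(t_ref))ᵀ **û**

(report minus true hand position at the referenced stimulus time, projected
on the hand's movement axis **û**, positive in movement direction) are
smoothed into localization-error curves with a moving Gaussian kernel
(SD 75 ms, grid −200…600 ms). Correct trials yield two template curves —
errors referenced to the first (t₁) or second (t₂) stimulus time. For the
incorrect trials, `estimate_time_shift()` finds the reference displacement
*s* ∈ [−300, 300] ms that minimizes the summed squared deviations of all
pooled samples around one common curve; *s* = 0 reproduces the time-1
construction, *s* = −SOA the time-2 construction. Under time reconstruction
the expected pair of shifts is (0, −SOA); recovered shift pairs classify the
generating account, and a space-to-limb diagnostic tests whether
incorrect-trial reports hug the correct hand's path.

Also included: a generative simulator for all three accounts (minimum-jerk
bimanual kinematics, logistic TOJ choice model with a crossing penalty,
temporal-uncertainty localization reports), motion-capture preprocessing
(spline gap interpolation, zero-phase 6-Hz Butterworth filtering, 5-cm/s
velocity-threshold movement bounds, trial exclusion rules), TOJ scoring
with movement-phase binning and Wilson intervals, and a participant-level
bootstrap for the mean shift.

## Worked example

```r
library(tojshift)

cfg <- sim_config(n_participants = 6, trials_per_condition = 150, seed = 42)
dat <- generate_dataset(cfg, include_trajectories = FALSE)
res <- run_pipeline(dataset = dat, preprocess = "annotations")

res$manifest$n_trials_valid        # 3600
res$shift_tests$time1$mean_shift   #   4.8 ms, CI [-5.4, 16.7], p = 0.48
res$shift_tests$time2$mean_shift   # -97.8 ms, CI [-111.5, -87.8], p < 1e-3
res$classification                 # "time_reconstruction"
```

The shift against the time-1 template is statistically indistinguishable
from zero while the shift against the time-2 template is close to −SOA
(−110 ms here, mildly shrunk toward zero by the kernel smoothing): the
incorrect-trial reports used the chosen hand's position at the *first*
stimulus time. TOJ accuracy shows the crossing effect the choice model
builds in — e.g. during the start posture, pooled proportion correct is
0.83 for uncrossed-uncrossed vs 0.62 for crossed-crossed movements:

```r
summarize_toj(res$trials)
plot_localization_curves(res$curves)   # the three curves per condition
```

A thin CLI wraps the same functions
(`exec/tojshift simulate|preprocess|score|curves|timeshift|report|run-all`).

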