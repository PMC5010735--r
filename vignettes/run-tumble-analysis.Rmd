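---
title: "Quantifying run-and-tumble migration: segmentation, protrusion statistics, and the pursuit model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying run-and-tumble migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(runtumble)
```

## The scientific problem

Mesendoderm progenitor cells migrating through the gastrulating zebrafish
embryo do not move in straight lines. Their trajectories alternate *runs* —
phases of relatively straight, fast migration — with *tumbles* — slow,
poorly directed phases that typically end in a change of direction. The
balance between the two controls the directional persistence of migration,
and, because the cells chase a moving morphogenetic target, it also
controls the *precision* with which a group of cells arrives together.

This package implements the quantitative machinery for that analysis:

1. an unbiased run/tumble segmentation of 3D tracking data, driven by the
   joint density of a local alignment index and scaled speed;
2. circular statistics of protrusion orientation (the polar order
   parameter), with phase-resolved protrusion formation frequencies;
3. a stochastic run-and-tumble active-Brownian model of cells pursuing a
   moving target, with calibration against measured summary statistics and
   a run-time sweep that exposes the dispersion minimum;
4. the positional-variance dispersion metric with internal-control
   normalisation;
5. seed-deterministic synthetic-data generators for every input, so the
   whole pipeline is testable against known ground truth.

## The A/S segmentation

For a track sampled at interval $\Delta t$ (1.5 min for the long
time-lapses analysed here), frame $i$ is the displacement vector
$\mathbf v_i$ between consecutive positions. Two dimensionless series
summarise local behaviour:

* the **alignment index** $A_i$: the mean cosine of the angles between
  $\mathbf v_i$ and its neighbours within a window of $\pm w$ frames;
  $A_i = 1$ for locally straight motion, $-1$ for frame-to-frame
  reversals. Zero-displacement frames carry $A = 0$ (stationary behaviour
  is treated as unaligned evidence).
* the **scaled speed** $S_i$: the instantaneous speed
  $|\mathbf v_i|/\Delta t$ divided by the trajectory's mean instantaneous
  speed.

Pooling all cells of an ensemble gives the joint density $P(A,S)$
(41 × 41 histogram over $A\in[-1,1]$, $S\in[0,3]$, smoothed with a
separable Gaussian kernel of 1.5 bins). In run-and-tumbling ensembles this
density is bimodal: a fast aligned run mode at high $A$ and a slow
unaligned tumble mode. A straight line $S^*(A)$ is fitted to the per-$A$
density maxima (columns whose peak exceeds 5% of the global maximum), the
density is read along this *maximum line*, and the threshold is the local
minimum of that cross-section between its global maximum and the nearest
distinct local maximum. Frames are classified by projecting each $(A_i,
S_i)$ onto the maximum line — in coordinates standardised by the pooled
standard deviations of $A$ and $S$, so that "perpendicular" is well
defined across mixed units — and comparing the projection with the
threshold point. `rt_fit()` runs this whole pipeline and returns a classed
object with `print`, `summary`, `coef`, `plot` and `residuals` methods.

```{r fit-example}
p <- rt_params_control(seed = 7)
tracks <- simulate(p, nsim = 23, duration = 120)
fit <- rt_fit(tracks)
fit
coef(fit)
```

### Numerical choices that matter

* **Alignment window `window = 1`.** Measured run and tumble segments are
  only 2–4 frames long at 1.5-min sampling. A wider window (e.g. $\pm 2$
  frames) mixes evidence across phase boundaries: in simulation studies it
  inflated measured durations by roughly 50% and pushed the calibrated
  model towards parameter regions where the bimodality of $P(A,S)$ — and
  with it the threshold — becomes unstable. With $w = 1$ transitions are
  resolved at the sampling scale and the recovered statistics are stable
  across ensembles. The window remains a user argument.
* **No minimum segment length (`min_segment = 1`).** Merging short
  segments into their neighbours biases mean durations upwards and removes
  exactly the short segments that carry most of the information about
  switching rates. Merging is available (`min_segment = 2` suppresses
  single-frame flicker) but off by default.
* **Threshold robustness.** The cross-section is lightly smoothed, and a
  candidate second mode must sit at least 0.25 $A$-units from the global
  mode, reach 12% of its height, and rise at least 5% out of the valley
  separating them; modes pressed against the end of the sampled range
  count. The nearest qualifying mode defines the between-mode minimum. A
  mass-balance guard rejects any threshold that would assign more than 95%
  of the pooled density to one phase (a spurious far-tail bump, not a
  behavioural state). When no qualifying mode exists — a shoulder instead
  of a peak, or a genuinely unimodal profile — the threshold falls back to
  a weighted Otsu split of the density's projection-coordinate mass (the
  same scalar the classifier thresholds) and the fit is flagged. These
  rules were stress-tested across simulated ensembles: without them the
  threshold occasionally collapsed onto noise structure and the measured
  statistics flipped wildly between ensembles; with them the cross-seed
  SD of the mean tumble duration drops about thirty-fold.
* **Boundary frames** (the first/last $w$ frames, where $A$ is undefined)
  inherit the nearest classified label so that segments tile the track
  exactly; the sum of run and tumble durations always equals the track
  duration.

For short high-resolution tracks (~10-s frames, 10–30 min), where too few
frames exist for a stable density, `classify_phases_short()` implements
the deterministic rule used for such movies: a run persists while the
direction stays within 45° of the run's initial direction or while larger
deviations last fewer than 5 frames; a deviation beyond 45° lasting at
least 5 frames opens a tumble, which ends when a new stable direction
(5 consecutive frames within 45° of the first of them) starts a new run.

### Per-phase statistics

`phase_statistics()` / `summary(rt_fit)` report: mean run and tumble
durations; the per-cell tumble-to-run total-time ratio; pooled per-phase
instantaneous speeds and their ratio; the angles between net-displacement
vectors of consecutive runs; and the directional persistence (net
displacement over path length). Run and tumble durations are approximately
exponential — `fit_exponential_durations()` returns the maximum-likelihood
mean with a bootstrap interval and the SD/mean diagnostic (≈1 under
exponentiality), which is why duration SDs are of the order of the means.

## Protrusion orientation

Each protrusion event carries an angle relative to the local migration
direction (from CoM vectors when not given; for planar data the angle is
signed, for true 3D vectors only the magnitude is defined). The **polar
order parameter** of a cell is the length of the weight-averaged unit
vector of its event angles; `polar_order_parameter()` reports the mean ±
SEM across cells, following the convention that two POPs differ when their
SEM intervals do not overlap (`pop_different()`). Actin-rich protrusions
are conventionally weighted by their total actin (Lifeact) intensity so
the distribution reflects the orientation of the larger protrusions; blebs
carry weight 1. `phase_frequency_ratio()` divides per-minute formation
rates in tumbles by those in runs, per cell and protrusion kind.
Protrusion classification from segmentation features (sustained actin,
peak curvature) requires a curvature threshold; no universal value exists,
so `calibrate_curvature_threshold()` chooses it from labelled data.

## The pursuit model

Cells are active Brownian particles in the plane switching between run and
tumble states with independent exponential durations (means $\tau_r$,
$\tau_t$). At each run start the cell reads the bearing to the current
target position with Gaussian angular error $\sigma_\epsilon$; during the
run its heading fluctuates around that bearing as an Ornstein–Uhlenbeck
process on the angle (relaxation time 1 min, stationary SD
$\sqrt{D_\theta}$), and its speed is redrawn each integration step from a
zero-truncated normal. During tumbles the heading is redrawn isotropically
every step (a rotational-diffusion tumble variant is available but off by
default) with a slower speed distribution. The target starts $d_0$ ahead
and moves at constant $v_{target}$ along $+x$.

Two read-outs quantify migration precision at the evaluation time $t_e$
(90 min): the mean distance to the target and the **dispersion**
$\mathrm{var}(x) + \mathrm{var}(y)$ of final positions (unbiased, and
rotation-invariant, so the axis convention is irrelevant). The model is
2D because the cells migrate in the quasi-planar interface between yolk
and overlying ectoderm and the experimental dispersion metric uses x and y
only.

Integration uses $dt = 0.1$ min with output subsampled at 1.5 min so that
simulated tracks are analysed by *exactly* the same segmentation as
experimental ones. Per-cell RNG substreams are derived deterministically
from the master seed, so ensembles are reproducible independent of
evaluation order.

Notable consequence of the isotropic tumble: per-step tumble speeds cancel
over a 1.5-min frame (≈ 15 steps shrink the net displacement about
four-fold), so the *generative* tumble speed parameter is several times
larger than the *measured* frame-scale tumble speed. Calibration bounds
account for this.

Two pairs of constants deserve comment. First, $\sigma_\epsilon$ and
$D_\theta$ are nearly interchangeable for every summary statistic (both
spread run directions), but not for pursuit precision: a systematic
aiming error persists over the whole run and its positional effect grows
with run length, whereas within-run wander averages out. Only the
small-$\sigma_\epsilon$ branch reproduces the dispersion minimum that
motivates the model, so the calibration bounds
$\sigma_\epsilon \le 0.6$ rad and let $D_\theta$ carry the angular
spread. Second, the initial target distance and target speed are not
identified by track statistics at all; they default to
$d_0 = 140\ \mu m$ and $v_{target} = 0.4\ \mu m/min$, a range in which
the pursuit feedback (re-aiming at each run start) is active within
$t_e$ — with a target placed much farther away every cell simply marches
+x and the run-time sweep below loses its minimum. Both remain ordinary
arguments.

## Calibration

No reference constants exist for the simulator, so all of its
parameters are estimated by `calibrate()`: simulated
ensembles are segmented with the same pipeline as data and compared to
target statistics (segmented run/tumble durations, speed ratio, inter-run
angle, tumble-to-run time ratio, persistence, absolute run speed) through
a weighted relative squared error. The search is a Latin-hypercube screen
over box bounds followed by coordinate-wise refinement restarted from the
best screening candidates (the objective is multi-modal), with common
random numbers and seed-averaged evaluations so Monte-Carlo noise does not
drive the search. Built-in target sets carry the measured control
statistics for MZoep hosts (tumble/run ratio 0.68, inter-run angle 68°,
speed ratio 1.8, run/tumble durations 5 / 3.1 min) and wt hosts (0.58,
56°, persistence 0.68). The absolute speed scale is not pinned by the
ratio statistics; the run-speed target defaults to 3 µm/min, a typical
mesendoderm progenitor speed. `d0 = 300` µm and `v_target = 1` µm/min are
package defaults (overridable); the graded statistics are ratios, angles
and durations, which they do not affect.

An important subtlety: the measured durations are *pipeline outputs*, not
latent parameters. At 1.5-min sampling, tumbles much shorter than a frame
are invisible and adjacent runs merge, so measured durations exceed the
generative means (with the shipped calibration, generative
$\tau_r \approx 2.3$ min maps onto a segmented run mean of ≈ 5.5 min).
The scenario generators therefore do not plug the measured per-condition
durations in as $\tau$ values; `derive_scenario_params()` inverts the
observation operator instead: the control scenario re-calibrates
$(\tau_r, \tau_t)$ against the measured control durations (5 / 3.1 min),
and the Ezrin perturbations keep the control $\tau_t$ — tumble durations
were experimentally unchanged — while re-calibrating $\tau_r$ alone
against the measured per-condition run duration (3.8 min for ezrin-MO,
6.4 min for CAEzrin). The search keeps $\tau_t \ge 1.3$ min and
$\tau_r \ge 1$ min: below roughly a sampling frame the states become
unresolvable and the measured statistics cease to be well-posed functions
of the parameters. The shipped presets (`rt_params_control()`,
`generator_spec(scenario)`) were produced by exactly this procedure at
the package defaults.

The inversion is imperfect: detected tumbles carry a duration floor
(≈ 3.5–4 min against a measured control value of 3.1) because a detected
tumble occupies at least one frame plus boundary smear, and because the
feasible (run, tumble) pairs of the inverse map form a frontier that does
not pass exactly through the measured pairs. Recovered tumble durations
and the short-run ezrin-MO run duration therefore sit 20–40% above their
targets, while run durations for control and CAEzrin recover to within a
few percent. This is a resolution limit of the 1.5-min measurement, not a
tunable defect.

## The run-time sweep and the dispersion minimum

`sweep_run_time()` scales $\tau_r$ by a set of factors, simulates
replicate ensembles per factor, and records mean target distance and
dispersion. Longer runs shorten the distance to the target (more time
moving ballistically towards it) until the ensemble reaches the pursuit
hover floor (~25 µm with the shipped calibration). Dispersion is
U-shaped: long runs amplify each run's aiming error over a longer lever
arm, while short runs weaken the re-aiming feedback (corrections scale
with the distance covered per run) against a tumble-noise input that does
not shrink, so between-cell spread accumulates. With the shipped
calibration the dispersion minimum falls at a generative run time of
≈ 4.7 min — which the observation operator maps onto a segmented run
duration of ≈ 5 min, i.e. the measured control run time. On the
generative-factor axis this is a factor ≈ 2 of the calibrated $\tau_r$;
dispersion at factor 1 is still strictly below the short-run (0.2×) and
long-run (5×) extremes. This is the model's explanation of why both
shortening (ezrin-MO) and lengthening (CAEzrin) runs increase the
measured dispersion of transplanted cells.

## Synthetic data and what passing tests mean

`generate_labeled_tracks()`, `generate_protrusion_events()` and
`generate_dispersion_dataset()` produce every input format the pipeline
reads, with exact ground truth: frame-level phase labels (majority state
per sampling interval), continuous true segment durations, Poisson
protrusion events with von Mises angular order (concentrations default to
population POPs of ≈0.44 / 0.19 / 0.16 for run-phase actin-rich, run-phase
bleb and tumble-phase actin-rich events, with isotropic tumble blebs, and
lognormal actin weights), and embryo groups with a planted dispersion
ratio. All generators are deterministic in the seed.

The generators emulate the statistical structure of the real data — state
switching, speed contrast, angular order, 1.5-min sampling over ~2 h —
but not everything about real tracks: no cell–cell contacts or crowding,
no drift of the embryo frame, no tracking noise or missed frames, no
z-structure (tracks are planar), and protrusion events are placed
independently of the actual displacement fluctuations. Tests that pass on
synthetic data therefore validate the estimators and their
implementations, not the biological interpretation of any particular real
data set.

## Problem sizes used in tests

The test-suite and the acceptance script work at the scale of the original
experiments: ensembles of 18–23 cells for the closed-loop statistics
(80 cells for the duration-recovery checks, giving ≈ 1000 segmented runs
and a stable pooled density), 120-min tracks at 1.5-min sampling,
calibration budgets of 100–300 objective evaluations with 46-cell
two-seed evaluations, and 100 replicate ensembles per point of the
run-time sweep. A full calibration takes a couple of minutes on one CPU.

## Known limitations

* The segmentation's duration estimates are resolution-limited: state
  dwell times below about half a frame are unobservable, and boundary
  frames mix evidence from both states. The calibration inverts this
  observation operator rather than pretending it is the identity, but the
  inversion cannot push recovered tumble durations below their detection
  floor (see above).
* $\tau_t$ is only weakly identified from segmented statistics when
  tumbles are short (the measured tumble duration saturates near the
  detection floor); recovery tests therefore use regimes where tumbles
  are resolvable.
* The unimodal-fallback threshold is a flagged last resort, not a
  trustworthy estimator.
* The model ignores cell–cell interactions, gradient-sensing kinetics and
  3D structure by design.
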