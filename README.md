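# runtumble

Quantitative analysis of run-and-tumble cell migration from 3D tracking
data, built around the migration of zebrafish mesendoderm progenitors:
cells that alternate persistent *runs* with reorienting *tumbles* while
chasing a moving morphogenetic target. The package is for cell biologists
and biophysicists who track single cells in vivo and want to (i) segment
trajectories into runs and tumbles without hand-set thresholds, (ii)
relate protrusion formation (blebs vs actin-rich protrusions) to those
phases, and (iii) ask, with a calibrated stochastic model, how the
tumbling-to-running balance controls the precision of collective arrival.

## The method in brief

For each trajectory frame the **alignment index** `A ∈ [−1, 1]` (mean
cosine between a displacement vector and its ±w-frame neighbours) and the
**scaled speed** `S` (instantaneous speed over the trajectory mean) are
computed. The pooled joint density `P(A, S)` of an ensemble is bimodal; a
line `S*(A)` fitted to its per-`A` maxima and the local minimum of the
density along that line define an unbiased threshold. Frames projecting
beyond the threshold (perpendicular in standardised coordinates) are runs,
the rest tumbles. Per-phase statistics follow: run/tumble durations
(approximately exponential), the tumble-to-run total-time ratio, per-phase
speeds, angles between consecutive runs, and the directional persistence
(net displacement / path length).

Protrusion orientation is summarised by the **polar order parameter**
`POP = |Σ w_i û(θ_i)| / Σ w_i` per cell (1 = perfectly focused, 0 =
isotropic), reported mean ± SEM across cells.

Cells are modelled as 2D run-and-tumble active Brownian particles pursuing
a target moving at constant speed: at each run start the heading is set to
the perceived target bearing (Gaussian error σ_ε), fluctuates as an
Ornstein–Uhlenbeck process during the run, and randomises during tumbles;
run/tumble durations are exponential with means τ_r, τ_t. `calibrate()`
fits the parameters so that *simulated tracks segmented exactly like data*
reproduce measured summary statistics, and `sweep_run_time()` scans τ_r to
show that the positional dispersion `var(x) + var(y)` of the ensemble is
minimal near the measured run time.

## Worked example

Simulate a control-like ensemble at the experimental scale (23 cells,
2 h at 1.5-min sampling), segment it blind, and read the summary:

```r
library(runtumble)
p <- rt_params_control(seed = 7)     # shipped control calibration
tracks <- simulate(p, nsim = 23, duration = 120)
fit <- rt_fit(tracks)
summary(fit)
#> Ensemble summary ( 23 cells )
#>   runs: 263 segments, mean duration 6.47 min
#>   tumbles: 263 segments, mean duration 4.02 min
#>   tumble/run time ratio: 0.635 +/- 0.155 (mean +/- SD)
#>   run speed 3.30, tumble speed 2.08 um/min (ratio 1.59)
#>   mean inter-run angle: 69.8 deg
#>   persistence: 0.529 +/- 0.031
#>   threshold_A = 0.215
```

Mean run and tumble durations (min), the tumble/run time ratio, the
per-phase speed ratio, and the inter-run reorientation angle (degrees) are
the statistics used to compare conditions; `plot(fit)` draws `P(A,S)` with
the maximum line, threshold and cross-section. Protrusion statistics and
the dispersion metric work the same way from event tables and endpoint
tables (`polar_order_parameter()`, `phase_frequency_ratio()`,
`normalized_dispersion()`); every input can be generated with known ground
truth by the `generate_*()` functions.

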