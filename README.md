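# divekin

Kinematic and kinetic analysis of soccer goalkeepers' penalty diving
saves, for sports biomechanists and movement scientists.

When a goalkeeper dives for a penalty, performance is summarised by how
far and how fast the centre of mass (CM) travels from the countermovement
bottom to the flight apex, and by the weight-normalised force and impulse
the push-off leg exerts on a force plate.  `divekin` turns raw CM
trajectories (nominally 400 Hz) and ground-reaction forces (nominally
2000 Hz, independent clock) into 14 outcome variables and runs the paired
comparisons of interest: old vs new goalkeeper feet-positioning rule,
dominant vs non-dominant dive side, and rule within each side.

The core quantities, with axes x (mediolateral), y (anteroposterior),
z (vertical) and the dive window `[argmin z(t), argmax z(t)]`:

- displacements `VD, MLD, APD` (m), resultant `RD = sqrt(VD² + MLD² + APD²)`;
- `AV = RD / Δt` and peak resultant speed `PV = max ‖dr/dt‖` (m/s);
- peak forces `VPF, MLPF, APPF, RPF = max ‖F‖ / mg` (×BW) and trapezoidal
  impulses `VI, MLI, API, RI = ∫‖F‖ dt / mg` (×BW·s) over the push-off
  phase (onset at the last upward crossing of 1.05 mg before the force
  peak, foot-off below 10 N).

Signals are conditioned with a fourth-order zero-lag Butterworth filter
whose cutoff is chosen per trial by Winter-style residual analysis (or
forced, e.g. to the conventional 10 Hz).  Statistics are Shapiro–Wilk
checks, Student's paired t-tests on per-subject condition means, and
pooled-SD Cohen's d.

Because real motion-capture data cannot be regenerated at desk scale, the
package includes a mechanistic synthetic-dive generator: a C1 piecewise CM
model (stance → countermovement → push-off → ballistic flight) whose
ground-reaction force satisfies `F = m(a + g ẑ)` during contact and
vanishes exactly at takeoff, sampled on the two instrument clocks with
Gaussian noise — with every outcome variable computed analytically from
the continuous model as ground truth for recovery testing.

## Worked example

```r
library(divekin)

# one new-rule dive with measurement noise, plus its exact ground truth
sim <- simulate_dive(sim_params(rule = "new", side = "right", seed = 42))
res <- process_trial(sim$trial, filter = filter_config(cutoff_hz = 10))
sprintf("RD = %.3f m (truth %.3f), AV = %.2f m/s, PV = %.2f m/s, VPF = %.2f xBW",
        res$RD, sim$truth$RD, res$AV, res$PV, res$VPF)
#> "RD = 1.584 m (truth 1.576), AV = 3.18 m/s, PV = 3.82 m/s, VPF = 1.92 xBW"
```

The recovered resultant displacement is within 0.5 % of the generator's
analytic truth; the dive covers ~1.6 m at an average 3.2 m/s with a peak
CM speed of 3.8 m/s and a vertical peak force of 1.9 body weights —
typical values for a high-corner penalty dive.

A full study, end to end:

```r
run <- run_pipeline(list(seed = 1, filter = list(cutoff_hz = 10)))
nrow(run$results)   # 120 trials: 6 subjects x 5 per rule-by-side cell
#> [1] 120
subset(run$report, design == "rule" & variable == "APD",
       c(mean_a, mean_b, t, p, cohens_d, significant))
```

The report has 56 rows (14 variables × 4 designs); with the generator's
default frontal-step effect the anteroposterior displacement is larger
under the new rule (negative t for OR − NR, p ≪ 0.05) — goalkeepers dive
farther and faster when allowed to project a foot forward.

The same pipeline is scriptable from the shell:

```sh
Rscript inst/cli/divekin simulate --out trials/ --seed 1
Rscript inst/cli/divekin process  --in trials/ --out results.csv --cutoff 10
Rscript inst/cli/divekin stats    --in results.csv --out report.csv
```

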