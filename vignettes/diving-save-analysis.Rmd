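---
title: "Goalkeeper diving-save kinematics: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Goalkeeper diving-save kinematics: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divekin)
```

## The problem

When a goalkeeper dives to save a penalty, the quality of the dive can be
summarised by how far and how fast the centre of mass (CM) travels between
the lowest point of the preparatory countermovement and the highest point
of the flight, and by how much force and impulse the push-off leg exerts on
the ground.  Since 2019 the goalkeeper may keep only one foot on the goal
line when the ball is struck (the "new rule", NR), instead of both (the
"old rule", OR); the frontal foot projection this allows changes the
push-off mechanics.  A second question is laterality: whether dives toward
the dominant-leg side (DLL) differ from dives toward the non-dominant side
(NDLL).

`divekin` implements the full measurement chain for this question as a
reusable, tested pipeline: multirate signal conditioning, event detection,
14 outcome variables, and the three paired comparisons (rule, laterality,
rule within side).  Because laboratory motion-capture data cannot be
redistributed or regenerated at desk scale, the package ships a
*mechanistic synthetic-dive generator* whose exact ground truth makes every
downstream stage falsifiable.

## The 14 outcome variables

With axes x (transversal/mediolateral), y (sagittal/anteroposterior),
z (longitudinal/vertical), and the *dive window* running from the global
minimum of CM z (countermovement bottom) to its global maximum (flight
apex):

* **VD, MLD, APD** — absolute per-axis CM displacement across the window (m);
* **RD** = sqrt(VD^2 + MLD^2 + APD^2) (m);
* **AV** = RD / window duration (m/s);
* **PV** — maximum instantaneous resultant CM speed inside the window (m/s);
* **VPF, MLPF, APPF** — per-axis peak |F| within the push-off phase,
  normalised by body weight m g (xBW); **RPF** — peak of the sample-wise
  force-vector magnitude (xBW);
* **VI, MLI, API** — trapezoidal integrals of per-axis |F| over the
  push-off phase, / m g (xBW s); **RI** — integral of the force magnitude
  (xBW s).

The push-off (*impulse*) phase starts at the last upward crossing of
1.05 x body weight before the vertical-force peak — the standard
jump-analysis onset after the unloading dip — and ends at foot-off, the
first sample below 10 N after the peak.  Both thresholds are arguments.
g is fixed at 9.81 m/s^2.

### Interpretation choices the source description leaves open

* *Peak velocity* is the resultant instantaneous speed (not a per-axis
  maximum): a single PV value is reported and CM-velocity literature uses
  the resultant.  A per-axis variant can be derived from
  `differentiate()` if needed.
* *Resultant force/impulse* are norm-then-aggregate (the physical GRF
  magnitude), not aggregates of per-axis results.
* *Per-axis impulses* integrate |F| by default so left/right dives are
  comparable; `impulses(..., signed = TRUE)` selects signed integration.
* *Window extrema* are global with first-occurrence tie-breaks, matching
  the literal "lowest/highest point" definition.

## Signal conditioning

Raw channels are low-passed with a fourth-order zero-lag Butterworth
filter.  Zero-lag (forward-backward) application is chosen because a
causal pass would delay the detected events; the net order is the stated
order (two passes of order 2), and the per-pass design cutoff is raised by
1/(sqrt(2)-1)^(1/4) ~ 1/0.802 so the -3 dB point of the *combined*
response sits at the requested cutoff.  A single-pass mode
(`zero_lag = FALSE`) is available.

The cutoff defaults to `"auto"`: Winter-style residual analysis computes
the RMS raw-minus-filtered residual over a candidate grid (default
1-40 Hz), fits a straight line to the noise-dominated upper half of the
grid, and returns the lowest candidate whose residual has fallen to the
line's zero-frequency intercept.  The conventional 10 Hz value can be forced with
`filter_config(cutoff_hz = 10)`, and `"none"` disables filtering (the
right choice for noise-free synthetic data, where the degenerate
no-noise-floor branch would otherwise return the grid minimum with a
warning).  Whether force data should share the kinematic cutoff is not
settled; both channels are independently configurable and both are
filtered by default.

Differentiation is by central differences (one-sided at the ends), applied
after filtering.

## The synthetic dive model

The CM trajectory is a C1-continuous piecewise curve: quiet stance (0.5 s)
-> countermovement (cosine dip, 0.40 s, 0.25 m) -> push-off (0.35 s) ->
ballistic flight.  During the push-off the vertical velocity is the cubic
fixed by v(0)=0, a(0) matching the countermovement end, v(T)=v0z and
a(T) = -g, so the ground-reaction force F = m (a + g e_z) reaches exactly
zero at takeoff; horizontal velocities follow a smoothstep over
countermovement + push-off ending at the takeoff velocity.  Flight is
projectile motion.  Takeoff velocities are solved from the stated targets:
flight apex gain 0.10 m, mediolateral window reach 1.40 m, anteroposterior
reach 0.25 m plus a 0.25 m *frontal step* under the new rule only — the
generator's single injected rule effect, per the experimental contrast
(lateral-only impulse under OR vs frontal foot projection under NR).

Defaults were fixed once, before any acceptance measurement, to put the
noise-free displacement and velocity outputs inside the mean +/- 2 SD
ranges reported for laboratory penalty dives (a convenience for
plausibility, not a claim): e.g. OR RD ~ 1.52 m, AV ~ 3.1 m/s,
PV ~ 3.6 m/s, VPF ~ 1.9 xBW.  The normalised impulses (VI ~ 0.78 xBW s)
are smaller than some reported values (~2.3 xBW s), whose magnitudes
imply integration windows much longer than the
body-weight-crossing-to-takeoff phase used here; impulse-window
definitions are rarely stated in reports, and no test asserts those
magnitudes.

Sampling emulates the instrumentation: positions at 400 Hz, forces at
2000 Hz on an independent clock (offset half a force sample, so no shared
timestamps), with i.i.d. Gaussian noise per channel (defaults 2 mm, 5 N).
Sessions add lognormal variability on the dive-shape parameters at subject
level (CV 6 %) and trial level (CV 5 %) — without it a null world would
have zero variance and no defined t-test — and randomise trial order.  The
default session is 6 goalkeepers x 20 dives (5 per rule-by-side cell), one
left-footed subject among six, masses 68-97 kg.

Ground truth for all 14 variables is computed from the *continuous* model
(closed forms where available, adaptive quadrature/optimisation
otherwise), never from the samples, so any downstream discrepancy is
attributable to the pipeline.

### What a green recovery test does and does not establish

The generator emulates the phase structure, Newtonian force-motion
consistency, multirate sampling and measurement noise of real recordings.
It does **not** emulate marker occlusion and gap-filling artefacts,
soft-tissue movement, filter-worthy high-frequency content beyond white
noise, force-plate drift, asymmetric or failed dives, or between-subject
technique differences beyond smooth parameter scaling.  Recovery within
tolerance therefore validates the numerics and event logic of the
pipeline, not the biomechanical validity of any specific laboratory
dataset.

## Statistics

Lower-limb dominance is mapped from the IPLAG score (1-2 left, 4-5 right;
3 is unclassifiable and rejected).  Four paired designs are analysed for
each variable: rule (OR vs NR), laterality (DLL vs NDLL), and rule within
each relative side (ORD vs NRD, ORND vs NRND) — 56 comparisons.

The pairing unit is the subject.  Studies of this design often pool ~100
trials into a paired test without stating the pairing unit; with six
subjects the statistically defensible default is one pair per subject of
condition means (`pairing_mode = "subject_mean"`), and `"trial_matched"`
emulates pooled trial-level pairing (k-th trial vs k-th trial within
subject, surplus dropped and logged).  Reports record the mode.

`paired_t_test()` is the textbook statistic with explicit degenerate
conventions (all-zero differences: t = 0, p = 1; constant non-zero
differences: p -> 0 with a warning).  `cohens_d()` defaults to the
pooled-SD formula (interpretable on the conventional 0.2/0.5/0.8 ladder);
the paired-difference variant is selectable, and because the two can
differ appreciably at these sample sizes every report records which was
used.  Shapiro-Wilk p-values are reported per group but do not gate the
analysis by default (a gate can be enabled when normality must be
enforced rather than merely inspected).  No multiple-testing correction
enters the
significance flag; a Holm-adjusted column is appended, clearly labelled,
for transparency.

### Calibration as an acceptance property

The package's core statistical acceptance property is calibration: with
the frontal step set to zero (null world), 1000 replicate sessions through
the *full* pipeline must give a per-variable type-I error inside the
binomial 95 % CI of 0.05; with the default frontal step, the APD and AV
rule comparisons must be detected (NR > OR) with power > 0.8.  These run
in `tests/testthat/test-acceptance.R` (about ten minutes on one CPU; the
replicate loop uses the fixed conventional 10 Hz cutoff rather than per-trial
residual analysis, which would multiply the cost ~40-fold without touching
the property under test).

## Numerical and degenerate-input choices

* Filter end effects are handled by odd-reflection padding (3 cutoff
  periods), adequate because trials begin and end in smooth phases.
* Foot-off detection with a 10 N threshold fires early by
  threshold/|dF/dt| (~1 ms at defaults); recovery tolerances account for
  this deterministic bias.
* The dive window is quantised to kinematic samples (no interpolation), so
  noise-free recovery of displacement-type variables has a floor of about
  half a sample times the CM speed at the apex (~0.1 %), well inside the
  0.5 % acceptance tolerance but far above machine precision.
* Trials whose vertical minimum does not precede the maximum ("no rising
  phase"), whose force never exceeds the onset level ("no impulse"), or
  never returns below the contact threshold ("no takeoff") are excluded
  and logged with machine-readable reason codes, as are quality-flagged
  trials.
* All randomness flows from a single integer seed; equal seeds give
  byte-identical sessions.

## Known limitations

* The generator's rule effect enters only through the frontal step; real
  dives likely also differ between rules in vertical force and impulse,
  which the default world reproduces only in direction, not size.
* `trial_matched` pairing treats trial order as meaningful; with
  randomised order this is a pragmatic emulation, not a model.
* On-disk layouts of deposited motion-capture datasets vary;
  `read_trial_dir` defines the package's canonical CSV/JSON layout and is
  the adapter point for additional readers.  C3D ingestion is out of
  scope.
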