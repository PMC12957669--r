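---
title: "Volumetric capnography with capnovol: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric capnography with capnovol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capnovol)
```

## What the package computes

A volumetric capnogram plots the expired CO2 partial pressure of one
breath against the cumulative expired volume. Its canonical anatomy is:
phase 1, CO2-free gas from the conducting airways and apparatus; phase 2,
the sigmoid transition as alveolar gas arrives at the sampling site; and
phase 3, the sloped alveolar plateau. From this curve `capnovol` derives,
per breath:

* **S2V**, the slope at the phase-2 inflection (mmHg/ml), reflecting the
  airway–alveolar interface, and **S3V**, the slope of a regression over
  the middle third of phase 3, reflecting the homogeneity of alveolar
  ventilation-to-perfusion (V/Q) ratios;
* **Sn2V, Sn3V**, the same slopes divided by the end-tidal CO2 (ETCO2),
  removing the trivial dependence of slope magnitudes on CO2 level;
* **VDF**, Fowler's anatomical dead space — the volume expired up to the
  phase-2 inflection, minus the instrumental dead space;
* **VDB/VT**, Bohr's physiological dead-space fraction,
  `(PACO2 − PECO2) / PACO2`, with PACO2 the mean alveolar CO2 taken at
  the phase-3 volume midpoint and PECO2 the mixed-expired CO2 (the
  volume-integral of the capnogram divided by VT);
* **VDE/VT**, Enghoff's modification, `(PaCO2 − PECO2) / PaCO2`, using
  the arterial blood-gas value. Because arterial CO2 exceeds alveolar CO2
  in the presence of perfused-but-unventilated lung, VDE additionally
  captures intrapulmonary shunt. The difference `VDE/VT − VDB/VT` and the
  arterial–alveolar gradient `PaCO2 − PACO2` are reported as shunt
  indices;
* **VCO2**, the expired CO2 volume per breath, integrating the fractional
  concentration `pco2 / (barometric − 47)` over expired volume (47 mmHg
  is the water-vapor pressure at 37 °C; gas-state conventions vary between
  labs, dry-gas BTPS was chosen and is a single constant in the code).

The central practical virtue of the volumetric (rather than time-domain)
capnogram is flow-pattern robustness: remapping CO2 onto expired volume
cancels the difference between a passive decelerating expiration (typical
of positive-pressure ventilation, PPV) and a ventilator-controlled slow
expiration (negative-pressure ventilation, NPV). The test suite asserts
this as an invariance: identical lung profiles rendered through the two
flow templates agree on every index to within 3% (in practice < 1%).

## The synthetic-recording generator

No public raw data accompany this class of small-animal experiment, so
the package ships a generator that is itself first-class, tested code.

**Expirogram profile.** The volume-to-CO2 relation of one breath is a
logistic transition multiplied into a sloped plateau line:
`PCO2(V) = [p3_mid + s3_true (V − V_mid3)] / (1 + exp(−(V − vd_aw)/w))`,
with `vd_aw` the airway dead-space volume, `w` the transition width, and
`V_mid3` the midpoint of the analytic phase-3 interval
`[vd_aw + 4w, vt]`. As `w → 0` the profile tends to a square wave, for
which every dead-space quantity has a closed form — the sharpest oracle
the tests use (`VDB/VT = vd_aw/vt`, `PECO2 = plateau · (1 − vd_aw/vt)`).

**Flow templates.** Inspiration is a half-sine in both modes.
PPV expiration is a decelerating exponential with time constant
`decel_tau`, truncated at the expiratory window and rescaled so its
integral equals VT; a 20 ms linear rise precedes the decay because a flow
discontinuity is both unphysical and non-integrable without bias at a
finite sampling rate (a true jump loses half a sample's volume,
~0.04 ml per breath at 256 Hz, to any trapezoid rule). NPV expiration is
a half-sine: the chamber ventilator controls the expired-volume
trajectory. Published descriptions of chamber-controlled exhalation give no
quantitative NPV flow shape; the half-sine is a modeling choice, stated
here, not inferred fact.

**Acquisition chain.** Sidestream capnometry draws sample gas through a
line to a remote analyzer, which (i) delays the CO2 signal by a transport
time (bench-measured constants near 0.58–0.61 s at 256 Hz), (ii) smears
it with roughly first-order dynamics, and (iii) adds noise. The generator
applies exactly these three stages: a nearest-integer sample shift
(sub-sample interpolation was rejected — an integer shift keeps the
delay-correction round trip exactly invertible in tests), a first-order
low-pass with `smoothing_tau` (default 0.05 s; transport delay is
bench-characterized but smearing is not, so this is an exposed modeling
default), and additive Gaussian noise (defaults 0.5 mmHg on CO2 and 2% of
peak flow, exposed in the configuration). During inspiration the sampled
CO2 washes toward 0 mmHg (fresh room air) with the sensor time constant.

**Defaults as study conditions.** The defaults describe a healthy ~300 g
rat ventilated at 10 ml/kg: `vt = 3` ml, `vd_aw = 0.6` ml, plateau
40 mmHg, `s3_true = 2` mmHg/ml, 65 breaths/min, `decel_tau = 0.2` s. The
transition width default is 0.1 ml — a sharp, physiological phase 2
occupying ~13% of the breath. Two consequences are intentional. First,
at 256 Hz and peak PPV flow the raw samples under-resolve such a
transition and the generator warns; this mirrors the recognized
limitation that sidestream capnography biases early-phase indices in
small animals. Second, phase 3 is then long enough (≈ 2 ml) that a
middle-third regression has usable leverage; per-breath S3V noise scales
as the −3/2 power of the regressed length, and a fat transition makes
the slope estimate statistically hopeless long before it makes it
biased.

**Ground truth.** `oracle_indices()` evaluates the clean profile on a
~1.5 µl volume grid and computes every index with plain centred finite
differences, trapezoid sums, and closed-form least squares. It shares no
code with the analysis path; the simulated arterial value is
`PaCO2 = PACO2 + paco2_offset`, so the generator's shunt knob propagates
to Enghoff-side indices with a known answer.

## Estimator design

Several estimators differ from the first thing one would write down, in
each case because measured (noisy, discretely sampled) capnograms broke
the naive version:

* **Capnogram construction.** Expiratory samples are mapped onto
  cumulative expired volume (trapezoid-integrated flow, re-zeroed per
  breath), duplicates averaged, and interpolated onto a uniform grid of
  at least 200 points with a monotone Hermite (Fritsch–Carlson) spline.
  Linear interpolation flattens a sharp sigmoid wherever high flow leaves
  few samples across it (a ~2% S2V bias); an ordinary cubic spline
  overshoots on noise; the monotone spline does neither. Trailing
  samples whose flow magnitude sits inside the segmentation hysteresis
  band are trimmed: under flow noise the expiration/inspiration boundary
  is ambiguous there, and a single washed-in inspiratory sample landing
  at the top of the volume axis corrupts ETCO2 and everything downstream.
  VT is the boundary-to-boundary expired volume, not the last kept
  sample.
* **Phase-2 inflection.** dP/dV is estimated by local quadratic
  (Savitzky–Golay) smoothing over a `vt/20` window; the inflection is the
  largest *interior local maximum* within the first 75% of expired
  volume. A global argmax is defeated by boundary spikes (slow early NPV
  flow concentrates sensor transients at V ≈ 0), and 75% rather than a
  tighter cap leaves room for small-animal recordings in which apparatus
  dead space pushes the transition deep into the breath. S2V itself is
  re-evaluated at the located index with half the window: evaluating at a
  fixed index removes the wide window's attenuation of sharp transitions
  without inheriting the upward extremum-selection bias that taking the
  maximum of a noisier derivative would add.
* **Phase-3 onset.** Conceptually the plateau begins where the transition
  curvature has died out — below 10% of its peak, sustained over 5% of
  VT. On measured data the criterion is applied to the first derivative
  instead: the onset is where the smoothed slope has descended to within
  4% of its plateau-to-peak excess (on a logistic these two points
  coincide; 4% = 4·exp(−x*) with x* the curvature-form solution).
  Second derivatives of interpolated noise are so large that the literal
  curvature rule placed onsets essentially at random. The clean-profile
  oracle retains the literal curvature form, so the two routes stay
  independent. If the criterion is never met, a fallback mirrors the
  25%-of-rise point through the inflection and flags the breath
  low-confidence; onsets are clamped below 80% of VT.
* **ETCO2** is the mean over the final 5% of expired volume rather than
  the last sample — robust to endpoint noise. This makes ETCO2 sit below
  the end-point profile value by exactly `s3 · 0.05 · vt / 2` on a linear
  plateau, which the tests assert in closed form.
* **Delay estimation** reproduces the bench procedure: a step change in
  sampled CO2 at a sharp flow onset; the delay is the time between the
  10%-of-peak crossings of the two channels. The synthetic calibration
  uses a rectangular flow pulse — with a soft onset the flow's own
  threshold-crossing time (~16 samples for a half-sine) contaminates the
  estimate. Correction shifts the CO2 channel earlier by a whole number
  of samples and truncates all channels to equal length.
* **Segmentation** places breath boundaries at flow zero-crossings with a
  5% of-peak hysteresis, walks each crossing back to the true
  zero-crossing, drops the leading and trailing partial cycles, flags —
  but keeps — breaths failing volume or ETCO2 thresholds, and refuses
  signals whose median expiratory phase is under 10 samples (pure noise
  produces abundant threshold crossings; duration is the honest
  discriminator).

## The simulated study and its statistics

`run_pipeline()` simulates a paired design: each subject (weight drawn
from 244–402 g, VT at 10 ml/kg, anatomical dead space 15% of VT —
tracheostomy bypasses the upper airway — plateau N(40, 2) mmHg, S3
N(2, 0.3) mmHg/ml, shunt offset N(3, 1) mmHg) is ventilated with both
modes at matched EEP magnitudes. The mode's instrumental dead space
(1.14 ml PPV circuit, 0.70 ml NPV) is *added to the apparent airway dead
space of the simulated profile* — apparatus volume proximal to the
sampling site is series dead space — and the analysis subtracts the same
constant, recovering the anatomical value. Modeling the instrument as a
pure volume offset, rather than simulating rebreathing dynamics, is a
deliberate simplification.

Noise seeds derive from subject and EEP level but not mode: paired
comparisons use common random numbers. This has two consequences. Mode
contrasts are not diluted by independent noise draws; and a true null —
both arms configured identically, including the expiratory flow template
via the `flow_mode` override — produces bit-identical recordings and
exactly zero paired differences, making the null-pipeline check a sharp
test of the bookkeeping (pairing, aggregation, arm symmetry) rather than
a draw from a ~92%-coverage interval. With independent seeds the
"all 16 confidence intervals cover zero" event was observed to be a coin
flip whose failing index changed sign across seeds.

Per-breath indices are computed first and averaged (mean by default,
median available) over the accepted breaths of a recording; recordings
aggregate to one row per mode × EEP condition; the mode contrast is the
within-subject NPV − PPV difference of EEP-averaged indices, summarized
by its mean over subjects with a percentile bootstrap CI (2000 resamples)
over subjects. The repeated-measures ANOVA / mixed-model machinery used
for inference in the motivating experimental literature is deliberately
out of scope: the computational surface here is the capnography, and the
paired bootstrap is transparent and seed-reproducible.

## What the tests do and do not show

The acceptance-style tests run the full chain on synthetic recordings
whose ground truth is known: closed-form square-wave identities at 1 µl
resolution; pipeline-vs-oracle agreement (slopes within 2%, Fowler volume
within 0.05 ml, fractions within 0.01, pressures within 0.5 mmHg) across
a grid of dead-space volumes and plateau slopes; breath-averaged recovery
under realistic noise (S3V within 10%, VDF within 0.1 ml, VDB within
0.02); delay estimation within ±2 samples of injected 0.58/0.61 s
constants; flow-pattern invariance within 3%; strict monotone response of
Enghoff-side indices to an injected shunt offset with Bohr untouched; and
exact identities (`SnXV · ETCO2 = SXV`, `VDE = VDB` when `PaCO2 = PACO2`,
`shunt = VDE/VT − VDB/VT`) on every analyzed breath.

The generator emulates the geometry of real recordings — not their full
physiology. It has no lung mechanics (no compliance/resistance ODE, no
EEP-dependent recruitment), no oxygen model, no cardiogenic
oscillations, no breath-to-breath autocorrelation, stationary Gaussian
noise, and a single-compartment plateau whose slope is an input rather
than an emergent V/Q property. Passing tests therefore demonstrate that
the *estimators* recover known truth through a realistic acquisition
chain; they cannot validate physiological claims about ventilation
modes, and EEP is a pure label in the simulation. Problem sizes were
chosen for desk-scale determinism: 4–20 breaths per recording, 9 subjects
× 2 modes × 4 EEP levels in pipeline scenarios, 2000 bootstrap
resamples.

## Degenerate inputs and numerical conventions

Profiles must be non-negative with the transition complete inside the
breath (`vd_aw + 4w < vt`); violations are rejected at construction with
the violated bound named. Capnograms need a CO2 rise of at least
10 mmHg and an expiration of at least 10 samples. Fowler correction
clamps negative corrected volumes to zero and flags the clamp. Division
guards: ETCO2, PACO2, PaCO2 and barometric − 47 must be positive where
they appear in denominators. All tie-breaks (inflection peaks, onset
crossings) resolve toward the smallest volume. Recordings are validated
on load — uniform time base to 1 ns, equal channel lengths, CO2 above
−5 mmHg — and either fully valid or rejected.
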