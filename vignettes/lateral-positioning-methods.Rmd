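---
title: "Methods: regional EIT analysis and the simulated lateral-positioning protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional EIT analysis and the simulated lateral-positioning protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`lungEIT` implements the analysis chain of an electrical impedance
tomography (EIT) study of sequential lateral positioning in experimental
ARDS: regional ventilation metrics from tidal impedance variation, regional
lung-volume surrogates from end-expiratory lung impedance (EELI), regional
perfusion from a hypertonic-saline first-pass dilution transient recorded
during apnea, and the real-time upward PEEP titration applied at each
lateral-position onset. Because no recorded datasets are distributed with
such studies, the package ships a compartmental gravitational lung
simulator that generates the 32 x 32 pixel, 50 Hz frame sequences the
pipeline consumes. The simulator is first-class, tested code: every
analysis claim in the test suite is a parameter-recovery or
mechanism-reproduction statement against simulator ground truth.

# The lung model

The thorax is an ellipse with a longer right-left than anterior-posterior
span (34 vs 24 cm for a ~69 kg pig). Each lung-mask pixel (352 of 1024)
hosts one lung unit with:

* a compliance coefficient (mL/cmH2O), lognormal jitter around a uniform
  mean, normalized so the fully open lung has a respiratory-system
  compliance of 32 mL/cmH2O;
* opening and closing pressures that rise ventral-to-dorsal and scale with
  `injury_severity` in [0, 1]. At severity 1 the opening mean runs from 6
  (ventral) to 32 cmH2O (dorsal) and the closing mean from -2 to 12 cmH2O.
  The opening-closing gap (~8-22 cmH2O) is deliberately wide: with the
  emergent driving pressures of a severely injured lung (15-20 cmH2O), a
  narrow hysteresis would force every unit recruited at peak pressure to
  re-collapse at end-expiration within the same breath, and posture-induced
  recruitment could never persist after returning supine. The wide gap
  matches the classic observation that opening pressures in ARDS greatly
  exceed closing pressures. At severity 0, opening pressures are exactly 0
  and closing pressures sit 30 cmH2O below zero, so a healthy lung never
  de-recruits at any PEEP >= 0;
* a perfusion weight (lognormal), modulated at evaluation time by gravity
  and by hypoxic pulmonary vasoconstriction (below).

## Transpulmonary pressure and posture

Pixel coordinates are body-fixed: the electrode belt rotates with the
animal, so ROI masks never change with posture; only the gravity axis
rotates. Pleural pressure is linear in gravitational depth
(`pleural_gradient`, default 0.5 cmH2O/cm, referenced to the
least-dependent lung point), and transpulmonary pressure is airway minus
pleural pressure. Because the right-left span exceeds the
anterior-posterior one, a 30 degree lateral tilt strictly widens the
across-unit transpulmonary-pressure range relative to supine - the
geometric fact that makes lateral positioning both an opportunity
(recruitment of the non-dependent lung) and a hazard (collapse of the
dependent one). The pig literature does not pin the gradient's magnitude
for this weight class; 0.5 cmH2O/cm is a mid-range choice and is exposed in
`simConfig()`.

## Breath-by-breath recruitment dynamics

Per breath, the driving pressure is emergent: deltaP = tidal volume /
summed compliance of open units. A collapsed unit opens the moment its
end-inspiratory transpulmonary pressure exceeds its opening pressure
(recruitment is fast). Derecruitment is gradual: an open unit whose
end-expiratory transpulmonary pressure falls below its closing pressure
accrues "damage" equal to the deficit each breath and collapses once a
per-unit seeded threshold (default uniform 120-1200 cmH2O x breaths) is
exceeded; the accumulator resets whenever the unit is safe. This gives
derecruitment the minutes-scale time constants seen physiologically and
makes "EELI stops decreasing" a well-posed criterion; setting the threshold
range to zero recovers an instantaneous rule, which the hand-computed
trajectory tests use. A state with every unit collapsed is a flagged
degenerate error.

## Gas exchange and perfusion surrogates

The shunt fraction is the summed perfusion fraction of collapsed units.
Oxygenation is reported through a logistic surrogate that decreases
strictly from 500 (shunt 0) to 40 (shunt 1) on a PaO2/FiO2-like scale; it
is a qualitative mapping, not a gas-exchange model. Perfusion fractions are
`perfWeight x (1 + gravity_perfusion_slope x depth) x hpv_factor-if-collapsed`,
renormalized to 1 at every evaluation. Two defaults deserve comment:

* `hpv_factor = 0.3`: collapsed units keep 30% of their flow, a typical
  efficiency for hypoxic vasoconstriction.
* `gravity_perfusion_slope = -0.02` per cm: slightly *negative*. With a
  positive (gravity-dominant) slope, turning lateral shifts flow toward the
  dependent lung; the redistribution of interest in injured lungs runs the
  opposite way (vascular compression in the most dependent regions, release
  of hypoxic vasoconstriction in newly recruited non-dependent ones), i.e.
  it is non-gravitational. The negative default encodes that compression;
  users wanting classic gravity-dominant perfusion set it positive.

## Signal composition

Rendered pixel signals are: an aeration baseline held by open units
(`eeli_gain x compliance x (eeli_floor + max(P_L_exp, 0))`), a tidal
component for open units (amplitude `compliance x deltaP`, constant-flow
ramp inspiration and exponential expiration at I:E 1:2), a cardiac
sinusoid (amplitude proportional to the unit's perfusion fraction; default
mean pixel amplitude 0.15 A.U. at 77/min - deliberately not an integer
multiple of the 30/min respiratory rate, which would phase-lock the two),
and white noise (sd 0.05 A.U. per pixel per frame). During an expiratory
breath hold the tidal component is held at zero. A saline bolus produces a
negative deflection per pixel (saline is conductive), proportional to the
pixel's perfusion fraction, shaped as a gamma-variate first-pass kernel
(arrival 1.5 s, time-to-peak 2.5 s, shape 3) plus a smaller, delayed
recirculation bump - gamma-variate being the conventional form for
indicator-dilution transits.

# The analysis chain

**Breath segmentation.** The lung-summed signal is band-passed (zero-phase
Butterworth, 0.4-1.8 x the rate hint) and alternating extrema are taken
from its zero crossings; each index is then refined on the raw signal.
When the cardiac frequency is known (simulator metadata, or the
`cardiacHz` argument), a least-squares sinusoid at that frequency is
removed first: the global cardiac oscillation is comparable in amplitude
to the flat expiratory tail and otherwise drags end-expiration indices by
up to half a cardiac period. Breaths overlapping apnea windows are
dropped.

**Amplitude read-out.** deltaZ and EELI are read as 0.3 s window means
around the detected indices (backward-looking at end-expiration so the
next inspiratory upstroke cannot leak in). The window attenuates residual
cardiac content about five-fold and cannot bias regional *ratios*, because
the tidal waveform is common to all pixels. Filtering is used for timing
only; amplitudes always come from raw samples.

**Ventilation metrics.** Regional deltaZ is additive over disjoint ROIs by
construction. Shares are `100 x deltaZ_r / deltaZ_total` with negative
regional values (out-of-phase noise) clipped before normalization and the
clipped mass reported. Regional tidal volume is share x tidal volume;
regional compliance is that volume over the driving pressure; both
identities are tested at machine precision.

**Perfusion.** Pixel dilution curves are baseline (pre-bolus apneic mean)
minus signal, low-passed below half the cardiac frequency (zero-phase, so
the upslope is not displaced). The per-pixel score is the maximal upslope
over a 0.25 s lag - the lag avoids the positive bias a single-sample
maximum of differenced noise would add to weakly perfused pixels - with an
area-under-curve alternative behind `metric = "auc"`; curves are truncated
at the first post-peak local minimum to exclude recirculation. The study's
device literature uses slope-type first-pass scoring, but no single metric
is canonical, hence both. Negative scores are clipped; regional shares are
normalized sums.

**PEEP titration.** An explicit state machine over per-breath EELI
summaries, generic over its stream source (live simulator or replayed
recordings). Criteria per observation window (default 2 min per PEEP
level, restarted after every change so each level earns its own
stabilization evidence): (a) global EELI slope and (b) dependent-lung EELI
slope no more negative than a tolerance, and (c) cumulative dependent-lung
EELI drop since lateral onset at most `dzMultiple` (default 1.0, the
permissive end of the protocol's 0.5-1.0 range) times the
pre-lateralization dependent-lung deltaZ. "Stops decreasing" needs a
number: the default tolerance is 1% of that deltaZ reference per minute.
Calibration runs showed that at 2%/min a slowly but steadily derecruiting
dependent lung passes as "stable" and titration stops about one step short
of protective; at 1%/min the end point lands on the smallest protective
step in the closed-form scenarios while a healthy (flat-EELI) lateral
still terminates immediately at the initial 10 cmH2O. A safety cap
(default 24 cmH2O) bounds the otherwise unbounded upward search.

**Protocol runner.** Five steps in fixed order (Supine 1, Lateral Left,
Supine 2, Lateral Right, Supine 3; "Lateral Left" = left lung dependent -
the protocol text's reading, kept even though one figure caption suggests
the opposite). A 10-minute supine settling phase precedes Supine 1 so the
injured baseline is at steady state. Titration runs at each lateral onset
with the deltaZ reference taken from the immediately preceding supine
epoch, and the titrated PEEP carries over into the following supine step.
Step durations are simulated time and deliberately compressed (default 3
min per step); the summaries are computed on the final epoch of each step
(24 s of ventilation, plus a 20 s breath hold with a bolus when perfusion
is enabled), and steady state rather than wall-clock fidelity is what the
summaries measure. Per-step respiratory-system compliance is computed per
subject as tidal volume over driving pressure and averaged across
subjects afterwards (mean of ratios, not ratio of means). Cohorts are
independent seeds with jittered compliance scale (+/-15%), injury severity
(+/-0.03) and tidal volume (+/-15%).

**Statistics.** The paired comparison between steps is the paired-samples
t statistic, t = mean(d) / (sd(d) / sqrt(n)) with n - 1 degrees of
freedom, implemented directly and cross-checked against `t.test` in the
suite; its type-I error at n = 7 is verified by 1000 null simulations.
Omnibus repeated-measures testing across the three supine steps is
standard methodology and is delegated to existing tools rather than
reimplemented.

# Constructed validation scenarios

* `ventilationRecoveryScenario()` / `perfusionRecoveryScenario()` rescale
  per-quadrant compliance or perfusion weights of a healthy lung to
  prescribed fractions, so the rendered data carry exact known truth; the
  suite demands recovery within 2 percentage points (ventilation, default
  noise) and 0.03 (perfusion).
* `titrationScenario()` zeroes the pleural gradient (end-expiratory
  transpulmonary pressure then equals PEEP exactly) and gives a band of
  dependent-lung units a common closing pressure with damage thresholds
  laid out across the cumulative deficit exposure of every sub-protective
  PEEP level - derecruitment therefore demonstrably continues at every
  PEEP below the known maximum closing pressure, and the correct end point
  is the smallest 10 + 2k at or above it, in closed form.
* `eeliShiftScenario()` isolates the geometric mechanism behind the
  paradoxical dependent-lung EELI split seen when turning lateral: with
  recruitment disabled and the lateral PEEP chosen to offset the *mean*
  dependent-lung pleural rise, the dependent-dorsal quadrant (whose depth
  coordinate contributes with cos 30 < 1) gains transpulmonary pressure
  while the dependent-ventral quadrant loses it, and the whole
  non-dependent lung gains. In the full injured protocol the dependent
  dorsal quadrant's EELI change is dominated by derecruitment instead;
  the geometric scenario is the package's account of how the split can
  arise without it.

# What the simulator does and does not emulate

It emulates: posture-rotated gravitational pleural gradients,
opening/closing hysteresis with gradual derecruitment, emergent driving
pressure, tidal/cardiac/bolus signal composition at 50 Hz with white
noise, and HPV-linked perfusion redistribution. It does not emulate:
electrode-level voltage reconstruction (it produces reconstructed pixel
images directly), airway resistance or time-constant heterogeneity
(pendelluft), cardiogenic oscillation harmonics, electrode drift or
movement artifacts, abdominal/mediastinal weight (the geometric EELI
scenario stands in for those effects), or any hemodynamics beyond the
perfusion weights. Passing recovery tests on this generator therefore
shows the pipeline is correct under its signal model, not that it is
robust to every artifact of real recordings.

# Numerical choices and problem sizes

Zero-phase (forward-backward) second-order Butterworth filters everywhere
a filter is needed, so no phase distortion enters timing or upslope
estimation. Least-squares slopes use the closed form. Ties and degenerate
inputs error loudly (zero deltaZ, empty ROIs, all-collapsed lungs, bolus
outside apnea, zero-variance paired differences). The test suite and the
acceptance script use compressed problem sizes chosen to keep the full
suite under a few minutes on one CPU: 20-30 s rendered epochs, 3-minute
simulated steps, cohorts of 7 subjects, 20 recovery scenarios per
modality, 10 titration scenarios, 1000 null t simulations, 100 container
round-trips.

# Known limitations

The pixel grid, lung mask and thorax geometry are declared approximations
(no subject CTs); masks are user-replaceable via JSON. The oxygenation
surrogate is ordinal, not quantitative. The damage-accumulation
derecruitment rule is the simplest model with the right time scales, not a
fitted one. Perfusion scoring assumes a common dilution kernel across
pixels; transit-time heterogeneity would bias slope-based shares slightly
toward early-arriving regions. The titration tolerance expresses "stops
decreasing" relative to a deltaZ reference; recordings with very different
amplitude calibrations need the absolute tolerance set explicitly.
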