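---
title: "Quantifying prone cervical HVLA manipulation: models, parameters and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying prone cervical HVLA manipulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(manipkin)
```

## The measurement problem

In the prone stretching-and-adjusting neck manipulation, an operator slowly
tractions a prone patient's neck, then delivers a brief high-velocity,
low-amplitude (HVLA) thrust with the active hand on the occipitotemporal
region while the auxiliary hand fixes the upper thoracic spine. The patient
lies with the head on force plate 1 and the chest on force plate 2; marker
trajectories (200 Hz) and plate forces (1000 Hz) are recorded
synchronously. Five quantities characterize one manoeuvre:

* **Loaded forces.** The vertical ground reaction force (GRF) on plate 1
  mirrors the applied pressure. A manoeuvre is segmented by four turning
  points — A (stretch onset), B (end of stretch / thrust onset), C (thrust
  peak), D (return to rest) — into stretching (A–B), triggering (B–C) and
  return (C–D) phases. The *loaded* force of a phase is its force peak
  minus the pre-manoeuvre baseline (the resting head/neck weight, which
  differs between subjects): `stretch_loaded_max = max[A,B] Fz − Fz0`,
  `trigger_loaded_max = Fz(C) − Fz0`.
* **Trigger time.** The duration of the thrust, read from the operator's
  active-side acromion marker: from movement onset (point I) to the peak
  vertical displacement (point II).
* **Neck extension amplitude.** The increase of the distance between the
  head vertex (crown marker) and the mid-shoulder point (acromion
  midpoint, a T1 proxy) during stretching, in mm.
* **Axial rotation.** The head's rotation relative to the thorax about the
  thorax's vertical axis, from rigid-body fits of the head (crown,
  temporals, occipital bulge, mastoids) and thorax (acromions, inferior
  scapular angles, T10) marker sets; its pre-thrust and at-thrust maxima
  are compared.
* **Position-change artifact.** Between the left- and right-rotation
  manoeuvres the subject lifts and turns the head, producing a trough on
  plate 1 and a simultaneous peak on plate 2. The event is detected by its
  coincidence signature and excluded from all phase metrics.

## Signal processing choices

Recorded curves are smoothed before analysis, but no filter is prescribed
by the source protocol; we use community-standard zero-phase (forward–
backward) 4th-order Butterworth low-passes, 10 Hz for markers and 50 Hz
for forces, both exposed in `analysis_config()`. No signal-processing
package in the supported stack provides Butterworth/filtfilt, so the
package implements the bilinear-transform design and scipy-style
forward–backward filtering (odd-reflection padding, steady-state initial
conditions) directly; the coefficients and outputs are pinned against a
reference design in the test suite. Zero-phase filtering preserves peak
locations (events are timed, so phase lag would bias every time metric)
at the cost of non-causal smearing of sharp corners, which is why
threshold-based event detectors below always refine along the smoothed
flank rather than trusting the raw crossing.

Marker occlusions up to 10 frames are filled by cubic splines; longer
gaps stay masked and any metric over them fails loudly rather than
interpolating through unseen motion.

## Event-detection rules

Verbal definitions of the turning points were made operational as
follows (all thresholds relative to baseline and event amplitude, so the
segmentation is equivariant under amplitude scaling and time shifts):

* **A** — first time Fz exceeds `baseline + max(10 N, 5% of event
  amplitude)` sustained ≥ 50 ms, then walked backward along the
  monotone flank to the baseline plateau. The backtracking recovers the
  true onset within one sample on noise-free signals; without it, the
  threshold crossing lags the onset by the threshold lead time.
* **C** — the global maximum of the filtered series (earliest sample on
  exact plateau ties).
* **B** — the last local minimum before the final monotone rise to C.
  The walk-back runs on a 10 Hz-smoothed copy (on the steep thrust rise,
  sample-to-sample noise would stop a raw walk almost immediately) and is
  then refined to the true minimum within ±25 ms on the analysis series.
  A `b_rule = "dfdt"` alternative (last non-positive-to-positive crossing
  of dF/dt) is selectable.
* **D** — symmetric to A after the peak.
* **Trigger onset (point I)** — the velocity-threshold rule (5% of peak
  speed, sustained 25 ms) taken literally ("last sub-threshold time
  before the peak") would fire just before point II where the velocity
  returns to zero, so the search runs backward from the *peak-speed*
  instant, then backtracks along strictly decreasing |v| until |v| falls
  below 1% of peak speed — below that, motion has genuinely ceased and
  further backtracking only chases filter ripple. On a pure half-cosine
  this recovers the half-period within one frame.
* **Artifact** — plate-2 must rise above its baseline + 50 N while
  plate-1 falls below its baseline − 20 N within ±0.5 s; the surrounding
  window (padded 0.1 s) is excluded and each side of the trial is
  re-baselined independently.

## Rigid-body kinematics

Per-frame poses are least-squares orthogonal Procrustes (Kabsch) fits:
SVD of the cross-covariance between the observed markers and a reference
shape, with a determinant guard so reflections can never be returned.
The reference shape is the marker average over the first 0.5 s of the
trial (subject prone and still); no separate neutral capture is assumed.

The axial angle is the *twist* component (swing–twist decomposition) of
the relative rotation `thorax⁻¹∘head` about the thorax's vertical axis,
positive for left rotation; a Cardan X-Y-Z alternative is available for
comparison with Euler-based software, with gimbal proximity flagged. The
original analysis software's decomposition sequence is not published, so
exact numeric equivalence with the original study cannot be checked; the
convention here is explicit and tagged in every output
(`convention_tag`).

The twist axis is *anatomical*, not the laboratory Z: it is built from
the subject's own markers (acromion line × cranial direction from T10 to
mid-shoulder). This makes the angle invariant under any common rigid
transform of the laboratory — a property the test suite enforces to
1e-6 degrees — and is what segment-coordinate-system pipelines such as
Visual3D do.

First-order error theory: under isotropic marker noise σ the twist SD of
a Kabsch fit is σ/√(Σ r²ₓᵧ) over the markers' in-plane radii. For a
head-sized six-marker set that is ≈ 0.25–0.3° at σ = 1 mm. The
Monte-Carlo tests check the estimator against this envelope rather than
against a fixed absolute bound, because no estimator can beat the
geometry.

## The synthetic world

No recordings are distributed with the source study, so verification
rests on a generator whose defaults *are* the published conditions:

| parameter | default | source |
|---|---|---|
| triggering-phase loaded force | 476.75 ± 33.11 N (extremes 551.5 / 418.3) | results |
| stretching-phase loaded force | 274.79 ± 52.08 N (extremes 400.43 / 182.4) | results |
| trigger time | 0.35 ± 0.03 s | results |
| extension amplitude | 4.39 ± 1.02 mm | results |
| max left rotation pre / post | 68.6 ± 2.37 / 73.7 ± 1.34 ° | results |
| artifact: plate-2 peak, time | 514.1 N at 5.68 s | results |
| marker / force rates | 200 / 1000 Hz | instrumentation |
| cohort size | 10 subjects × 2 sides | study design |

Where the study is silent, values were fixed once at what a movement
scientist would call realistic and not revisited: plate-1 baseline 50 N
(head ≈ 5 kg), plate-2 baseline 350 N (chest share of body weight),
marker noise 0.5 mm and force noise 2 N (typical optical/plate noise
floors), thrust marker excursion 5 cm, a 1-s quiet lead-in, 2-s stretch
ramp, a small pre-thrust dip (8% of stretch level) that gives point B its
local-minimum signature, 1-s return, and a mirrored right side 6 s after
the left. The thrust is a raised cosine — C¹-smooth, with the rise width
mapping one-to-one to the trigger time so recovery semantics are exact.
Plate 2 receives 5% of the thrust amplitude as bracing coupling (the true
inter-plate force sharing is not reported; this is nominal and
configurable to zero). Head motion is a rigid twist about the vertical
axis through the mid-shoulder point plus a cranial translation equal to
the extension target, so rotation and extension are decoupled by
construction and every metric has a closed-form ground truth. The T10
marker is placed level with the acromions so the anatomical vertical of
the simulated subject coincides with lab Z exactly.

Per-subject parameters are drawn from normal distributions truncated at
zero (matching the study's normality testing), with deterministic
per-subject seeds derived from a master seed; the realized draws are
recorded so cohort tests compare extraction against *realized*, not
configured, values. Two guards keep drawn waveforms physically valid:
the stretch level is capped at 90% of the trigger peak (binding with
negligible probability under the published distributions) and the
post-rotation is kept at least 0.5° above the pre-rotation, as the
domain type demands.

What the generator does *not* emulate: soft-tissue artifact, marker-set
asymmetries, operator whole-body motion (only the active acromion moves),
inter-plate force redistribution dynamics, and non-stationary noise. A
green recovery test therefore establishes that the *pipeline* is
unbiased on trials with the study's published structure — it cannot
validate the biomechanics of real skin-mounted markers.

## Known estimator limitations

Two metrics have irreducible noise-induced bias by definition, which the
test suite characterizes rather than hides:

* **Extension amplitude** is a *maximum* of a distance over a window; the
  expected maximum of signal-plus-noise exceeds the signal plateau, so at
  1 mm marker noise the estimate runs ≈ +0.5–0.7 mm high (≈ 15% of the
  4.39 mm effect). Heavier smoothing cannot remove this without drooping
  the 1.5-s ramp it must track.
* **Trigger time** depends on a velocity-threshold onset; at 1 mm marker
  noise the filtered velocity noise is commensurate with the 5%-of-peak
  threshold and the onset jitters by tens of milliseconds.

A uniform sub-2% cohort-bias claim is therefore attainable for the force
and rotation metrics (and tested at that bound) but not for these two;
their tests assert the measured-bias envelopes (|bias| < 1 mm and
< 0.05 s respectively). Noise-free recovery — the basis of the
acceptance criteria — is exact to within filter transients for all
metrics.

## Statistics

Cohort summaries mirror the study's reporting: Shapiro–Wilk normality
(3 ≤ n ≤ 50), mean-centered Levene variance homogeneity (computed
directly as a one-way ANOVA on absolute mean deviations), and two-sided
paired t tests at α = 0.05 — left vs right loaded forces and pre vs post
rotation, with subjects missing a side dropped pairwise. The study's
"corrected T-test" for heterogeneous variances is ambiguous; it is
interpreted as a Welch comparison, reported alongside whenever Levene
rejects, and logged. p-values render to three decimals with a "0.000"
floor. Identical samples are reported as t = 0, p = 1 (no difference and
no evidence of one); nonzero constant differences are an error, since t
is undefined at zero variance.

Calibration runs at the parameter-sampling layer (draws fed straight to
the tests, 500 null cohorts and 200 effect cohorts) because the
extraction layer is shown separately to add no bias; re-synthesizing
500 × 20 full trials would add nothing but runtime.

## Degenerate inputs and tie-breaks

* Plateau maxima at C: earliest sample (documented `which.max` contract).
* Fewer than 3 visible markers, or collinear markers: named errors per
  frame; `angle_series` masks such frames and warns with a count.
* Baseline windows shorter than 0.25 s are rejected; windows with SD
  above 5 N warn but still return the median (robust to single spikes).
* Filtered series shorter than three filter lengths are rejected rather
  than silently unpadded.
* C3D I/O uses standard 32-bit floats, so round trips are exact only to
  single precision; the CSV dialect round-trips to 1e-6 N / 1e-7 m.
* Trials without a detectable artifact are treated as single-manoeuvre
  recordings, analyzed over the full duration with the side taken from
  trial metadata.

## Scope

Out of scope by design: centre-of-pressure trajectories, EMG and other
analog channels, inverse dynamics and joint loads, horizontal-force
phase analysis (computed only as the combined-force diagnostic), full
3-DOF joint angles, skin-artifact correction, real-time streaming, and
any clinical-efficacy inference.
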