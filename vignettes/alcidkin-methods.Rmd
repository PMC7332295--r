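---
title: "Measuring dual-medium wing kinematics from video landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring dual-medium wing kinematics from video landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alcidkin)
```

## The measurement problem

Alcids (murres, puffins, guillemots) flap the same wings in air and in
water. Whether they do so efficiently in both fluids can be framed through
the Strouhal number,

$$ St = \frac{f\,A}{U}, $$

where $f$ is wingbeat frequency (Hz), $A$ is wing excursion — the
peak-to-trough elevation of a wing landmark relative to the body — and $U$
is forward speed. Flapping-foil propulsion is most efficient roughly for
$0.2 < St < 0.4$, and cruising birds in general have been reported between
0.12 and 0.47. Alongside $St$, the stroke-plane angle $\beta$ (orientation
of the wrist/wingtip path between elevation extremes relative to travel),
the chord angle $\alpha$ (wingtip-to-wrist vector against the tail-to-eye
body axis at mid-half-stroke), wingbeat amplitude (angular sweep of the
shoulder-to-wrist vector, measured on flights seen head-on) and stroke
velocity (sweep over half-stroke duration) describe how
the wing is used differently in the two fluids.

All of these are computed from hand-digitized 2-D landmarks — eye, tail
tip, shoulder, wrist, wingtip — in single-camera video, so the pipeline has
to solve three measurement problems before any kinematics can be read off:

1. **Scale.** There is no calibration object; the camera-to-bird distance
   varies within a flight, and underwater shots add refraction. The package
   self-calibrates by dividing each frame's coordinates by that frame's
   (smoothed) eye-to-tail distance, expressing everything in body lengths
   (BL). A per-frame scale absorbs distance drift and refraction to first
   order.
2. **Frame.** Descending birds travel obliquely; elevation must be measured
   perpendicular to travel. Tracks whose trajectory is steeper than 20
   degrees are rotated rigidly about their centroid so travel is $+x$.
   Trajectories below 10 degrees are treated as horizontal and left
   untouched; the 10-20 degree gap belongs to neither defined class and is
   excluded.
3. **Noise.** Manual digitization jitters at the pixel level, and the head
   moves in sync with the wingbeat, contaminating both the body-length
   scale and any body-referenced quantity. Both are handled by penalized
   cubic smoothing splines, described next.

## Smoothing: convention and defaults

`smooth_series()` minimises

$$ p \sum_i (y_i - g(t_i))^2 + (1 - p) \int g''(t)^2 \, dt, $$

with time in seconds. $p \to 1$ interpolates, $p \to 0$ tends to the
least-squares line; constants and straight lines are reproduced exactly for
any $p$. Numeric values of smoothing parameters are convention-specific:
toolboxes that scale the penalty by knot spacing need very different
numbers for the same effect, so values quoted elsewhere transfer only
approximately.

Three smoothers with distinct jobs:

* **Body-length series** (`p_bodylength = 1e-4`). The eye-to-tail distance
  carries slow, real variation (apparent size) plus a wingbeat-frequency
  oscillation from head movement. At typical clip lengths of a few seconds,
  $p = 10^{-4}$ crushes everything above ~0.5 Hz while following linear
  drift exactly, which is precisely the separation wanted: the smoothed
  series is the per-frame calibration scale.
* **Kinematic smoothing** (`p_kinematics = NULL`, automatic). The landmark
  series themselves must keep the wingbeat intact. A fidelity weight fixed
  in seconds cannot do that across the study's range of frequencies
  (2-11 Hz) and frame rates (29.97-239.76 fps), so the default sets the
  roughness weight by its effect: viewing the spline as the low-pass filter
  $H(\omega) = (1 + \lambda h \omega^4)^{-1}$ ($h$ = frame interval), the
  half-power point is placed at 5 times the flight's dominant wingbeat
  frequency (estimated from mean crossings), capped at 0.3 times the frame
  rate. Attenuation at the wingbeat frequency is then below
  $(1/5)^4 \approx 0.2$ percent while frame-level jitter is damped. An
  explicit `p_kinematics` overrides the automatism.
* **Bird-centre reference.** Bird-centred vectors (for $\beta$) and the
  elevation reference (the per-frame eye/tail average) must not inherit the
  head bob, which is phase-locked to the wingbeat and otherwise biases
  $\beta$ by several degrees. The eye-tail midpoint path is therefore
  low-passed at one third of the wingbeat frequency — far enough below the
  wingbeat to reject the bob, high enough to track slow apparent-size
  drift, whose calibrated image offset is curved in time when the camera
  distance changes linearly.

## Per-flight reduction

For each flight: estimate the descent angle (orthogonal least-squares line
through the eye-tail midpoint cloud), classify, rotate if descending,
calibrate, smooth, then:

* **Segmentation.** Alternating elevation extrema of the smoothed wrist
  (aquatic) or wingtip (aerial) series, pruned by a prominence rule — local
  ranges below 10 percent of the flight's median peak-to-trough range are
  jitter, not half-strokes (manual digitization at extremes needs no such
  rule; automation does). Each surviving extremum is refined on an
  interpolating spline at 20-fold temporal resolution: without refinement,
  sampling-phase quantization alone biases excursion by more than a percent
  at high $f$/low fps. Leading/trailing incomplete half-strokes drop out by
  construction.
* **Excursion** per wingbeat: max minus min elevation, in BL.
* **Frequency**: inverse wingbeat duration per wingbeat (aquatic), or
  complete wingbeats over total duration (aerial — robust at low frame
  rates).
* **Stroke-plane angle** per downstroke: angle in $[0, 180]$ between $+x$
  (travel) and the bird-centred displacement of the wing landmark from
  elevation maximum to the following minimum. Values under 90 degrees mean
  a down-and-forward downstroke (aerial posture); over 90, down-and-back
  (aquatic). The max-to-min direction convention is chosen so those two
  regimes land on those two sides.
* **Chord angle** at the temporal midpoint of each half-stroke (robust to
  asymmetric elevation profiles), aquatic flights only, requiring both
  wrist and wingtip.
* **Translational velocity**: along-path tail velocity for aquatic flights
  (the head is an unreliable proxy for body motion), with the
  pitch-induced component $\dot\varphi \times r$ removed vectorially
  ($\varphi$ from the smoothed tail-to-eye vector, differentiated through
  the spline — an $O(h^3)$ derivative where finite differences of the
  sampled series would be $O(h^2)$ and fail the sub-$10^{-3}$ BL/s
  pure-pitch contract at 119.88 fps). Aerial flights use the eye-tail
  midpoint (ground speed), which sits on the pitch axis. The correction is
  exposed as a toggle (`pitch_correction`).
* **Strouhal number** from the per-flight means, $St = \bar f \bar A /
  \bar U$, with the excursion SD propagated holding $f$ and $U$ fixed:
  $\mathrm{sd}(St) = \bar f\, \mathrm{sd}(A) / \bar U$. For aerial flights
  $St$ is reported both from ground speed and as a range over the species'
  cruising-airspeed prediction interval (mean ± 1.96 SD from the
  literature, by size class), since $St$ decreases in $U$.
* **Parallel-view flights** yield wingbeat amplitude (angle at the shoulder
  between shoulder-to-wrist vectors at the elevation extremes) and stroke
  velocity, either per half-stroke or via the $0.5/f$ duration
  approximation used where frame rates are too low to time individual
  strokes.

Flights are the unit of analysis throughout: statistics consume per-flight
means, never per-wingbeat rows.

## The statistical workflow

`fit_lm_sequential_anova()` fits ordinary least squares on (by default)
log-transformed responses — multiplicative biological variation becomes
additive and homoscedastic — and decomposes variance sequentially (type I)
in the stated factor order, reporting $\eta^2 = SS_\mathrm{term} /
SS_\mathrm{total}$. A non-significant interaction (threshold 0.05, matching
the reporting convention; the rule itself is fixed, the threshold was an
open choice) is dropped and the model refit with main effects. Post hoc
within-species contrasts use Tukey's studentized range on the
interaction-cell means; the aov is refit with the interaction present even
when the sequential model dropped it, so contrasts are always between cell
means (the alternative — per-species models — was the other reading of an
underspecified design, and is noted here as not chosen). Stroke velocities,
whose variances differ strongly among species, are compared within species
by Welch's unequal-variance t-test (closed-form statistic and
Welch-Satterthwaite df) at a Bonferroni-corrected critical p of $0.05/4 =
0.0125$, with Cohen's d alongside. Model fits are screened with a
Bonferroni outlier test on the largest externally studentized residual; a
significant outlier is excluded and the model refit once — a single pass is
conservative and reproducible, where iterating to convergence could
cascade.

## What the synthetic generator emulates — and what it does not

`generate_flight()` animates a rigid body of length $L$ translating at $U$
along a straight path $\theta$ below horizontal, with sinusoidal wrist
elevation of peak-to-trough $A$ directed along a stroke plane at $\beta$ to
travel, chord angle blending sinusoidally between its mid-upstroke and
mid-downstroke values, head movement along the body axis in sync with the
wingbeat, sinusoidal body pitch about the eye-tail midpoint, off-axis
cosine foreshortening, a pixel scale with optional linear apparent-size
drift, and i.i.d. Gaussian digitization noise. The stroke vector is scaled
by $1/\sin\beta$ so that the generated *elevation* range equals $A$ exactly
— ground truth is defined in the measured quantity (this is why the
generator requires $15 < \beta < 165$ degrees).

Defaults are study-like: a murre-scale bird ($L = 0.43$ m) swimming at
1.63 m/s, flapping at 2.4 Hz with $A = 0.122$ m; aquatic camera at 119.88
fps; digitization noise calibrated so the apparent body-length jitter is
about 1 percent of body length; head-bob amplitude 5 percent of body
length; pitch amplitude 2 degrees (which keeps the pitch-induced velocity
under 5 percent of translational speed, the regime the method expects);
five wingbeats per flight. `default_study_design()` spans four species in
five conditions (aerial, horizontal aquatic, descending aquatic,
perpendicular view; aerial and aquatic, parallel view), with per-cell means
set to the magnitudes the method is meant to resolve — aquatic frequencies
a third of aerial ones, greater amplitude in water, aquatic $\beta$ just
above 90 and aerial well below, $St$ between 0.13 and 0.29 — and
between-flight scatter of 6-10 percent. Synthetic aerial flights are
generated at 239.76 fps so a single segmentation path serves both fluids.

What passing recovery tests does **not** show about real data: the
waveform is a pure sinusoid (real strokes are asymmetric), the wing is a
point (feather bending inflates aerial wingtip amplitude, and no
correction is applied — aerial amplitude carries that caveat), the camera
model is a single off-axis angle with scaling about the image origin (a
real lens scales about its optical axis and distorts), refraction is
folded entirely into the per-frame calibration, and digitization error is
Gaussian and independent where human error is neither. Parameter recovery
on this generator validates the estimators' algebra and the smoothing
design, not the biology.

## Numerical choices and degenerate inputs

* Rotation is about the track centroid; all derived quantities are
  translation-invariant, so the centre choice is immaterial.
* Rotation sign: y is up internally (readers can flip screen coordinates on
  ingest), depth increase maps to $-y$, and a positive descent angle
  rotates points counter-clockwise, which levels a descending path.
* The descent-angle line is the principal axis of the midpoint cloud
  (orthogonal regression), symmetric in x and y, so near-vertical dives do
  not blow up a slope.
* Extremum refinement: ±1.5 frames around each sampled extremum, 61 dense
  spline evaluations.
* Spline mapping: the seconds-based roughness weight is rescaled by the
  cube of the time range to `stats::smooth.spline`'s internal unit-interval
  abscissa; `all.knots = TRUE`.
* Errors, not guesses, for: fewer than 2 frames, duplicated or non-monotone
  frames, missing required landmarks, coincident eye/tail, non-positive
  calibration scale, zero net displacement, frame rate at or below twice
  the wingbeat frequency, no detectable extrema, zero stroke duration,
  zero-variance Welch inputs, insufficient residual df for studentization.
  Interior undigitized gaps of at most 2 frames are interpolated with a
  warning; longer gaps split the flight into separate tracks.
* Efficiency-band membership uses half-open intervals $[low, high)$ so
  boundary values classify unambiguously; the optimal band takes precedence
  over the literature band.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on
synthetic flights of 5-6 wingbeats (250-300 frames at 119.88 fps), a
3×2×3×3 recovery grid ($f \in \{2,4,8\}$ Hz, $A \in \{0.2,0.4\}$ BL, $U
\in \{1,2,4\}$ BL/s, descent $\in \{0,30,60\}$ degrees) in noise-free and
noisy versions, a study simulation of 6 flights per design cell (120
flights), and $10^4$ null replicates for the Welch type-I-error check —
sizes chosen so the whole suite exercises every code path in a few minutes
on one core while keeping Monte-Carlo error well inside the tolerances
being asserted.

## Known limitations

Single-camera 2-D analysis cannot see spanwise wing posture; chord angle is
a projection. Aerial $St$ from ground speed ignores wind (hence the
airspeed-range variant). The culmen-to-body-length ratios shipped in
`species_config_synthetic.csv` are synthetic stand-ins for
photograph-derived measurements; metric quantities depend on them, the
dimensionless $St$ does not. The pitch-correction construction (rotation
about the eye-tail midpoint) is a reconstruction of a procedure whose
original details live outside this package, and is therefore toggleable.
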