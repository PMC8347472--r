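---
title: "Posture assessment from 2D keypoints: models, parameters and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Posture assessment from 2D keypoints: models, parameters and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergopose)
```

## The problem

Prolonged desk work in a poorly adapted workstation drives musculoskeletal
strain in the neck, shoulders and arms. Ergonomic practice grades the
strain of a joint angle into four range-of-motion zones — zone 0 (very low
risk) through zone 3 (high risk) — with published degree thresholds per
postural parameter. A webcam plus any modern 2D pose estimator yields, per
video frame, an 18-point skeleton (the 17 COCO landmarks plus a neck
point); `ergopose` is everything downstream of that estimator: angles,
zones, alerts, and the statistics needed to evaluate such a system against
manually labelled ground truth.

## From keypoints to angles

Each postural parameter is the orientation of one keypoint segment
relative to an image axis, computed with the quadrant-aware arctangent in
its explicit six-branch piecewise form (`atan2_piecewise()`), then folded
to an unsigned deviation. With image coordinates (origin top-left, y
downward) and `dx, dy` the coordinate differences of the two endpoints:

* **shoulder alignment** — left→right shoulder against the horizontal,
  `|atan2(dy, dx)|` folded to [0°, 90°]; level shoulders read 0°;
* **neck lateral bend** — neck→nose against the vertical,
  `|atan2(dx, dy)|` folded to [0°, 90°]; an upright head reads 0°;
* **left / right arm abduction** — shoulder→same-side elbow against the
  vertical (down), kept on [0°, 180°]; a hanging arm reads 0°, a
  horizontal upper arm 90°, an arm overhead up to 180°.

The fold (θ > 90° ↦ 180° − θ) makes the symmetric parameters direction-
blind, which is what the zone tables expect: they grade magnitude of
deviation, not side. Arm abduction keeps the full half-turn because its
zone 3 ("68°+") extends past horizontal. These reference-axis choices are
a design decision — the keypoint pairs alone do not fix an axis — made so
that the zone-0 bands correspond to level shoulders, upright head and
hanging arms.

Two caveats are inherent to a frontal 2D view and are deliberately not
modelled: the nose–neck segment conflates lateral bend with in-plane head
rotation, and back flexion/extension (and neck flexion/extension) are
unobservable without a side view or depth. The range table still ships all
nine parameter rows so users with other instruments can classify those
angles through the same machinery.

A measurement is *invalid* — never a number — when an endpoint keypoint is
absent (or gated out by the optional minimum-confidence threshold, default
off) or the two endpoints coincide. Invalidity propagates: the zone, the
binary class and the smoothed series all stay `NA` for that parameter and
frame, and the other parameters are unaffected.

## Zones and the safe/dangerous collapse

`classify_angle()` maps an angle to its zone via three inclusive upper
bounds `u0 < u1 < u2` per parameter (defaults e.g. neck lateral bend
5/12/24, shoulder alignment 5/10/20, arms abduction 13/34/67). Printed
band tables use integer ranges ("0–5, 6–12, 13–24, 25+"); for real-valued
angles we declare left-open/right-closed intervals on the printed upper
bounds — zone 0 = [0, u0], zone 1 = (u0, u1], zone 2 = (u1, u2], zone 3
above — which matches every printed integer band, covers the continuum
without gaps, and is isolated in one function should a user prefer a
different convention (the table itself is overridable from YAML). Both arm
parameters classify against the *abduction* row; the adduction row
(5/12/24) remains available for users measuring that movement.

Zones 0–1 collapse to *safe*, zones 2–3 to *dangerous*. The collapse
direction matters clinically: a dangerous posture predicted safe is a
*critical error*; the converse is only a false alarm.

## Alerts

Per-frame zones are too jittery to notify on, and no published algorithm
exists for the temporal side, so the whole alert policy is this package's
own design, with conservative defaults chosen so that single-frame
estimator glitches can never page the worker:

* trailing majority-vote smoothing over a **2 s** window (ties break to
  the higher zone — cautious by construction; windows with no valid frame
  are invalid);
* an alert opens only after the smoothed zone has been ≥ the trigger zone
  (default 2) continuously for a **10 s** dwell, and closes when it drops
  below;
* a renewed violation within a **60 s** cooldown of the previous close
  extends that alert instead of opening a new one.

All three durations and the trigger zone are user-settable. The session
report integrates time-in-zone from frame timestamp differences (the last
frame lasts one nominal frame period), so per parameter the four zone
times plus invalid time sum exactly to the observed duration.

## Evaluation machinery

Against labelled samples (per frame and parameter: true zone, predicted
zone), the package computes 4×4 confusion matrices (rows truth, columns
prediction; invalid predictions excluded and counted), per-class
one-vs-rest scores with accuracy `(TP + TN) / TOTAL`, the headline overall
accuracy as trace/total, critical-error counts, and the same quantities
after the two-class collapse. Merging classes can only keep or move
off-diagonal mass onto the diagonal, so two-class accuracy is provably ≥
four-class accuracy on the same samples — a property the tests assert on
random label sets.

The repeated-subset evaluation draws `n_subsets` (default 15) random
subsets of 50% of the samples *without replacement* — the protocol is
sometimes called bootstrap, but taking half the samples is subsampling,
so that is the default and a with-replacement flag exists — and
summarizes per-subset accuracies with MIN/MAX (exact order statistics),
MEAN, population standard deviation (divide by n; the convention is not
fixed by any reference, and recomputation from rounded published tables
cannot distinguish the two, so the simpler population form is declared),
and `Improve`, the relative percent gain of the two-class mean over the
four-class mean. `summarize_subset_table()` applies the same summary to an
externally supplied per-subset table; the package bundles one such
15-subset worked example (`inst/extdata/resample_accuracy_subsets.csv`,
transcribed from a published frontal-camera posture study) whose shoulder,
right-arm and left-arm summary rows reproduce exactly at three decimals.
Recomputed means from 3-dp-rounded per-subset values can legitimately sit
up to one final-digit ulp (0.001) from a published mean — the neck
4-class column needs that allowance — and one published MAX cell is
internally inconsistent with its own column; the test suite documents
both observations rather than asserting the impossible.

## The synthetic generator

No public dataset pairs skeleton streams with ergonomic zone labels, so
the generator emulates the study conditions such systems are evaluated
under: **12 subjects × 13 frames** (156 frames, the scale of a small
multi-subject recording campaign), ground-truth zones balanced over 0–3
per parameter (the least-informative choice, exercising every zone
boundary; real label distributions are unknown), angles drawn uniformly
inside the target zone's interval with zone 3 capped at its lower bound
+ 30° to stay anatomically plausible, isotropic Gaussian keypoint jitter
of **σ = 2 px** standing in for pose-estimator noise (uncharacterized in
the literature; 2 px on a 640×480 frame yields ~1–2° angle noise on these
segment lengths, which lands evaluation accuracies in the realistic
0.8–0.95 band), and keypoint dropout probability **p = 0** by default
(dropout is a separate, controlled experiment in the tests). Fixed-angle,
fixed-zone and linear-drift target scripts cover the remaining test
needs.

The articulation is exact by construction: posing the template at
requested angles and re-measuring recovers them to 1e-6°, so with σ = 0
the end-to-end pipeline reproduces ground-truth zones on 100% of frames —
the key identity test separating geometry bugs from genuine noise
effects. What the generator does *not* emulate: correlated or
heavy-tailed estimator noise, anatomy varying between subjects, camera
distortion, annotator error in manual labels. Passing on synthetic data
therefore validates the post-processing pipeline, not any pose estimator.

## Numerical and degenerate-input choices

* `atan2_piecewise` raises an error at (0, 0) (the angle is undefined)
  and agrees with the reference `base::atan2` to 1e-12 over a 10^4-point
  grid including all six branches in the tests.
* Coincident keypoints raise an undefined-angle error, caught and turned
  into an invalid measurement at the frame level.
* Stream serialization writes coordinates at 17 significant digits, so
  both on-disk formats round-trip doubles exactly.
* Empty streams classify to empty outputs without error; empty sample
  sets raise explicit empty-input errors in the evaluation functions.
* All randomness (generation, subsampling) flows from explicit integer
  seeds; every command is deterministic given its configuration.

## Problem sizes

The test suite and the acceptance script run the generator at its default
156-frame scale (with a few smaller 40–80-frame configurations for
property sweeps across seeds and jitter levels), 15-subset × 50%
resampling, and 10^4-point numeric grids — sizes chosen to mirror the
study scale the package emulates while keeping a full run in the order of
seconds to a couple of minutes on one CPU.
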