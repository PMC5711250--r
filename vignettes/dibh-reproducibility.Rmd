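---
title: "Quantifying DIBH surface reproducibility: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DIBH surface reproducibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dibhtrack)
```

## The problem

In left-breast radiotherapy with deep-inspiration breath holds (DIBH), the
patient holds a forced inspiration inside a spirometric gating window —
90% of the maximum inspiratory capacity with a tolerance of ±0.1 L
(`compute_gating_window()`) — while tangential fields are delivered.
Spirometry controls the *inspired volume*, but the treatment geometry
depends on the *surface position*: the same volume can be reached with
more thoracic elevation (cranio-caudal, CC) and less abdominal filling
(antero-posterior, AP), or vice versa. `dibhtrack` implements the
analysis that quantifies how reproducible the external surface actually
is under volume-only guidance, using passive markers tracked by a stereo
optical localizer in the linac frame (x = LL, y = AP, z = CC, isocenter
origin, mm; the sign convention — +LL towards patient left, +AP anterior,
+CC cranial — is fixed by this package, as clinical reports name the axes
but not their signs).

## Variability model and estimators

All indices are built from two robust primitives: the per-axis **median**
and the **5th–95th percentile range**. For marker `m` and hold `i` within
window `T_i`:

* `S_i^m` — percentile range of the raw coordinate within `T_i`
  (intra-DIBH stability; drift and noise);
* `d_i^m` — median coordinate within `T_i` (intra-DIBH position);
* `V_n^m` — percentile range of `{d_i^m}` over the holds of session `n`
  (intrafraction reproducibility);
* `W^m` — percentile range of the pooled `{d_i^m − f_n^m}` over all
  sessions, with `f_n^m` the session's free-breathing baseline
  (interfraction reproducibility);
* `F^m` — median of `|f_n^m − b_i^m|` (free-breathing stability, the
  sanity check on the baseline);
* Pearson `r` between `d_i^m` and the mean volume held during `T_i`.

Three estimator-level decisions are fixed package-wide so every number is
exactly reproducible:

1. **Percentile estimator.** Linear interpolation between order statistics
   (`stats::quantile()` type 7). No percentile convention is standard in
   the clinical literature; fixing one makes the brute-force oracles in
   the test suite exact rather than approximate.
2. **Pooled reading of `W`.** `W` is computed on the single pooled set of
   baseline-corrected positions from all sessions, not per-session and
   then combined — "all holds of all sessions" admits only the pooled
   reading.
3. **`F` as absolute per-axis deviation.** The defining expression can be
   read signed or absolute; since the quantity is reported "per spatial
   coordinate" as a distance, the per-axis absolute deviation is used.
   (A signed median would hover near zero by symmetry and carry no
   stability information.)

Two further conventions, stated because the source protocols are silent:
intrafraction and interfraction indices use *setup-corrected* positions
(holds acquired during the SSD check and portal imaging are shifted by the
applied couch correction, `correct_setup_shift()`, before pooling with
field-delivery holds — field holds pass through unchanged); and
marker-averaged quantities use the **median over markers** (with 25th–75th
quartiles), including the marker-averaged Pearson coefficient.

Missing data are excluded and logged, never imputed: a hold needs ≥ 50% of
its in-window samples valid, `V` needs ≥ 2 holds, `W` ≥ 2 sessions with a
valid baseline, and a Pearson coefficient ≥ 3 pairs with non-degenerate
variance.

## Rigid registration and population errors

The planning-to-treatment displacement of the marker constellation is
estimated by least-squares rigid registration (`fit_rigid()`): centroid
alignment, SVD of the cross-covariance with reflection correction, no
scaling. Conventions:

* **Euler angles**: intrinsic rotations in the order LL, then AP, then CC.
  At setup-error magnitudes (≤ a few degrees) the ordering effect is
  second-order, but one convention is needed for exact round-trips.
* **Rotation pivot**: the planning-constellation centroid — the natural
  least-squares pivot. Reported translations are therefore centroid
  displacements; a transform expressed about another pivot differs in its
  translation by `(R − I)(pivot − centroid)`.
* **Direction**: planning → treatment; `invert_transform()` gives the
  reverse mapping exactly.

Per session, the treatment position of a marker is the median of its
`d_i^m` over the field-delivery holds; the session with the largest mean
3D planning-to-treatment distance is the *worst session* (ties towards the
earliest). Residual displacements after rigid correction are summarised
as median ± interquartile range. For a multi-patient study, a rigid
transform is fitted to every field hold and the parameters decomposed into
the standard population components: group mean `M`, systematic
`Σ` (SD of per-patient means) and random `σ` (RMS of per-patient SDs).

## Stereo calibration

3D marker coordinates come from a dual-camera optical localizer, so the
package includes the calibration chain: an 11-parameter DLT camera model
without distortion terms (consistent with the ~1 mm accuracy of such
systems), Hartley-style coordinate normalisation for conditioning of the
linear system, and linear two-view triangulation. The calibration fixture
is the clinical protocol's grid phantom: 7 × 7 markers on a 36 × 36 cm
plane, acquired at five couch heights in 5 cm steps (245 points, central
marker at the isocenter). A single height is coplanar and is rejected as
degenerate — the multi-height stack is what makes the DLT system full
rank. The dual-camera geometry is not prescribed anywhere, so the fixture
assumes a plausible rig (two cameras 3 m apart, ~2.9 m from the
isocenter, 1800 px focal length); with 0.4 px image noise — calibrated
once by Monte-Carlo — the median 3D reconstruction error of the fixture
is about 1 mm, matching the accuracy regime of clinical optical
localizers.

## What the simulator emulates

No clinical tracking data are distributed, so validation rests on a
generative model (`simulation_config()`, `simulate_cohort()`) with a full
ground-truth sidecar. Default study conditions mirror a monitored
left-breast DIBH course: 7 sessions, 5 holds per session (SSD check,
portal acquisition, then field deliveries — 35 holds in total), 8 markers
in breast/thorax/abdomen groups, 50 Hz sampling, holds of 5–20 s each
preceded by two complete free-breathing cycles.

Model components, per marker coordinate:

* **Free breathing**: a raised-cosine-squared waveform (long end-exhale
  dwell, period 4 s) with 5% per-cycle period and amplitude jitter.
* **Volume signal**: a fixed positive linear combination of the thoracic
  CC and abdominal AP compartment displacements (defaults 0.135 and
  0.1125 L/mm, chosen so the nominal plateau elevations of 10 and 12 mm
  carry a 2.7 L held volume), plus hold logic. During a plateau the held
  volume stays inside the gating window by construction; the thoracic
  share of that volume (`alpha_split`, nominally 0.5) is jittered per hold
  and per session — this is exactly the constant-volume thoracic/abdominal
  trade-off, and produces the inverse CC-thorax/AP-abdomen relationship.
* **Plateau variability**: a linear drift (defaults up to 0.1 mm/s, an
  optional Brownian term), a constellation-wide between-hold offset
  (SD 0.8 mm), a per-marker scatter (SD 0.3 mm) and a between-session
  offset applied to plateaus only (SD 1.0 mm). The session offset is
  deliberately *not* applied to free breathing: it models the
  constant-volume posture difference between fractions, which baseline
  subtraction must not cancel — while marker-replacement and setup errors,
  which affect free breathing and holds alike, are cancelled by the
  baseline by construction.
* **Setup**: an optional rigid transform per session (planning-to-
  treatment displacement) and a couch setup shift (1 mm resolution)
  applied after the portal hold; samples acquired before the correction
  are displaced by minus the shift.
* **Measurement noise**: isotropic Gaussian, SD 0.3 mm per sample —
  conservative relative to the ~0.9 mm median 3D calibration error of the
  localizer class, since the variability indices operate on medians of
  hundreds of samples.
* The inhale ramp tops out just below the gating window's lower bound and
  the plateau starts at the held volume directly, so the annotated
  breath-hold window coincides exactly with the maximal in-window run —
  detection and annotation agree to one sample period on clean traces.

Defaults were chosen once to land in the clinically reported magnitude
range (intra-hold ~1–2 mm, within-session ~2–3 mm, between-session
~4–6 mm, free-breathing stability ≪ 1 mm) and are not tuned further.

**What the simulator does not emulate** — and hence what passing tests do
*not* establish about real data: non-rigid chest-wall deformation beyond
the regional compartment model (real residual displacements after rigid
correction are typically 2–3 mm; the simulator's are smaller because its
deformations are regionally coherent), cardiac motion, marker occlusion
bursts (dropout is i.i.d.), spirometer drift and volume measurement
noise, intra-session baseline wander of free breathing, and any
image-formation effects (marker centroiding is abstracted into pixel
noise).

## Window detection

When annotations are absent, holds are detected as maximal runs of
volume samples inside the gating band lasting ≥ 3 s (the verification
holds last about 5 s, field holds 11–20 s, so 3 s accepts all types while
rejecting transients). Free-breathing cycles are delimited end-exhale to
end-exhale: trough candidates are found on a 0.5 s moving-average-smoothed
signal with a prominence threshold of 10% of the local breathing
amplitude, then refined on the raw samples via the first
negative-to-nonnegative transition of the finite difference — exact to one
sample on noise-free traces, degrading to the smoothing width on noisy
ones. Smoothing is internal to detection; all indices are computed on raw
coordinates. The inhale ramp into the plateau is excluded from the cycles.

## Validation design and problem sizes

The test suite validates each estimator against an independent sort-based
percentile oracle (1000 random vectors), checks the baseline-cancellation
identity for `W` to 1e-9, recovers injected rigid transforms exactly
(noiseless) and with the theoretical `noise/√m` translation error scaling
(1000 replicates), and recovers injected variability sources: with a
between-hold SD of 1.0 mm and a between-session SD of 1.5 mm, cohorts of
10^4 holds reproduce `V ≈ 3.29 σ_d` and `W ≈ 3.29 √(σ_d² + σ_s²)` within
5%. The two recovery cohorts are shaped for the statistic being checked —
10 sessions × 1000 holds for `V` (the 5th–95th range of small per-session
samples is biased low, so a stable per-session estimate needs many holds
per session) and 400 sessions × 25 holds for `W` (whose Monte-Carlo error
is dominated by the realized between-session SD) — and run at a reduced
10 Hz sampling with short plateaus, which leaves the position medians
essentially unchanged while keeping the suite fast. Population error
recovery (`Σ₀` = 3.6 mm / `σ₀` = 2.1 mm at 20 patients × 20 holds each)
averages eight Monte-Carlo replicates and pools the three axes, since a
single 20-patient draw estimates a systematic SD with ~16% sampling error.
The nesting property (median `S ≤ V ≤ W` per axis) is checked on 100
seeds of the full 35-hold default cohort.

## Known limitations

* The free-breathing cycle delimiter assumes breathing periods well above
  the 1.5 s separation floor and a reasonably stationary amplitude.
* Rotations are reported about the planning centroid; comparing with
  transforms reported about the isocenter requires the pivot conversion
  above.
* The DLT model carries no lens distortion; for wide-angle optics the
  reconstruction error would be optimistic.
* `V` and `W` are order-statistic ranges: with the clinical 4–5 holds per
  session, `V` systematically underestimates the population 5th–95th
  range (this affects the real analysis equally, not just the package).
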