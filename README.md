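# dibhtrack

Quantitative analysis of external-surface position reproducibility during
spirometer-guided deep-inspiration breath holds (DIBH) in left-breast
radiotherapy.

During DIBH treatments the patient holds a forced inspiration inside a
spirometric gating window (90% of the maximum inspiratory capacity,
tolerance ±0.1 L) so the heart moves away from the irradiated breast. A
constant inspired volume, however, does not guarantee a constant surface
position: the same volume can be reached with different combinations of
thoracic elevation (CC) and abdominal filling (AP). `dibhtrack` provides
the full analysis chain used to quantify this effect from optical tracking
of passive surface markers, for medical physicists and motion-management
researchers:

- **Variability indices.** For a marker coordinate `y(t)` (linac frame,
  mm), per axis:
  - intra-DIBH stability `S_i = P95 − P5` of `y(t)` within one hold `T_i`;
  - intra-DIBH position `d_i = median_{t∈T_i} y(t)`;
  - intrafraction reproducibility `V_n = P95 − P5` of `{d_i : i ∈ S_n}`
    over the holds of session `n` (pre-setup holds corrected by the
    applied couch shift);
  - interfraction reproducibility `W = P95 − P5` of the pooled
    `{d_i − f_n}`, where `f_n = median_i b_i` is the session's
    free-breathing baseline and `b_i` the median position over the
    free-breathing cycles preceding hold `i`;
  - free-breathing stability `F = median |f_n − b_i|`;
  - Pearson correlation of `d_i` with the mean inspired plateau volumes.
- **Rigid registration.** Least-squares (SVD/Kabsch) planning-to-treatment
  registration of the marker constellation, residual 3D displacements
  (median ± IQR), worst-session selection, and the population setup-error
  decomposition `M / Σ / σ` (group mean, SD of per-patient means, RMS of
  per-patient SDs) of the per-field-hold transform parameters.
- **DLT stereo calibration.** 11-parameter Direct Linear Transformation
  calibration on a 7×7 grid phantom acquired at five couch heights (245
  points), two-view triangulation, and reconstruction-error reporting.
- **Breath-hold simulator.** A spirometric cohort generator (quasi-periodic
  free breathing, gated plateaus with drift, between-hold and
  between-session offsets at constant volume, thoracic-CC/abdominal-AP
  volume trade-off, couch setup shifts, rigid session displacements) with
  a full ground-truth sidecar, used to validate every downstream quantity.

## Worked example

```r
library(dibhtrack)

cfg <- simulation_config(seed = 7)   # 7 sessions x 5 holds, 8 markers, 50 Hz
run <- run_pipeline(cfg)
print(run)
```

```
DIBH surface reproducibility summary
====================================

Variability indices, median (q25-q75) over markers [mm]:
  group    index  LL / AP / CC
  all      S      0.98 (0.97-0.98) | 1.22 (1.20-1.70) | 1.22 (1.21-1.69)
  all      V      2.29 (2.16-2.46) | 1.51 (1.43-2.43) | 2.36 (2.19-2.80)
  all      W      5.24 (4.76-5.32) | 4.29 (4.21-6.52) | 4.03 (3.87-5.50)
  all      F      0.03 (0.02-0.04) | 0.06 (0.04-0.07) | 0.05 (0.04-0.06)
  ...
Volume correlation, marker-median Pearson r: LL -0.20, AP 0.23, CC 0.21
```

Reading the output: within a single hold the surface is stable to about
1 mm (`S`), holds within one session scatter by about 2 mm (`V`), and
sessions differ by 4–5 mm (`W`) *even though every hold was performed at
the same inspired volume* — the free-breathing baseline `F` below 0.1 mm
confirms the baseline subtraction is sound, and the small Pearson values
show the residual motion is uncorrelated with the volume actually held.
`run$registration` carries the planning-to-treatment rigid transform,
residual displacements and the worst session; `run_cohort_study()` repeats
the pipeline over several patients and adds the `M/Σ/σ` population table.

Stereo calibration:

```r
rig <- default_stereo_rig()
v <- generate_phantom_views(rig$camera_a, rig$camera_b, noise_px = 0.4, seed = 2)
cam_a <- dlt_calibrate(v$world, v$image_a)
cam_b <- dlt_calibrate(v$world, v$image_b)
rec <- triangulate(cam_a, cam_b, v$image_a, v$image_b)
reconstruction_error_report(rec, v$world)$median_mm
#> [1] 1.018105
```

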