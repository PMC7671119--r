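# vromm

Marker-based videogrammetry for fish feeding biomechanics: from
multi-camera 2D marker tracks to 3D skeletal kinematics and muscle strain,
with the validation statistics for skin-marker ("external") strain
measurement built in.

Suction-feeding fishes expand the mouth cavity in tens of milliseconds by
elevating the neurocranium, retracting the pectoral girdle and depressing
the hyoid. `vromm` reconstructs this from high-speed video of skin-sutured
bead markers and answers two kinds of question:

* **Kinematics** — how far did the urohyal and cleithrum retract and
  depress relative to the body, and how much did the neurocranium elevate?
* **Muscle strain** — how much, and how fast, did a muscle spanned by a
  marker pair (e.g. the sternohyoideus, SH) shorten, relative to peak
  gape?

It is aimed at researchers running two- or three-camera marker studies who
want a scriptable, testable pipeline instead of a GUI animation workflow.

## What it computes

| Stage | Method |
|---|---|
| Camera calibration | 11-parameter DLT, linear least squares from ≥6 non-coplanar control points: `u = (L₁X+L₂Y+L₃Z+L₄)/(L₉X+L₁₀Y+L₁₁Z+1)`, likewise `v` |
| Triangulation | linear least-squares DLT inversion, ≥2 views, RMS reprojection residual per frame |
| Rigid-body / body-plane pose | SVD orthogonal Procrustes (det +1), ≥3 markers per frame; body plane (≥5 markers) doubles as the anatomical frame (X rostral, Y left, Z dorsal) |
| Tracking precision | SD over time of pairwise within-body marker distances (mean over pairs) |
| Kinematics | excursions as baseline-zeroed −ΔX (retraction) and −ΔZ (depression) in the body frame; elevation as the Z-Y-X Euler Y angle of R_body⁻¹R_neuro, dorsal positive |
| Muscle strain | s(t) = 100·(Lᵢ − L(t))/Lᵢ (shortening positive); velocity = −d(L/Lᵢ)/dt in Lᵢ·s⁻¹, zero-phase low-pass + central differences |
| Method validation | per-trial OLS of external on internal strain: accuracy = slope vs 1, precision = residual RMSE, pooled over trials |

A synthetic suction-strike generator (`strike_params()`,
`simulate_strike()`, `make_camera_rig()`, `render_observations()`)
provides exact ground truth for every stage, so the whole pipeline is
testable offline.

## Worked example

Simulate one strike, render three noisy camera views, and run the full
pipeline:

```r
library(vromm)
p <- strike_params()          # defaults: 500 fps, 7.2% SH strain, 15 ms lag
truth <- simulate_strike(p)
rig <- make_camera_rig(3)
obs <- render_observations(truth, rig)   # 0.75 px tracking noise
rep <- process_trial(obs, rig, truth$defs, truth$roles)
print(rep)
```

```
trial_report: 101 frames; peak gape at frame 51 
                        variable peak peak_frame latency_ms
1             urohyal_retraction 2.10         52          2
2             urohyal_depression 3.11         51          0
3           cleithrum_retraction 1.10         54          6
4           cleithrum_depression 1.01         50         -2
5                      elevation 8.04         52          2
6                 sh_peak_strain 7.20         59         16
7               sh_peak_velocity 3.51         52          2
8       sh_velocity_at_peak_gape 3.34         51          0
...
```

Reading this: the urohyal retracted 2.1 mm and depressed 3.1 mm relative
to the body plane, the neurocranium elevated 8.0°, and the SH shortened by
a peak of 7.2 % of its initial length 16 ms after peak gape — all within
noise of the generator's ground truth (2, 3, 8, 7.2, 15). Tracking
precision and the validation experiment:

```r
print(rep$precision)
#> Tracking precision over 6 marker pairs
#>   mean SD of pairwise distances: 0.175 mm

run_validation_experiment(n_strikes = 7, skin_slip_alpha = 0.90,
                          strain_noise_sd = 0.5, seed = 1)
#> External-vs-internal strain validation over 7 trials
#>   accuracy (slope): 0.899 +/- 0.0065 (SEM)
#>   precision (RMSE): 0.504 +/- 0.016 % strain
#>   underestimation margin: 10.1 %
```

The regression slope recovers the simulated skin-slip attenuation (0.90):
external markers underestimate true strain by ~10 %, with a precision set
by the injected strain noise.

File-based trials run from a YAML config (`run_trial("trial.yaml")`), and
a thin CLI wraps the same functions:
`Rscript inst/cli/vromm.R simulate --out dir`, `... run --config
trial.yaml`, `... validate --strikes 7 --alpha 0.9 --noise 0.5`. See the
methods vignette (`vignettes/vromm-methods.Rmd`) for conventions,
filtering choices and limitations.

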