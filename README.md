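# arnav

Hardware-free computation core for **markerless augmented-reality surgical
navigation**. In the deployment this package models, a head-mounted display
overlays a preoperative 3-D organ model on the patient while an RGB-D
camera tracks the organ: each depth frame is cropped with a segmentation
mask, registered to the organ surface model with point-to-point ICP, and —
because segmentation + registration cost about one frame interval of
latency — the *next* frame's pose is pre-computed by Double Exponential
Smoothing of the registration stream, so the overlay never lags. `arnav`
implements that whole loop, the multi-device calibration chain, the
evaluation metrics and the hyperparameter-tuning methodology, and replaces
the cameras, trackers and phantom with a deterministic simulator, so the
entire system can be exercised, tuned and validated on a laptop.

Who it is for: researchers developing or evaluating image-guided AR
navigation pipelines who need a reproducible, instrumented stand-in for
the hardware loop, and anyone who needs the individual components —
SE(3)/quaternion transform algebra, pose forecasting, ICP registration,
Horn's fiducial alignment, registration metrics, response-surface tuning —
as plain R functions.

## The methods at the core

* **Registration** `T_R_L(t)`: masked depth pixels are back-projected to a
  target cloud, the model surface is sampled (5000 points) as the source
  cloud, both are voxel-downsampled at 5 mm, and point-to-point ICP
  (10 mm correspondence threshold, Kabsch/SVD update, warm-started from
  the previous frame) aligns them. The source cloud is back-face-culled at
  the pose estimate, since a depth camera only sees one side of the organ.
* **Forecasting**: Holt's Double Exponential Smoothing generalized to
  poses. Translation: `S_t = α τ_t + (1-α)(S_{t-1} + b_{t-1})`,
  `b_t = γ (S_t - S_{t-1}) + (1-γ) b_{t-1}`, forecast `τ̂ = S + m b`.
  Rotation: the quaternion analogue with SLERP as the convex blend,
  `S_t = slerp(S_{t-1} b_{t-1}, Θ_t, α)`,
  `b_t = slerp(b_{t-1}, S_{t-1}⁻¹ S_t, γ)`, forecast `Θ̂ = S b^m`.
  With `m = 1` this bypasses one frame interval (0.1 s) of latency.
* **Calibration chain**: `T_H_R = T_H_C ∘ T_R_C⁻¹` from a chart observed
  by both devices; `T_R_L(0) = T_H_R⁻¹ ∘ T_H_L(0)` turns the user's
  display-space pre-alignment into the ICP initialization;
  `T_H_L(t) = T_H_R ∘ T_R_L(t)` is the display transform. The
  sensor-to-reference alignment `T_E_R` comes from Horn's closed-form
  quaternion-eigenvector fiducial registration.
* **Evaluation**: target registration error
  `TRE = sqrt(mean_i ‖r_i - (T_E_R ∘ T_R_L) p_i‖²)`, symmetric Chamfer
  distance between the detected and registered clouds, mask IoU,
  visibility factor (occlusion grading), forecast translation/rotation
  errors (mm / degrees between quaternions) and success rates.
* **Tuning**: a full-factorial sweep of `(α, γ)` (0.0–1.0 in 0.1 steps,
  121 cells per channel), a quadratic response-surface fit by least
  squares, and closed-form minimization over the unit box.

## Worked example

Simulate the fastest turning-wheel scenario (10 s per turn, phantom centre
100 mm off-axis, 0.1 s frames, pose noise 0.5 mm / 0.2°), run the full
navigation loop, and summarize:

```r
library(arnav)

scn <- wheel_scenario(period_s_per_turn = 10, duration_frames = 100, seed = 42)
run <- simulate_wheel_run(scn)                   # mesh + frames + calibration
out <- run_navigation(run, run_config(alpha_rot = 0.8, gamma_rot = 0.6))
str(out$summary)
#> $ mean_chamfer_mm     : num 1.69
#> $ mean_chamfer_full_mm: num 8.74
#> $ median_te_mm        : num 1.6
#> $ median_re_deg       : num 1.01
#> $ mean_tre_mm         : num 2.55
#> $ frame_success_pct   : num 100
#> $ run_success         : logi TRUE
```

`mean_chamfer_mm` (1.69 mm) is the frame-averaged symmetric Chamfer
distance between the cropped target cloud and the camera-facing part of
the registered model cloud — the registration-quality monitor; the
full-cloud variant (8.74 mm) includes the self-occluded far side of the
organ and is reported for completeness. `median_te_mm` / `median_re_deg`
score the one-step forecasts against the next frame's registration
*including* ICP jitter; forecasting the ground-truth motion directly
isolates the smoother:

```r
hp <- wheel_optimum_hyperparameters(10)          # tuned (alpha, gamma) per channel
fc <- forecast_trajectory(wheel_trajectory(scn),
                          hp$alpha_tau, hp$gamma_tau,
                          hp$alpha_rot, hp$gamma_rot, m = 1)
median(fc$te_mm); median(fc$re_deg)
#> [1] 1.432
#> [1] 0.262
```

i.e. the forecaster predicts the next frame's pose to ~1.4 mm and ~0.26°
at the fastest wheel speed — comfortably below the 2 mm / 1.5° regime that
makes latency bypassing viable.

A thin CLI over the same functions ships in `inst/cli/arnav`
(subcommands `simulate`, `register`, `forecast`, `tune`, `evaluate`,
`run`), e.g.:

```sh
arnav=$(Rscript -e 'cat(system.file("cli", "arnav", package = "arnav"))')
Rscript $arnav simulate --period 10 --frames 300 --seed 1 --out run_dir
Rscript $arnav run --run run_dir --out results_dir
```

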