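---
title: "Markerless AR navigation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markerless AR navigation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arnav)
```

`arnav` is the computation core of a markerless augmented-reality
navigation system for open surgery, rebuilt as a hardware-free, fully
simulated package. The intended deployment couples a head-mounted display
(frame `H`) used for visualization with an RGB-D camera (frame `R`) used
for 3-D sensing; a preoperative organ surface model (`L`) is continuously
registered to the camera's masked depth stream and shown overlaid on the
real organ, while an external tracking system (`E`) provides reference
measurements for evaluation only. This vignette explains the models
implemented, the parameters that matter, what the simulator does and does
not emulate, and the design decisions taken where the problem left real
choices.

## Coordinate conventions

All transforms are rigid (unit quaternion `w, x, y, z` plus a translation
in millimetres) and use the column-vector convention `p' = R p + tau`.
`T_A_B` denotes the map taking coordinates *from* frame `B` *to* frame
`A`, so chains compose right-to-left:

* device offset from a commonly observed calibration chart:
  `T_H_R = T_H_C ∘ T_R_C⁻¹` (`chain_offset()`);
* sensor-frame initialization from the user's display-space pre-alignment:
  `T_R_L(0) = T_H_R⁻¹ ∘ T_H_L(0)` (`init_registration()`);
* display transform of the registered pose:
  `T_H_L(t) = T_H_R ∘ T_R_L(t)` (`to_display()`).

Because chain formulas transcribed between row- and column-vector
conventions are a classic source of silent order bugs, every chain is
pinned by tests against a 4x4 matrix oracle and by the chain-closure
property on synthetic scenes with known ground truth (100 random scenes,
1e-9 tolerance). All binary quaternion operations sign-align their second
argument first, so `q` and `-q` are interchangeable everywhere.

## Registration

Each frame supplies a depth map (mm), pinhole intrinsics and a binary
organ mask (in deployment produced by a promptable segmentation model plus
a mask tracker; here by the simulator — segmentation inference is an input
contract, not part of this package). The target cloud is the back-projection
of the masked pixels; the source cloud samples the organ model surface
area-uniformly (default 5000 points, seeded). Both clouds are
voxel-downsampled at 5 mm and aligned by point-to-point ICP with

* nearest-neighbour correspondences source → target (exact uniform-grid
  search), pairs beyond the 10 mm threshold rejected,
* the closed-form Kabsch/SVD update on the corresponded pairs,
* termination on a relative inlier-RMSE change below `rel_tol = 1e-6` or
  `max_iter = 50`, returning the best transform seen.

Two accuracy-critical refinements were added after measuring the plain
pipeline's behaviour on rendered data:

1. **Back-face culling of the source cloud** (`cull_backfacing()`): a depth
   camera sees one side of the organ. Keeping the full model cloud lets
   far-side points within the distance threshold grab spurious
   correspondences near the silhouette and bias the solve. The source is
   therefore restricted to points whose outward normal faces the camera at
   the current pose estimate.
2. **Optional refinement passes** (`register_frame(refine_passes = )`):
   with both clouds at 5 mm resolution, ICP exhibits discretization-locked
   fixed points a few millimetres from the generating pose — the iteration
   stalls although the true pose has a lower objective. Re-culling the
   visibility at the intermediate estimate and re-registering the full
   model sampling against a 1 mm-voxel target removes this; two passes
   reach ~0.3 mm / ~0.4° on noise-free rendered frames at full visibility.

The tracking loop itself runs the coarse stage only (about 60 ms per frame
on one CPU): tracking is warm-started from the previous frame, and the
monitored cloud-to-cloud agreement is insensitive to the residual
millimetre-scale pose slack. A frame whose mask yields no target points
holds the last pose and is flagged, so the loop survives dropouts and the
failure is visible to the success-rate metric.

## Forecasting

The processing chain (segmentation, tracking, registration) costs roughly
one frame interval of latency; the displayed pose would always be one
frame old. Double Exponential Smoothing (Holt's method) of the
registration stream pre-computes the next frame's pose instead. The
translation channel is the textbook vector recursion with data smoothing
factor `alpha` and trend smoothing factor `gamma`; the rotation channel is
its quaternion analogue with SLERP as the convex blend and composition as
the additive structure:

* level: `S_t = slerp(S_{t-1} * b_{t-1}, Theta_t, alpha)`
* trend: `b_t = slerp(b_{t-1}, S_{t-1}⁻¹ * S_t, gamma)`
* m-step forecast: `tau = S + m b`, `Theta = S * b^m`.

The printed recursions admit more than one reading of where the convex
weights attach; this implementation places `alpha` on the observation and
`gamma` on the level innovation, the only reading under which
constant-velocity translation streams and constant-increment rotation
streams are forecast *exactly* (to machine precision) for every
`(alpha, gamma)` in `(0, 1]²` — that exactness is enforced by tests, so
an argument-order regression cannot pass. Initialization follows the
first two frames (`S_0 = x_0`, `b_0 = x_1 - x_0`, and the quaternion
analogue `b_0 = Theta_0⁻¹ Theta_1`); the first scored forecast is issued
at the second frame. The horizon `m` is real-valued (fractional horizons
interpolate the forecast; `quat_power` handles fractional exponents), with
`m = 1` — one frame interval, 0.1 s — the default. Sign alignment before
every blend keeps the recursion continuous across the quaternion double
cover; the exactness property fails at the ±q boundary without it.

Forecast quality is scored against the registration of the subsequent
frame: translation error as Euclidean distance (mm) and rotation error as
the angular distance between quaternions — the rotation angle
`2·atan2(‖vec‖, |w|)` of the relative quaternion, in degrees. (The
quaternion-space half-angle reading `acos|⟨qa,qb⟩|` exists in the
literature; it is available behind `half_angle = TRUE`, and the atan2 form
is used because `acos` of a near-unit dot product cannot resolve angles
below ~1e-6 degrees.)

## Hyperparameter tuning

`doe_sweep()` runs the full factorial design over `(alpha, gamma)` — by
default 0.0 to 1.0 in 0.1 steps, 121 cells per channel — on an observed
trajectory, recording mean (and median) translation and rotation errors;
the translation error depends only on the translation-channel factors and
vice versa, so one sweep serves both channels, which are then fitted and
minimized separately. `fit_response_surface()` fits the full quadratic
`b0 + b1 a + b2 g + b3 a² + b4 g² + b5 a g` by ordinary least squares
(cubic terms neglected), and `minimize_surface()` returns the stationary
point when the Hessian is positive definite and interior, otherwise the
closed-form minimum over the box boundary, flagging which case occurred.
Both the continuous minimizer and its snap to the nearest design level are
reported, since a printed optimum table may use either convention. The
mean error is the sweep objective; medians are logged alongside because
distribution summaries of forecast errors are conventionally reported as
medians with quartiles.

The per-scenario optima used by the navigation defaults are embedded as
`wheel_optimum_hyperparameters()`: `alpha_tau = gamma_tau = 0.7` for all
three wheel speeds, and `(alpha, gamma)` of the rotation channel moving
from `(0.7, 0.3)` at 30 s/turn to `(0.8, 0.6)` at 10 s/turn — faster
motion favours heavier trend adaptation.

## Evaluation metrics

* **TRE** (`tre()`): RMS Euclidean distance between reference landmarks and
  model landmarks mapped through registration and the sensor-to-reference
  alignment. RMS, not mean distance — the two are often conflated.
* **Chamfer distance** (`chamfer_distance()`): symmetric average of the two
  directed mean nearest-neighbour distances. The navigation loop monitors
  it between the target cloud and the *camera-facing subset* of the
  registered model cloud: with a one-sided sensor the full-cloud value is
  dominated by the self-occluded far side (tens of millimetres at perfect
  alignment for a ~60 mm-thick organ) and measures geometry, not
  registration. Both values are recorded per frame (`chamfer_mm`,
  `chamfer_full_mm`).
* **IoU** and **visibility factor**: mask overlap over union (1 for two
  empty masks), and the percentage of reference-mask pixels surviving an
  occlusion, which grades the resection scenarios.
* **Success rate**: percentage of trials that converged with final error
  below a threshold (default 20 mm, configurable — the criterion in the
  source literature is cited rather than restated, so the threshold is
  always reported with results).

Horn's quaternion eigenvector method (`horn_fiducial_registration()`)
provides the closed-form fiducial alignment `T_E_R` between the sensor and
the reference tracker: the optimal rotation is the largest-eigenvalue
eigenvector of the 4x4 correlation matrix — the global optimum, verified
in tests both against an independent SVD solver and against 1000 randomly
perturbed alternatives on noisy fiducials. No scale is estimated; the
devices share metric units. Collinear fiducial sets are rejected by a rank
check with an explicit error.

## The simulator

The simulator generates every input the experiments assume, each
bit-reproducible from `(seed, config)`:

* **Phantom** (`make_phantom_mesh()`): a watertight UV-sphere triangulation
  of a radially deformed ellipsoid, ~150 x 100 x 60 mm, with two broad
  lobes of unequal amplitude plus ten smaller seeded bumps and dents
  emulating the ridges and impressions of a liver surface. The relief is
  functional, not cosmetic: a smooth ellipsoid viewed from one side leaves
  the tangential pose directions nearly unobservable to ICP.
* **Motion** (`wheel_trajectory()`): a turning wheel at 30 / 15 / 10 s per
  turn (or static), the phantom centre 100 mm off the vertical axis so the
  motion mixes rotation and translation, sampled at 0.1 s — the pipeline's
  total latency. The per-frame rotation increment is constant to 1e-12,
  which is exactly the premise under which the smoothing recursions are
  exact. The axis offset value is a simulator choice (only "off-center" is
  prescribed by the study design).
* **Noise**: per-frame Gaussian pose noise, `sigma_t = 0.5` mm per axis and
  `sigma_r = 0.2°` about random axes. These defaults are a choice: they
  put the simulated one-step forecast-error medians in the
  millimetre/sub-degree regime that motivated forecasting in the first
  place. Both are printed in every scenario record.
* **Rendering** (`render_depth_frame()`): perspective-correct triangle
  z-buffer rasterization into a 640 x 480, 600 px-focal-length depth frame
  ~400 mm from the phantom, mask = pixels covered. No depth noise, holes,
  motion blur or specular dropout are simulated — sensor pathology enters
  only through the pose-noise channel.
* **Occlusion** (`apply_occlusion()`): vertical half-plane mask cuts
  (resection analogues) reaching target visibility factors
  100 / 85 / 66 / 52 / 35 / 15 % within ±2 %. The cut removes mask, not
  depth — occlusion means the segmentation stops reporting the organ, not
  that the sensor stops seeing it.
* **Calibration scenes** (`make_calibration_scene()`): random device/chart
  poses with chart-corner fiducials expressed in each frame, plus a user
  pre-alignment perturbed by up to 100 mm / 15° (the hand-placement
  budget). The navigation runs themselves default to a 10 mm / 5°
  pre-alignment error: a 100 mm initial offset yields zero ICP
  correspondences at a 10 mm threshold, and the deployed workflow's
  human-in-the-loop pre-alignment check (out of scope here) is what
  guarantees a usable starting point.

What passing simulated tests does **not** show: robustness to real sensor
noise spectra, imperfect segmentation masks (the simulator's masks are
exact silhouettes), specular or wet-surface depth artefacts, soft-tissue
deformation (the registration is rigid by design; non-rigid refinement is
explicitly downstream work), tools or smoke in the scene, and network
latency between devices.

## Numerical choices

Quaternions are renormalized after every operation (inputs off unit norm
by more than 1e-6 are rejected rather than silently fixed); rotation
matrices entering `quat_from_matrix()` must be proper within 1e-6. SLERP
falls back to a normalized linear blend within 1e-10 of parallelism.
Voxel grids are anchored at the origin (`floor(p / voxel)`), making
downsampling deterministic and idempotent on sparse clouds. ICP tracks and
returns the best iterate rather than the last, and reports
`converged = FALSE` only for the no-correspondence failure, which the
pipeline maps to hold-last-pose. The response-surface minimizer treats a
non-positive-definite Hessian via the exact boundary solve instead of a
numerical optimizer, so degenerate (flat or saddle) surfaces cannot
produce spurious interior optima.

## Problem sizes

The package's own test and acceptance runs use the study geometry at full
scale: 300-frame scenarios at 640 x 480 rendering, 5000-point model
sampling, the 121-cell tuning design, 100-scene chain-closure checks,
50-trial ICP recovery and 1000-alternative Horn optimality checks. A full
300-frame tracking scenario takes roughly 20 s on one CPU.
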