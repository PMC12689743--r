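# End-to-end navigation loop: crop -> downsample -> ICP -> smoothing update
# -> one-frame-ahead forecast -> display transform, over a simulated or
# file-backed frame sequence, plus the tuning and evaluation drivers.

#' Navigation run configuration
#'
#' Consolidates the pipeline constants: 5 mm voxel resolution, 1 cm ICP
#' correspondence threshold, 5000 model sample points, per-channel smoothing
#' factors, forecast horizon and frame interval.
#'
#' @param voxel_mm voxel size for downsampling (mm).
#' @param icp_threshold_mm ICP correspondence threshold (mm).
#' @param model_samples points sampled on the model surface.
#' @param alpha_tau,gamma_tau translation-channel smoothing factors.
#' @param alpha_rot,gamma_rot rotation-channel smoothing factors.
#' @param m forecast horizon in frames.
#' @param frame_interval_s frame interval (timestamps only).
#' @param success_threshold_mm success threshold on the final error.
#' @param seed RNG seed (model sampling).
#' @param max_iter,rel_tol ICP stopping parameters.
#' @return a `run_config` list.
#' @export
run_config <- function(voxel_mm = 5, icp_threshold_mm = 10, model_samples = 5000,
                       alpha_tau = 0.7, gamma_tau = 0.7,
                       alpha_rot = 0.7, gamma_rot = 0.3,
                       m = 1L, frame_interval_s = 0.1,
                       success_threshold_mm = 20, seed = 1L,
                       max_iter = 50L, rel_tol = 1e-6) {
  stopifnot(voxel_mm > 0, icp_threshold_mm > 0, model_samples >= 1, m >= 1)
  for (x in c(alpha_tau, gamma_tau, alpha_rot, gamma_rot))
    check_smoothing_factor(x, "smoothing factor")
  structure(list(voxel_mm = voxel_mm, icp_threshold_mm = icp_threshold_mm,
                 model_samples = as.integer(model_samples),
                 alpha_tau = alpha_tau, gamma_tau = gamma_tau,
                 alpha_rot = alpha_rot, gamma_rot = gamma_rot,
                 m = as.integer(m), frame_interval_s = frame_interval_s,
                 success_threshold_mm = success_threshold_mm,
                 seed = as.integer(seed), max_iter = as.integer(max_iter),
                 rel_tol = rel_tol),
            class = "run_config")
}

#' Simulate a complete navigation run
#'
#' Builds every input the navigation loop consumes for one turning-wheel
#' scenario: the phantom mesh, the (noisy) ground-truth pose sequence, a
#' per-frame depth/mask renderer, a display-device offset, a perturbed user
#' pre-alignment and three surface landmarks for the target registration
#' error. Frames are rendered lazily (`frame_fn(t)`, 0-based) so long runs
#' never hold all depth maps in memory; pass `out_dir` to materialize the
#' run directory on disk instead.
#'
#' @param scenario a [wheel_scenario()].
#' @param mesh phantom mesh (default: [make_phantom_mesh()] with the
#'   scenario seed).
#' @param intrinsics a [camera_intrinsics()].
#' @param camera_distance_mm camera stand-off (default 400 mm).
#' @param occlusion `NULL`, a scenario name from [occlusion_scenarios()],
#'   or a list with `target_visibility_pct` and `keep_side`.
#' @param prealign_t_mm,prealign_r_deg magnitude of the simulated
#'   pre-alignment error (defaults 10 mm / 5 degrees, a pre-alignment
#'   accepted by the quality-control step; the raw hand-placed bound is
#'   100 mm, see [make_calibration_scene()]).
#' @param out_dir optional directory to write the run to (see
#'   [write_run_dir()]).
#' @return a `nav_run` list (see [run_navigation()]).
#' @export
simulate_wheel_run <- function(scenario, mesh = NULL,
                               intrinsics = default_intrinsics(),
                               camera_distance_mm = 400, occlusion = NULL,
                               prealign_t_mm = 10, prealign_r_deg = 5,
                               out_dir = NULL) {
  stopifnot(inherits(scenario, "wheel_scenario"))
  if (is.null(mesh)) mesh <- make_phantom_mesh(scenario$seed)
  if (is.character(occlusion)) {
    sc <- occlusion_scenarios()
    i <- match(occlusion, sc$name)
    if (is.na(i)) stop("unknown occlusion scenario: ", occlusion)
    occlusion <- if (sc$name[i] == "reference") NULL else
      list(target_visibility_pct = sc$target_visibility_pct[i],
           keep_side = sc$keep_side[i])
  }
  traj <- wheel_trajectory(scenario)
  n <- nrow(traj)
  cam_offset <- rigid_transform(translation = c(0, 0, camera_distance_mm))
  gt_poses <- lapply(seq_len(n), function(i)
    rt_compose(cam_offset, trajectory_pose(traj, i)))
  trajectory_gt <- trajectory_from_transforms(gt_poses, dt_s = scenario$dt_s)
  frame_fn <- function(t) {    # 0-based frame index
    fr <- render_depth_frame(mesh, trajectory_pose(traj, t + 1L),
                             intrinsics, camera_distance_mm)
    if (!is.null(occlusion))
      fr <- apply_occlusion(fr, occlusion$target_visibility_pct,
                            keep_side = occlusion$keep_side)
    fr
  }
  T_H_R <- with_seed(scenario$seed + 7919L, random_pose(t_range = 300))
  prealign_R <- with_seed(scenario$seed + 104729L,
                          perturb_pose(gt_poses[[1]], prealign_t_mm, prealign_r_deg))
  V <- mesh$vertices
  landmarks <- V[c(which.max(V[, 1]), which.min(V[, 1]), which.max(V[, 2])), ,
                 drop = FALSE]
  run <- structure(list(mesh = mesh, intrinsics = intrinsics,
                        camera_distance_mm = camera_distance_mm,
                        n_frames = n, frame_fn = frame_fn,
                        trajectory_gt = trajectory_gt,
                        wheel_trajectory = traj,
                        scenario = scenario, occlusion = occlusion,
                        calibration = list(T_H_R = T_H_R),
                        prealign_T_H_L0 = to_display(prealign_R, T_H_R),
                        landmarks = landmarks),
                   class = "nav_run")
  if (!is.null(out_dir)) {
    write_run_dir(run, out_dir)
    run$dir <- out_dir
  }
  run
}

#' Write / read a navigation run directory
#'
#' Layout: `mesh.ply`, `frames/NNNN_depth.npy` (float32 mm) and
#' `frames/NNNN_mask.png`, `intrinsics.json`, `trajectory_gt.csv`,
#' `calibration.json` (device offset and pre-alignment) and
#' `scenario.yaml` (scenario, camera distance, landmarks).
#'
#' @param run a `nav_run`.
#' @param dir run directory.
#' @export
write_run_dir <- function(run, dir) {
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  write_mesh(run$mesh, file.path(dir, "mesh.ply"))
  write_intrinsics_json(run$intrinsics, file.path(dir, "intrinsics.json"))
  write_trajectory_csv(run$trajectory_gt, file.path(dir, "trajectory_gt.csv"))
  write_calibration_json(c(run$calibration,
                           list(prealign_T_H_L0 = run$prealign_T_H_L0)),
                         file.path(dir, "calibration.json"))
  scn <- unclass(run$scenario)
  scn$period_s_per_turn <- ifelse(is.finite(scn$period_s_per_turn),
                                  scn$period_s_per_turn, 0)  # 0 = static
  yaml::write_yaml(list(scenario = scn,
                        camera_distance_mm = run$camera_distance_mm,
                        occlusion = run$occlusion,
                        landmarks = apply(run$landmarks, 1, as.list)),
                   file.path(dir, "scenario.yaml"))
  for (t in seq_len(run$n_frames) - 1L) {
    fr <- run$frame_fn(t)
    write_depth(fr$depth, file.path(dir, "frames", sprintf("%04d_depth.npy", t)))
    write_mask_png(fr$mask, file.path(dir, "frames", sprintf("%04d_mask.png", t)))
  }
  invisible(dir)
}

#' @param dir run directory.
#' @rdname write_run_dir
#' @return `read_run_dir`: a `nav_run` whose `frame_fn` reads frames from
#'   disk on demand.
#' @export
read_run_dir <- function(dir) {
  need <- c("mesh.ply", "intrinsics.json", "calibration.json", "scenario.yaml")
  absent <- need[!file.exists(file.path(dir, need))]
  if (length(absent))
    stop("run directory is missing: ", paste(absent, collapse = ", "))
  mesh <- read_mesh(file.path(dir, "mesh.ply"))
  intr <- read_intrinsics_json(file.path(dir, "intrinsics.json"))
  calib <- read_calibration_json(file.path(dir, "calibration.json"))
  meta <- yaml::read_yaml(file.path(dir, "scenario.yaml"))
  scn <- do.call(wheel_scenario, meta$scenario[setdiff(names(meta$scenario), NULL)])
  gt_path <- file.path(dir, "trajectory_gt.csv")
  trajectory_gt <- if (file.exists(gt_path)) read_trajectory_csv(gt_path) else NULL
  depth_files <- sort(list.files(file.path(dir, "frames"),
                                 pattern = "_depth\\.(npy|png)$", full.names = TRUE))
  if (length(depth_files) == 0) stop("run directory has no frames")
  frame_fn <- function(t) {
    dp <- depth_files[t + 1L]
    mask_path <- sub("_depth\\.(npy|png)$", "_mask.png", dp)
    depth_frame(read_depth(dp), intr,
                mask = if (file.exists(mask_path)) read_mask_png(mask_path) else NULL)
  }
  landmarks <- if (!is.null(meta$landmarks))
    do.call(rbind, lapply(meta$landmarks, unlist)) else NULL
  structure(list(mesh = mesh, intrinsics = intr,
                 camera_distance_mm = meta$camera_distance_mm,
                 n_frames = length(depth_files), frame_fn = frame_fn,
                 trajectory_gt = trajectory_gt, wheel_trajectory = NULL,
                 scenario = scn, occlusion = meta$occlusion,
                 calibration = calib["T_H_R"],
                 prealign_T_H_L0 = calib$prealign_T_H_L0,
                 landmarks = landmarks, dir = dir),
            class = "nav_run")
}

#' Run the navigation loop over a frame sequence
#'
#' For every frame: back-project the masked depth pixels, voxel-downsample,
#' register the model cloud with point-to-point ICP initialized at the
#' previous pose (frame 0: the pre-alignment mapped through the calibration
#' chain), advance the smoothing states, forecast the pose `m` frames ahead
#' and derive the display-space transform. A frame with an empty target
#' cloud holds the last pose and is flagged. The forecast stored for frame
#' `t` was computed from observations up to `t - m` only.
#'
#' Per-frame Chamfer distances are monitored between the downsampled target
#' cloud and the camera-facing (back-face-culled) subset of the registered
#' model cloud (`chamfer_mm`); the full-cloud value, which includes the
#' self-occluded far side of the organ, is reported alongside
#' (`chamfer_full_mm`).
#'
#' @param run a `nav_run` (from [simulate_wheel_run()] or [read_run_dir()])
#'   or a run-directory path.
#' @param config a [run_config()].
#' @return list with `frames` (per-frame records: registered / forecast /
#'   display poses, forecast errors `te_mm`/`re_deg`, Chamfer distances,
#'   `tre_mm` and pose errors vs ground truth when available, convergence
#'   flags) and `summary` (means, medians and the success rate).
#' @export
run_navigation <- function(run, config = run_config()) {
  if (is.character(run)) run <- read_run_dir(run)
  stopifnot(inherits(run, "nav_run"), inherits(config, "run_config"))
  model <- sample_mesh_points(run$mesh, config$model_samples, config$seed)
  normals <- attr(model, "normals")
  T_H_R <- run$calibration$T_H_R
  if (is.null(run$prealign_T_H_L0) || is.null(T_H_R))
    stop("run is missing the pre-alignment or the device calibration")
  prev <- init_registration(run$prealign_T_H_L0, T_H_R)
  n <- run$n_frames
  m <- config$m
  has_gt <- !is.null(run$trajectory_gt)
  pending <- vector("list", n)              # forecast targeted at each frame
  st <- sr <- NULL
  reg_list <- vector("list", n)
  rec <- data.frame(frame = seq_len(n) - 1L,
                    time_s = (seq_len(n) - 1L) * config$frame_interval_s,
                    converged = FALSE, fitness = NA_real_,
                    inlier_rmse_mm = NA_real_,
                    chamfer_mm = NA_real_, chamfer_full_mm = NA_real_,
                    te_mm = NA_real_, re_deg = NA_real_,
                    tre_mm = NA_real_, gt_te_mm = NA_real_, gt_re_deg = NA_real_)
  for (t in seq_len(n) - 1L) {
    fr <- run$frame_fn(t)
    target <- backproject_and_crop(fr)
    if (nrow(target) == 0) {
      res <- icp_result(prev, Inf, 0, 0L, FALSE)
      target_ds <- NULL
    } else {
      target_ds <- voxel_downsample(target, config$voxel_mm)
      src <- voxel_downsample(cull_backfacing(model, prev), config$voxel_mm)
      res <- icp_point_to_point(src, target_ds, init = prev,
                                threshold_mm = config$icp_threshold_mm,
                                max_iter = config$max_iter,
                                rel_tol = config$rel_tol)
    }
    registered <- res$transform
    prev <- registered
    reg_list[[t + 1L]] <- registered
    rec$converged[t + 1L] <- res$converged
    rec$fitness[t + 1L] <- res$fitness
    rec$inlier_rmse_mm[t + 1L] <- res$inlier_rmse
    if (!is.null(target_ds)) {
      pts_cam <- rt_apply(registered, model)
      n_cam <- normals %*% t(quat_to_matrix(registered$rotation))
      vis <- rowSums(n_cam * pts_cam) < 0
      if (sum(vis) > 0)
        rec$chamfer_mm[t + 1L] <-
          chamfer_distance(pts_cam[vis, , drop = FALSE], target_ds)
      rec$chamfer_full_mm[t + 1L] <- chamfer_distance(pts_cam, target_ds)
    }
    # smoothing + forecast (begins with the second frame)
    if (t == 1L) {
      p0 <- reg_list[[1L]]; p1 <- reg_list[[2L]]
      st <- des_update_translation(
        des_init_translation(p0$translation, p1$translation,
                             config$alpha_tau, config$gamma_tau),
        p1$translation)
      sr <- des_update_rotation(
        des_init_rotation(p0$rotation, p1$rotation,
                          config$alpha_rot, config$gamma_rot),
        p1$rotation)
    } else if (t > 1L) {
      st <- des_update_translation(st, registered$translation)
      sr <- des_update_rotation(sr, registered$rotation)
    }
    if (t >= 1L && t + m <= n - 1L)
      pending[[t + m + 1L]] <- des_forecast(st, sr, m)
    if (!is.null(pending[[t + 1L]])) {
      err <- forecast_errors(registered, pending[[t + 1L]])
      rec$te_mm[t + 1L] <- err$te_mm
      rec$re_deg[t + 1L] <- err$re_deg
    }
    if (has_gt) {
      gt <- trajectory_pose(run$trajectory_gt, t + 1L)
      d <- rt_distance(gt, registered)
      rec$gt_te_mm[t + 1L] <- d$translation_mm
      rec$gt_re_deg[t + 1L] <- d$angle_deg
      if (!is.null(run$landmarks))
        rec$tre_mm[t + 1L] <- tre(run$landmarks, rt_apply(gt, run$landmarks),
                                  registered)
    }
  }
  reg_traj <- trajectory_from_transforms(reg_list, dt_s = config$frame_interval_s)
  names(reg_traj)[3:9] <- paste0("reg_", names(reg_traj)[3:9])
  disp <- lapply(reg_list, to_display, T_H_R = T_H_R)
  disp_traj <- trajectory_from_transforms(disp, dt_s = config$frame_interval_s)
  names(disp_traj)[3:9] <- paste0("disp_", names(disp_traj)[3:9])
  frames <- cbind(rec, reg_traj[, 3:9], disp_traj[, 3:9])
  final_err <- if (has_gt && !is.null(run$landmarks))
    rec$tre_mm[n] else rec$inlier_rmse_mm[n]
  summary <- list(
    n_frames = n,
    mean_chamfer_mm = mean(rec$chamfer_mm, na.rm = TRUE),
    mean_chamfer_full_mm = mean(rec$chamfer_full_mm, na.rm = TRUE),
    median_te_mm = stats::median(rec$te_mm, na.rm = TRUE),
    median_re_deg = stats::median(rec$re_deg, na.rm = TRUE),
    mean_te_mm = mean(rec$te_mm, na.rm = TRUE),
    mean_re_deg = mean(rec$re_deg, na.rm = TRUE),
    mean_tre_mm = if (has_gt) mean(rec$tre_mm, na.rm = TRUE) else NA_real_,
    final_tre_mm = if (has_gt) rec$tre_mm[n] else NA_real_,
    frame_success_pct = 100 * mean(rec$converged & rec$fitness > 0),
    run_success = isTRUE(rec$converged[n]) &&
      isTRUE(final_err < config$success_threshold_mm),
    final_error_mm = final_err)
  list(frames = frames, summary = summary, config = config)
}

#' Tune the smoothing hyperparameters for a trajectory
#'
#' Design-of-experiments sweep plus response-surface fit and minimization
#' for both channels (see [tune_hyperparameters()]); optionally writes the
#' surface CSV, the fitted coefficients JSON and a config fragment with the
#' chosen optima.
#'
#' @param trajectory trajectory `data.frame` or CSV path.
#' @param levels design levels (default 0 to 1 by 0.1).
#' @param m forecast horizon.
#' @param out_dir optional output directory.
#' @return the [tune_hyperparameters()] result, with `optima` (a one-row
#'   `data.frame` in the per-scenario optimum layout) appended.
#' @export
run_tuning <- function(trajectory, levels = seq(0, 1, by = 0.1), m = 1L,
                       out_dir = NULL) {
  if (is.character(trajectory)) trajectory <- read_trajectory_csv(trajectory)
  tuned <- tune_hyperparameters(trajectory, levels = levels, m = m)
  tuned$optima <- data.frame(
    alpha_tau = tuned$optimum_te$alpha_snapped,
    gamma_tau = tuned$optimum_te$gamma_snapped,
    alpha_rot = tuned$optimum_re$alpha_snapped,
    gamma_rot = tuned$optimum_re$gamma_snapped,
    alpha_tau_continuous = tuned$optimum_te$alpha,
    gamma_tau_continuous = tuned$optimum_te$gamma,
    alpha_rot_continuous = tuned$optimum_re$alpha,
    gamma_rot_continuous = tuned$optimum_re$gamma)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tuned$surface$grid, file.path(out_dir, "surface.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(coeffs_te = as.list(tuned$coeffs_te),
                              coeffs_re = as.list(tuned$coeffs_re),
                              optimum_te = tuned$optimum_te,
                              optimum_re = tuned$optimum_re),
                         file.path(out_dir, "response_surface.json"),
                         auto_unbox = TRUE, digits = NA)
    yaml::write_yaml(as.list(tuned$optima[1, 1:4]),
                     file.path(out_dir, "optima.yaml"))
  }
  tuned
}

#' Summarize navigation results across scenarios
#'
#' Builds the three study tables from a set of completed navigation runs:
#' registration accuracy and success per occlusion scenario, mean Chamfer
#' distance per motion scenario, and the forecast-error distribution
#' (median and quartiles) per motion scenario.
#'
#' @param results named list of [run_navigation()] results.
#' @param success_threshold_mm success threshold (default 20 mm).
#' @return list of `data.frame`s: `registration`, `chamfer`, `forecasting`.
#' @export
run_evaluation <- function(results, success_threshold_mm = 20) {
  nm <- names(results)
  if (is.null(nm)) nm <- paste0("run", seq_along(results))
  reg <- do.call(rbind, lapply(seq_along(results), function(i) {
    fr <- results[[i]]$frames
    data.frame(run = nm[i],
               mean_tre_mm = mean(fr$tre_mm, na.rm = TRUE),
               final_tre_mm = fr$tre_mm[nrow(fr)],
               frame_success_pct = 100 * mean(fr$converged & fr$fitness > 0),
               run_success = isTRUE(results[[i]]$summary$run_success))
  }))
  reg$success_rate_pct <- 100 * mean(reg$run_success)
  cham <- do.call(rbind, lapply(seq_along(results), function(i) {
    fr <- results[[i]]$frames
    data.frame(run = nm[i],
               mean_chamfer_mm = mean(fr$chamfer_mm, na.rm = TRUE),
               sd_chamfer_mm = stats::sd(fr$chamfer_mm, na.rm = TRUE),
               n_frames = nrow(fr))
  }))
  fc <- do.call(rbind, lapply(seq_along(results), function(i) {
    fr <- results[[i]]$frames
    q_te <- stats::quantile(fr$te_mm, c(0.25, 0.5, 0.75), na.rm = TRUE)
    q_re <- stats::quantile(fr$re_deg, c(0.25, 0.5, 0.75), na.rm = TRUE)
    data.frame(run = nm[i],
               te_q25_mm = q_te[1], te_median_mm = q_te[2], te_q75_mm = q_te[3],
               re_q25_deg = q_re[1], re_median_deg = q_re[2], re_q75_deg = q_re[3],
               row.names = NULL)
  }))
  list(registration = reg, chamfer = cham, forecasting = fc)
}
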