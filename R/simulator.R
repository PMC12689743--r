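# Synthetic study generator: liver-like phantom surface, turning-wheel rigid
# trajectories, rendered depth + mask frames, occlusion scenarios, noise and
# calibration scenes. Everything is bit-reproducible from (seed, config).

#' Default depth-sensor intrinsics
#'
#' A 640 x 480 pinhole profile with 600 px focal length and centered
#' principal point, mimicking a compact RGB-D depth stream.
#'
#' @param width,height image size (pixels).
#' @param fx,fy focal lengths (pixels).
#' @return a [camera_intrinsics()].
#' @export
default_intrinsics <- function(width = 640, height = 480, fx = 600, fy = 600) {
  camera_intrinsics(fx, fy, (width - 1) / 2, (height - 1) / 2, width, height)
}

#' Generate a liver-like two-lobed phantom surface
#'
#' Deterministic watertight triangle mesh: a UV-sphere triangulation of a
#' radially deformed ellipsoid (about 150 x 100 x 60 mm) with seeded lobe
#' bumps of unequal amplitude. The asymmetry guarantees a unique ICP
#' optimum (no rotational self-similarity).
#'
#' @param seed integer seed controlling lobe placement and amplitudes.
#' @param n_lobes number of lobe bumps (default 2).
#' @param n_lat,n_lon angular resolution of the triangulation.
#' @return a `triangle_mesh`, centered at the origin, mm units.
#' @export
make_phantom_mesh <- function(seed = 1L, n_lobes = 2L, n_lat = 36L, n_lon = 54L) {
  semi <- c(75, 50, 30)    # base ellipsoid semi-axes, mm
  with_seed(seed, {
    # lobes: broad bumps near the x-y plane; plus smaller seeded bumps and
    # dents everywhere, mimicking the ridges and impressions of a liver
    # surface (they also give ICP distinctive geometry to lock onto)
    n_detail <- 10L
    nb <- n_lobes + n_detail
    az <- stats::runif(nb, 0, 2 * pi)
    el <- c(stats::runif(n_lobes, -pi / 9, pi / 9),
            stats::runif(n_detail, -pi / 2, pi / 2))
    lobe_dir <- cbind(cos(el) * cos(az), cos(el) * sin(az), sin(el))
    amp <- c(stats::runif(1, 0.08, 0.10),            # one dominant lobe
             stats::runif(n_lobes - 1, 0.03, 0.06),
             stats::runif(n_detail, -0.05, 0.05))    # dents and ridges
    width <- c(stats::runif(n_lobes, 0.35, 0.55),    # radians
               stats::runif(n_detail, 0.15, 0.30))
    # unit sphere directions on a lat-lon grid plus the two poles
    lat <- seq_len(n_lat - 1) * pi / n_lat           # interior latitudes
    lon <- (seq_len(n_lon) - 1) * 2 * pi / n_lon
    gr <- expand.grid(lon = lon, lat = lat)
    dirs <- rbind(c(0, 0, 1),
                  cbind(sin(gr$lat) * cos(gr$lon), sin(gr$lat) * sin(gr$lon),
                        cos(gr$lat)),
                  c(0, 0, -1))
    r_ell <- 1 / sqrt((dirs[, 1] / semi[1])^2 + (dirs[, 2] / semi[2])^2 +
                        (dirs[, 3] / semi[3])^2)
    bump <- rep(0, nrow(dirs))
    for (k in seq_len(nrow(lobe_dir))) {
      ang <- acos(pmin(1, pmax(-1, dirs %*% lobe_dir[k, ])))
      bump <- bump + amp[k] * exp(-(ang / width[k])^2)
    }
    V <- dirs * (r_ell * (1 + bump))
    triangle_mesh(V, uv_sphere_faces(n_lat, n_lon))
  })
}

# triangulation of the lat-lon grid built above: vertex 1 = north pole,
# vertices 2..(1 + (n_lat-1) * n_lon) = rings (longitude fastest), last =
# south pole; every edge is shared by exactly two triangles
uv_sphere_faces <- function(n_lat, n_lon) {
  ring <- function(i) 1L + (i - 1L) * n_lon + seq_len(n_lon)   # i in 1..n_lat-1
  faces <- list()
  r1 <- ring(1)
  for (j in seq_len(n_lon))
    faces[[length(faces) + 1]] <- c(1L, r1[j], r1[j %% n_lon + 1L])
  for (i in seq_len(n_lat - 2)) {
    a <- ring(i); b <- ring(i + 1)
    for (j in seq_len(n_lon)) {
      jn <- j %% n_lon + 1L
      faces[[length(faces) + 1]] <- c(a[j], b[j], b[jn])
      faces[[length(faces) + 1]] <- c(a[j], b[jn], a[jn])
    }
  }
  south <- 2L + (n_lat - 1L) * n_lon
  rl <- ring(n_lat - 1)
  for (j in seq_len(n_lon))
    faces[[length(faces) + 1]] <- c(south, rl[j %% n_lon + 1L], rl[j])
  do.call(rbind, faces)
}

#' Turning-wheel motion scenario
#'
#' The phantom sits on a turning wheel with its centre off the rotation
#' axis, so it undergoes both rotation and translation; poses are sampled at
#' the pipeline's frame interval. A non-finite or non-positive period means
#' a static scenario.
#'
#' @param period_s_per_turn seconds per full turn (30, 15, 10 in the motion
#'   study; `0` or `Inf` for static).
#' @param axis rotation axis (unit 3-vector; default vertical).
#' @param axis_offset_mm distance from phantom centre to the axis
#'   (default 100 mm).
#' @param dt_s sampling interval in seconds (default 0.1, the pipeline's
#'   total latency).
#' @param duration_frames number of frames (default 300).
#' @param seed RNG seed for the noise stream.
#' @param noise_sigma_t_mm per-axis Gaussian translation noise (default 0.5).
#' @param noise_sigma_r_deg Gaussian rotation noise angle about random axes
#'   (default 0.2).
#' @return a `wheel_scenario` list.
#' @export
wheel_scenario <- function(period_s_per_turn = 30, axis = c(0, 1, 0),
                           axis_offset_mm = 100, dt_s = 0.1,
                           duration_frames = 300, seed = 1L,
                           noise_sigma_t_mm = 0.5, noise_sigma_r_deg = 0.2) {
  if (!is.finite(period_s_per_turn) || period_s_per_turn <= 0)
    period_s_per_turn <- Inf
  stopifnot(dt_s > 0, duration_frames >= 1,
            noise_sigma_t_mm >= 0, noise_sigma_r_deg >= 0)
  axis <- as.numeric(axis) / sqrt(sum(axis^2))
  structure(list(period_s_per_turn = period_s_per_turn, axis = axis,
                 axis_offset_mm = axis_offset_mm, dt_s = dt_s,
                 duration_frames = as.integer(duration_frames),
                 seed = as.integer(seed),
                 noise_sigma_t_mm = noise_sigma_t_mm,
                 noise_sigma_r_deg = noise_sigma_r_deg),
            class = "wheel_scenario")
}

# deterministic unit vector orthogonal to v
orthogonal_unit <- function(v) {
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  w <- c(v[2] * ref[3] - v[3] * ref[2],
         v[3] * ref[1] - v[1] * ref[3],
         v[1] * ref[2] - v[2] * ref[1])
  w / sqrt(sum(w^2))
}

#' Rigid poses of the turning-wheel motion
#'
#' Frame `t` pose: rotation about the scenario axis (through the origin) by
#' `omega * t * dt` applied to an initial centre offset `axis_offset_mm`
#' from the axis, composed with seeded Gaussian noise. The phantom centre
#' traces a circle of radius `axis_offset_mm`; the per-frame rotation
#' increment is constant (e.g. 3.6 degrees per 0.1 s at 10 s per turn).
#'
#' @param scn a [wheel_scenario()].
#' @return trajectory `data.frame` (see [trajectory_from_transforms()]).
#' @export
wheel_trajectory <- function(scn) {
  stopifnot(inherits(scn, "wheel_scenario"))
  n <- scn$duration_frames
  omega_deg <- if (is.finite(scn$period_s_per_turn))
    360 / scn$period_s_per_turn else 0
  r0 <- orthogonal_unit(scn$axis) * scn$axis_offset_mm
  base <- rigid_transform(translation = r0)
  with_seed(scn$seed, {
    poses <- vector("list", n)
    for (t in seq_len(n)) {
      ang <- omega_deg * (t - 1) * scn$dt_s
      pose <- rt_compose(rigid_transform(quat_from_axis_angle(scn$axis, ang)),
                         base)
      if (scn$noise_sigma_t_mm > 0 || scn$noise_sigma_r_deg > 0) {
        ax <- stats::rnorm(3)
        nq <- quat_from_axis_angle(ax, stats::rnorm(1, 0, scn$noise_sigma_r_deg))
        nt <- stats::rnorm(3, 0, scn$noise_sigma_t_mm)
        pose <- rt_compose(rigid_transform(nq, nt), pose)
      }
      poses[[t]] <- pose
    }
    trajectory_from_transforms(poses, dt_s = scn$dt_s)
  })
}

#' Render a depth + mask frame of a posed mesh
#'
#' Perspective z-buffer rasterization of the mesh under `pose`, viewed by a
#' pinhole camera at the origin looking down +z; the camera is backed off by
#' `camera_distance_mm` along z, so a pose near the origin puts the organ
#' surface roughly that far from the camera. The mask marks every pixel the
#' organ covers.
#'
#' @param mesh a `triangle_mesh` (mm).
#' @param pose model pose (`rigid_transform`).
#' @param intrinsics a [camera_intrinsics()].
#' @param camera_distance_mm camera stand-off distance (default 400).
#' @return a [depth_frame()]; attribute `camera_pose` holds the effective
#'   model-to-camera transform (the ground-truth registration pose), and
#'   attribute `empty` flags a frame the organ missed entirely.
#' @export
render_depth_frame <- function(mesh, pose = rt_identity(),
                               intrinsics = default_intrinsics(),
                               camera_distance_mm = 400) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  cam_pose <- rt_compose(rigid_transform(translation = c(0, 0, camera_distance_mm)),
                         pose)
  verts <- rt_apply(cam_pose, mesh$vertices)
  depth <- .rasterize_cpp(verts, mesh$faces,
                          intrinsics$fx, intrinsics$fy,
                          intrinsics$cx, intrinsics$cy,
                          intrinsics$width, intrinsics$height)
  frame <- depth_frame(depth, intrinsics, mask = depth > 0)
  attr(frame, "camera_pose") <- cam_pose
  attr(frame, "empty") <- !any(frame$mask)
  frame
}

#' The occlusion scenarios of the resection study
#'
#' Six scenarios emulating open liver surgery resection situations, graded
#' by the visibility factor (percentage of the unoccluded organ mask left
#' visible): the unoccluded reference, extended right hepatectomy (ERH),
#' right hepatectomy (RH), extended left hepatectomy (ELH), left
#' hepatectomy (LH) and left lobectomy (LL). Right-sided resections keep
#' the image-left part of the mask and vice versa.
#'
#' @return `data.frame` with `name`, `target_visibility_pct`, `keep_side`.
#' @export
occlusion_scenarios <- function() {
  data.frame(name = c("reference", "ERH", "RH", "ELH", "LH", "LL"),
             target_visibility_pct = c(100, 66, 35, 85, 52, 15),
             keep_side = c("all", "left", "left", "right", "right", "right"),
             stringsAsFactors = FALSE)
}

#' Occlude a frame's mask to a target visibility factor
#'
#' Reduces the segmentation mask by a vertical half-plane cut (anatomically
#' a left/right resection analogue) positioned so the achieved visibility
#' factor is within about 1 percent of the target; the depth map is left
#' unchanged (the sensor still sees the organ — the segmentation no longer
#' reports it).
#'
#' @param frame a [depth_frame()].
#' @param target_visibility_pct visibility to keep, in `(0, 100]`.
#' @param reference_mask unoccluded reference mask (defaults to the frame's
#'   own mask).
#' @param keep_side `"right"` or `"left"`: which image side survives the cut.
#' @return the frame with the reduced mask.
#' @export
apply_occlusion <- function(frame, target_visibility_pct,
                            reference_mask = frame$mask,
                            keep_side = c("right", "left")) {
  keep_side <- match.arg(keep_side)
  stopifnot(inherits(frame, "depth_frame"))
  if (target_visibility_pct <= 0 || target_visibility_pct > 100)
    stop("target visibility must be in (0, 100]")
  if (!any(reference_mask)) stop("reference mask is empty")
  if (target_visibility_pct == 100) return(frame)
  vis <- frame$mask & reference_mask
  n_ref <- sum(reference_mask)
  k <- round(target_visibility_pct / 100 * n_ref)
  if (k > sum(vis))
    stop(sprintf("target visibility %.1f%% exceeds the %.1f%% currently visible",
                 target_visibility_pct, 100 * sum(vis) / n_ref))
  u <- col(vis)[vis]
  thr <- sort(u, decreasing = (keep_side == "right"))[k]
  cut <- if (keep_side == "right") col(frame$mask) >= thr else col(frame$mask) <= thr
  frame$mask <- frame$mask & cut
  frame
}

# uniform random unit quaternion (Shoemake's method)
random_quaternion <- function() {
  u <- stats::runif(3)
  quaternion(c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
               sqrt(1 - u[1]) * cos(2 * pi * u[2]),
               sqrt(u[1]) * sin(2 * pi * u[3]),
               sqrt(u[1]) * cos(2 * pi * u[3])), normalize = TRUE)
}

random_pose <- function(t_range = 500) {
  rigid_transform(random_quaternion(), stats::runif(3, -t_range, t_range))
}

# left-composed random perturbation with bounded magnitude
perturb_pose <- function(pose, max_t_mm, max_r_deg) {
  d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
  t_err <- stats::runif(1, 0, max_t_mm) * d
  ax <- stats::rnorm(3)
  q_err <- quat_from_axis_angle(ax, stats::runif(1, 0, max_r_deg))
  rt_compose(rigid_transform(q_err, t_err), pose)
}

#' Generate a self-consistent synthetic calibration scene
#'
#' Draws random poses for the display (H), sensor (R), reference tracker
#' (E), calibration chart (C) and organ model (L) in a common world frame
#' and derives every observation the calibration chain consumes: the chart
#' pose in the sensor and display frames, the chart-corner fiducials in the
#' sensor and reference frames, and a user pre-alignment perturbed by at
#' most 100 mm / 15 degrees from the true display-frame model pose.
#'
#' @param seed integer seed.
#' @param chart_size_mm side length of the square chart (default 100).
#' @return list with `calibration` (observed `T_R_C`, `T_H_C` and true
#'   `T_H_R`, `T_E_R`), `fiducials` (`points_a` in the sensor frame,
#'   `points_b` in the reference frame), `prealign_T_H_L0` (perturbed) and
#'   `truth` (`T_H_L0`, `T_R_L0`, `T_H_R`, `T_E_R`).
#' @export
make_calibration_scene <- function(seed = 1L, chart_size_mm = 100) {
  with_seed(seed, {
    T_W_H <- random_pose(); T_W_R <- random_pose(); T_W_E <- random_pose()
    T_W_C <- random_pose(); T_W_L <- random_pose()
    T_R_C <- rt_compose(rt_invert(T_W_R), T_W_C)
    T_H_C <- rt_compose(rt_invert(T_W_H), T_W_C)
    T_E_C <- rt_compose(rt_invert(T_W_E), T_W_C)
    T_H_R <- rt_compose(rt_invert(T_W_H), T_W_R)
    T_E_R <- rt_compose(rt_invert(T_W_E), T_W_R)
    T_H_L0 <- rt_compose(rt_invert(T_W_H), T_W_L)
    T_R_L0 <- rt_compose(rt_invert(T_W_R), T_W_L)
    s <- chart_size_mm
    corners <- rbind(c(0, 0, 0), c(s, 0, 0), c(s, s, 0), c(0, s, 0))
    list(calibration = list(T_R_C = T_R_C, T_H_C = T_H_C,
                            T_H_R = T_H_R, T_E_R = T_E_R),
         fiducials = list(points_a = rt_apply(T_R_C, corners),
                          points_b = rt_apply(T_E_C, corners)),
         prealign_T_H_L0 = perturb_pose(T_H_L0, 100, 15),
         truth = list(T_H_L0 = T_H_L0, T_R_L0 = T_R_L0,
                      T_H_R = T_H_R, T_E_R = T_E_R),
         seed = seed)
  })
}
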