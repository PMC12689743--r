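# Target-cloud construction from masked depth frames and rigid point-to-point
# ICP registration of the sampled organ model.

#' Camera intrinsics for a pinhole depth sensor
#'
#' @param fx,fy focal lengths (pixels).
#' @param cx,cy principal point (pixels, 0-based pixel-center convention:
#'   `u` = column, `v` = row).
#' @param width,height image size (pixels).
#' @return a `camera_intrinsics` list.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width, height) {
  stopifnot(fx > 0, fy > 0, width >= 1, height >= 1)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_intrinsics")
}

#' A depth frame with segmentation mask
#'
#' @param depth `height x width` numeric matrix of depths in mm; 0 marks an
#'   invalid pixel.
#' @param intrinsics a [camera_intrinsics()].
#' @param mask `height x width` logical matrix; `TRUE` marks organ pixels.
#'   Defaults to all valid pixels.
#' @return a `depth_frame`.
#' @export
depth_frame <- function(depth, intrinsics, mask = NULL) {
  depth <- as.matrix(depth)
  if (any(!is.finite(depth)) || any(depth < 0))
    stop("depth must be finite and non-negative (mm; 0 = invalid)")
  if (nrow(depth) != intrinsics$height || ncol(depth) != intrinsics$width)
    stop("depth dimensions do not match the intrinsics")
  if (is.null(mask)) mask <- depth > 0
  mask <- matrix(as.logical(mask), nrow(depth), ncol(depth))
  if (!all(dim(mask) == dim(depth))) stop("mask shape must equal depth shape")
  structure(list(depth = depth, intrinsics = intrinsics, mask = mask),
            class = "depth_frame")
}

#' Back-project masked depth pixels to a camera-frame point cloud
#'
#' One point per masked pixel with valid depth:
#' `x = (u - cx) z / fx`, `y = (v - cy) z / fy`, `z = depth(v, u)`, in mm,
#' with `u` = column and `v` = row, 0-based at pixel centers.
#'
#' @param frame a [depth_frame()].
#' @return N x 3 point matrix (possibly 0-row when no masked pixel is valid).
#' @export
backproject_and_crop <- function(frame) {
  stopifnot(inherits(frame, "depth_frame"))
  sel <- which(frame$mask & frame$depth > 0, arr.ind = TRUE)
  if (nrow(sel) == 0) return(matrix(numeric(0), 0, 3))
  z <- frame$depth[sel]
  u <- sel[, 2] - 1   # 0-based column
  v <- sel[, 1] - 1   # 0-based row
  K <- frame$intrinsics
  cbind((u - K$cx) * z / K$fx, (v - K$cy) * z / K$fy, z)
}

#' Voxel-grid downsampling of a point cloud
#'
#' Points are binned into a cubic grid anchored at the origin
#' (`floor(p / voxel)`), and each occupied voxel is replaced by the centroid
#' of its members.
#'
#' @param points N x 3 point matrix (mm).
#' @param voxel_mm voxel edge length (mm, default 5).
#' @return M x 3 matrix of voxel centroids, `M <= N`, ordered by voxel index.
#' @export
voxel_downsample <- function(points, voxel_mm = 5) {
  if (voxel_mm <= 0) stop("voxel_mm must be positive")
  points <- as.matrix(points)
  if (nrow(points) == 0) return(points)
  k <- floor(points / voxel_mm)
  mins <- apply(k, 2, min)
  dims <- apply(k, 2, max) - mins + 1
  lin <- (k[, 1] - mins[1]) + dims[1] * ((k[, 2] - mins[2]) + dims[2] * (k[, 3] - mins[3]))
  sums <- rowsum(points, group = lin)
  cnt <- as.vector(rowsum(rep(1, nrow(points)), group = lin))
  unname(sums / cnt)
}

#' Sample points area-uniformly on a triangle mesh surface
#'
#' Builds the model (source) point cloud from the preoperative surface model.
#' Triangles are drawn with probability proportional to area; points are
#' placed by uniform barycentric sampling. Deterministic for a fixed seed.
#'
#' @param mesh a `triangle_mesh` (see [read_mesh()] / [make_phantom_mesh()]).
#' @param n number of points (default 5000).
#' @param seed integer RNG seed.
#' @return N x 3 point matrix with an `normals` attribute (outward per-point
#'   face normals, used for visibility culling).
#' @export
sample_mesh_points <- function(mesh, n = 5000, seed = 1L) {
  stopifnot(inherits(mesh, "triangle_mesh"), n >= 1)
  V <- mesh$vertices; Fc <- mesh$faces
  if (nrow(Fc) < 1) stop("mesh has no triangles")
  a <- V[Fc[, 1], , drop = FALSE]
  b <- V[Fc[, 2], , drop = FALSE]
  c_ <- V[Fc[, 3], , drop = FALSE]
  cr <- cross_rows(b - a, c_ - a)
  area2 <- sqrt(rowSums(cr^2))            # 2 * triangle area
  if (sum(area2) <= 0) stop("degenerate mesh: zero total surface area")
  with_seed(seed, {
    tri <- sample.int(nrow(Fc), n, replace = TRUE, prob = area2)
    u <- stats::runif(n); v <- stats::runif(n)
    flip <- u + v > 1
    u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
    pts <- a[tri, , drop = FALSE] +
      u * (b[tri, , drop = FALSE] - a[tri, , drop = FALSE]) +
      v * (c_[tri, , drop = FALSE] - a[tri, , drop = FALSE])
    nrm <- cr[tri, , drop = FALSE] / area2[tri]
    attr(pts, "normals") <- nrm
    pts
  })
}

cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Point-to-point ICP registration
#'
#' Iteratively alternates nearest-neighbour correspondence search
#' (source to target, pairs beyond `threshold_mm` rejected) with the
#' closed-form least-squares rigid update (Kabsch/SVD on the corresponded
#' pairs). Stops when the relative change of the inlier RMSE falls below
#' `rel_tol` or after `max_iter` iterations; the best transform seen is
#' returned.
#'
#' @param source N x 3 model (source) cloud (mm).
#' @param target M x 3 sensor (target) cloud (mm).
#' @param init initial `rigid_transform` (e.g. the previous frame's result).
#' @param threshold_mm correspondence distance threshold (default 10 mm).
#' @param max_iter iteration cap (default 50).
#' @param rel_tol relative RMSE-change stopping tolerance (default 1e-6).
#' @return an `icp_result`: list with `transform`, `inlier_rmse` (mm),
#'   `fitness` (fraction of source points with a correspondence within
#'   threshold), `iterations`, and `converged` — whether the solve produced
#'   a valid registration (`FALSE` when no correspondence within the
#'   threshold ever existed, in which case `transform` is `init` and
#'   `fitness` is 0).
#' @export
icp_point_to_point <- function(source, target, init = rt_identity(),
                               threshold_mm = 10, max_iter = 50, rel_tol = 1e-6) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) == 0 || nrow(target) == 0)
    stop("ICP requires non-empty source and target clouds")
  if (threshold_mm <= 0) stop("threshold_mm must be positive")
  current <- init
  best <- list(transform = init, inlier_rmse = Inf, fitness = 0)
  prev_rmse <- Inf
  had_correspondences <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    nn <- .nn_query_cpp(rt_apply(current, source), target)
    inl <- nn$distance <= threshold_mm
    if (!any(inl)) {
      if (iter == 1L)
        return(icp_result(init, Inf, 0, 0L, FALSE))
      break
    }
    had_correspondences <- TRUE
    rmse <- sqrt(mean(nn$distance[inl]^2))
    fitness <- mean(inl)
    if (rmse < best$inlier_rmse)
      best <- list(transform = current, inlier_rmse = rmse, fitness = fitness)
    if (is.finite(prev_rmse) &&
        abs(prev_rmse - rmse) <= rel_tol * max(rmse, .Machine$double.eps))
      break
    prev_rmse <- rmse
    current <- kabsch(source[inl, , drop = FALSE],
                      target[nn$index[inl], , drop = FALSE])
  }
  icp_result(best$transform, best$inlier_rmse, best$fitness, iter,
             had_correspondences)
}

icp_result <- function(transform, inlier_rmse, fitness, iterations, converged) {
  structure(list(transform = transform, inlier_rmse = inlier_rmse,
                 fitness = fitness, iterations = iterations,
                 converged = converged),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf("<icp_result> converged=%s, iterations=%d, inlier_rmse=%.4f mm, fitness=%.3f\n",
              x$converged, x$iterations, x$inlier_rmse, x$fitness))
  invisible(x)
}

#' Least-squares rigid alignment of corresponded point sets (Kabsch/SVD)
#'
#' Returns the rigid transform `T` minimizing `sum_i ||T(a_i) - b_i||^2` for
#' paired points.
#'
#' @param a,b N x 3 corresponded point matrices (N >= 3).
#' @return a `rigid_transform`.
#' @export
kabsch <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b), nrow(a) >= 3)
  ca <- colMeans(a); cb <- colMeans(b)
  H <- crossprod(sweep(a, 2, ca), sweep(b, 2, cb))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(quat_from_matrix(R, tol = 1e-4), cb - as.numeric(R %*% ca))
}

#' Keep the model points facing the camera at a given pose
#'
#' A one-sided depth sensor only observes the camera-facing surface;
#' correspondences from the self-occluded far side systematically bias
#' point-to-point ICP, so the source cloud is restricted to points whose
#' outward normal faces the camera (back-face culling; the camera sits at
#' the origin looking down +z).
#'
#' @param model N x 3 model cloud carrying a `normals` attribute
#'   (see [sample_mesh_points()]).
#' @param pose candidate model pose (`rigid_transform`).
#' @return the visible subset of `model` (model-frame coordinates, with the
#'   matching `normals` attribute).
#' @export
cull_backfacing <- function(model, pose) {
  normals <- attr(model, "normals")
  if (is.null(normals)) return(model)
  p_cam <- rt_apply(pose, model)
  n_cam <- normals %*% t(quat_to_matrix(pose$rotation))
  keep <- rowSums(n_cam * p_cam) < 0
  out <- model[keep, , drop = FALSE]
  attr(out, "normals") <- normals[keep, , drop = FALSE]
  out
}

#' Register the model cloud to one masked depth frame
#'
#' One step of the tracking loop: back-project the masked depth pixels,
#' voxel-downsample both clouds (the model side after culling its
#' self-occluded back face at the initial pose), then run point-to-point
#' ICP initialized at the previous frame's pose. Optional refinement passes
#' re-cull the visibility at the current estimate and re-register the full
#' model sampling against a finer-voxel target, which removes the residual
#' tangential bias of coarse-cloud ICP (sub-millimetre recovery at full
#' visibility). When the frame yields no target points the previous pose is
#' held (`converged = FALSE`) so the loop can continue and the failure is
#' visible to the success-rate metric.
#'
#' @param model N x 3 model (source) cloud sampled from the organ surface,
#'   ideally with the `normals` attribute of [sample_mesh_points()].
#' @param frame a [depth_frame()].
#' @param prev previous-frame `rigid_transform` (for the first frame, the
#'   pre-alignment mapped into the sensor frame, see [init_registration()]).
#' @param voxel_mm voxel size for both clouds (default 5 mm); set
#'   `downsample_model`/`downsample_target` to control each side.
#' @param threshold_mm,max_iter,rel_tol ICP parameters.
#' @param downsample_model,downsample_target apply the voxel filter to each
#'   cloud (default both, the balanced-resolution choice).
#' @param cull apply back-face culling to the model cloud (default `TRUE`;
#'   a no-op when `model` has no normals).
#' @param refine_passes number of visibility-refreshing refinement passes
#'   (default 0: coarse tracking only).
#' @param refine_voxel_mm target voxel size during refinement (default 1).
#' @return an `icp_result` whose `transform` is the model pose in the sensor
#'   frame at this frame.
#' @export
register_frame <- function(model, frame, prev, voxel_mm = 5, threshold_mm = 10,
                           max_iter = 50, rel_tol = 1e-6,
                           downsample_model = TRUE, downsample_target = TRUE,
                           cull = TRUE, refine_passes = 0L, refine_voxel_mm = 1) {
  target_raw <- backproject_and_crop(frame)
  if (nrow(target_raw) == 0)
    return(icp_result(prev, Inf, 0, 0L, FALSE))
  target <- if (downsample_target) voxel_downsample(target_raw, voxel_mm) else target_raw
  src <- if (cull) cull_backfacing(model, prev) else as.matrix(model)
  if (downsample_model) src <- voxel_downsample(src, voxel_mm)
  res <- icp_point_to_point(src, target, init = prev, threshold_mm = threshold_mm,
                            max_iter = max_iter, rel_tol = rel_tol)
  if (refine_passes > 0 && res$fitness > 0) {
    tgt_fine <- voxel_downsample(target_raw, refine_voxel_mm)
    total_iter <- res$iterations
    for (k in seq_len(refine_passes)) {
      src_k <- if (cull) cull_backfacing(model, res$transform) else as.matrix(model)
      res <- icp_point_to_point(src_k, tgt_fine, init = res$transform,
                                threshold_mm = threshold_mm,
                                max_iter = max(max_iter, 150L), rel_tol = 1e-8)
      total_iter <- total_iter + res$iterations
    }
    res$iterations <- total_iter
  }
  res
}
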