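# depth back-projection, voxel filtering, surface sampling and ICP

test_that("back-projection inverts the pinhole model", {
  K <- camera_intrinsics(fx = 500, fy = 500, cx = 20, cy = 15, width = 41, height = 31)
  depth <- matrix(0, 31, 41)
  depth[15 + 1, 20 + 1] <- 400            # principal point (0-based u=20, v=15)
  fr <- depth_frame(depth, K)
  expect_equal(backproject_and_crop(fr), cbind(0, 0, 400), ignore_attr = TRUE)

  # a full synthetic plane at z = 400 mm round-trips exactly
  z <- matrix(400, 31, 41)
  cloud <- backproject_and_crop(depth_frame(z, K))
  expect_equal(nrow(cloud), 31 * 41)
  expect_true(all(abs(cloud[, 3] - 400) < 1e-9))
  u <- (cloud[, 1] * 500 / 400) + 20
  v <- (cloud[, 2] * 500 / 400) + 15
  expect_lt(max(abs(u - round(u))), 1e-6)
  expect_lt(max(abs(v - round(v))), 1e-6)

  # all-false mask yields the explicit empty cloud
  fr2 <- depth_frame(z, K, mask = matrix(FALSE, 31, 41))
  expect_equal(nrow(backproject_and_crop(fr2)), 0)
})

test_that("voxel downsampling takes per-voxel centroids on an origin-anchored grid", {
  p <- rbind(c(1, 1, 1), c(2, 2, 2))      # same 5 mm voxel
  expect_equal(voxel_downsample(p, 5), rbind(c(1.5, 1.5, 1.5)))
  line <- cbind(seq(0.5, 99.5, by = 10), 0.1, 0.1)   # 10 mm apart, 5 mm voxels
  expect_equal(nrow(voxel_downsample(line, 5)), nrow(line))
  set.seed(1)
  cloud <- matrix(runif(3000, 0, 100), ncol = 3)
  ds <- voxel_downsample(cloud, 5)
  expect_lte(nrow(ds), nrow(cloud))
  nn <- arnav:::.nn_query_cpp(ds, cloud)
  expect_lt(max(nn$distance), 5 * sqrt(3) / 2)       # within voxel half-diagonal
  # idempotent on already-sparse clouds
  expect_equal(voxel_downsample(ds, 5), voxel_downsample(voxel_downsample(ds, 5), 5))
  expect_error(voxel_downsample(cloud, 0), "positive")
})

test_that("surface sampling is area-uniform, on-surface and deterministic", {
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(1:3))
  pts <- sample_mesh_points(tri, 5000, seed = 1)
  expect_true(all(pts[, 1] >= -1e-12 & pts[, 2] >= -1e-12 &
                    pts[, 1] + pts[, 2] <= 1 + 1e-12))
  expect_true(all(abs(pts[, 3]) < 1e-12))

  # two triangles with 1:9 area ratio collect points accordingly
  two <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                             c(10, 0, 0), c(13, 0, 0), c(10, 3, 0)),
                       rbind(1:3, 4:6))
  n <- 20000
  pts2 <- sample_mesh_points(two, n, seed = 2)
  frac_small <- mean(pts2[, 1] < 5)
  ci <- qbinom(c(0.005, 0.995), n, 0.1) / n
  expect_gte(frac_small, ci[1]); expect_lte(frac_small, ci[2])

  expect_equal(sample_mesh_points(two, 100, seed = 7),
               sample_mesh_points(two, 100, seed = 7))
  degenerate <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), rbind(1:3))
  expect_error(sample_mesh_points(degenerate, 10, seed = 1), "zero total surface area")
})

test_that("Kabsch alignment and one ICP step are least-squares optimal", {
  set.seed(3)
  a <- matrix(runif(60, -50, 50), ncol = 3)
  tr <- rand_rt()
  b <- rt_apply(tr, a)
  expect_rt_equal(kabsch(a, b), tr)
  # fixed correspondences: the Kabsch update cannot increase the objective
  init <- rt_compose(rigid_transform(Rz(4), c(3, -2, 1)), tr)
  rmse0 <- sqrt(mean(rowSums((rt_apply(init, a) - b)^2)))
  upd <- kabsch(a, b)
  rmse1 <- sqrt(mean(rowSums((rt_apply(upd, a) - b)^2)))
  expect_lte(rmse1, rmse0)
})

test_that("ICP recovers ground truth on identical clouds", {
  src <- sample_mesh_points(make_phantom_mesh(2), 800, seed = 1)
  res0 <- icp_point_to_point(src, src, rt_identity())
  expect_true(res0$converged)
  expect_equal(res0$fitness, 1)
  expect_lt(res0$inlier_rmse, 1e-9)
  expect_rt_equal(res0$transform, rt_identity(), tol = 1e-6)

  set.seed(4)
  for (i in 1:5) {
    tr <- rand_rt(t_range = 30)
    tgt <- rt_apply(tr, src)
    init <- perturb_rt(tr, 8, 5)
    res <- icp_point_to_point(src, tgt, init, threshold_mm = 50, max_iter = 100)
    d <- rt_distance(res$transform, tr)
    expect_lt(d$translation_mm, 1e-6)
    expect_lt(d$angle_deg, 1e-6)
  }
})

test_that("ICP under Gaussian noise keeps landmark TRE below 3 sigma", {
  set.seed(5)
  src <- sample_mesh_points(make_phantom_mesh(3), 1500, seed = 1)
  sigma <- 1
  tr <- rand_rt(t_range = 20)
  tgt <- rt_apply(tr, src) + matrix(rnorm(length(src), sd = sigma), ncol = 3)
  init <- perturb_rt(tr, 5, 3)
  res <- icp_point_to_point(src, tgt, init, threshold_mm = 20, max_iter = 100)
  landmarks <- src[1:3, ]
  err <- tre(landmarks, rt_apply(tr, landmarks), res$transform)
  expect_lt(err, 3 * sigma)
})

test_that("ICP reports failure when no correspondences exist at the initialization", {
  src <- matrix(runif(30, 0, 10), ncol = 3)
  tgt <- src + 1000
  init <- rt_identity()
  res <- icp_point_to_point(src, tgt, init, threshold_mm = 10)
  expect_false(res$converged)
  expect_equal(res$fitness, 0)
  expect_rt_equal(res$transform, init)
})

test_that("registration is equivariant under a global rigid motion", {
  set.seed(6)
  src <- sample_mesh_points(make_phantom_mesh(4), 700, seed = 2)
  tr <- rand_rt(t_range = 10)
  tgt <- rt_apply(tr, src)
  init <- perturb_rt(tr, 4, 2)
  res <- icp_point_to_point(src, tgt, init, threshold_mm = 30)
  G <- rand_rt(t_range = 50)
  res_g <- icp_point_to_point(src, rt_apply(G, tgt), rt_compose(G, init),
                              threshold_mm = 30)
  expect_rt_equal(res_g$transform, rt_compose(G, res$transform), tol = 1e-6)
})

test_that("register_frame tracks rendered frames and holds the pose on empty ones", {
  mesh <- make_phantom_mesh(1)
  model <- sample_mesh_points(mesh, 5000, seed = 1)
  fr <- render_depth_frame(mesh)
  gt <- attr(fr, "camera_pose")
  # frame rendered exactly at prev: result stays at prev
  res <- register_frame(model, fr, gt)
  d <- rt_distance(res$transform, gt)
  expect_lt(d$translation_mm, 1)
  expect_lt(d$angle_deg, 1)
  # empty frame: hold-last-pose, flagged
  empty <- depth_frame(fr$depth, fr$intrinsics, mask = matrix(FALSE, nrow(fr$depth), ncol(fr$depth)))
  held <- register_frame(model, empty, gt)
  expect_false(held$converged)
  expect_rt_equal(held$transform, gt)
})

test_that("register_frame with refinement recovers a 5 mm offset below 1 mm", {
  mesh <- make_phantom_mesh(1)
  model <- sample_mesh_points(mesh, 5000, seed = 1)
  fr <- render_depth_frame(mesh)
  gt <- attr(fr, "camera_pose")
  prev <- rt_compose(rigid_transform(translation = c(5, 0, 0)), gt)
  res <- register_frame(model, fr, prev, refine_passes = 2)
  d <- rt_distance(res$transform, gt)
  expect_lt(d$translation_mm, 1)
  expect_lt(d$angle_deg, 1)
})

test_that("register_frame converges under heavy occlusion (15% visibility)", {
  mesh <- make_phantom_mesh(1)
  model <- sample_mesh_points(mesh, 5000, seed = 1)
  fr <- render_depth_frame(mesh)
  occ <- apply_occlusion(fr, 15, keep_side = "right")
  res <- register_frame(model, occ, attr(fr, "camera_pose"))
  expect_true(res$converged)
  expect_gt(res$fitness, 0)
})
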