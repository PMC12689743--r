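# synthetic study generator: phantom, wheel kinematics, rendering, occlusion
# and calibration scenes

test_that("the phantom mesh is deterministic, bounded and watertight", {
  m1 <- make_phantom_mesh(5)
  m2 <- make_phantom_mesh(5)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)
  expect_false(identical(m1$vertices, make_phantom_mesh(6)$vertices))

  ext <- apply(m1$vertices, 2, function(x) diff(range(x)))
  expect_gte(ext[1], 120); expect_lte(ext[1], 180)
  expect_gte(ext[2], 80);  expect_lte(ext[2], 120)
  expect_gte(ext[3], 40);  expect_lte(ext[3], 80)

  # watertight manifold: every edge is shared by exactly two triangles
  e <- rbind(m1$faces[, 1:2], m1$faces[, 2:3], m1$faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(table(key) == 2))
})

test_that("wheel kinematics: constant increment, circular centre path, static limit", {
  scn <- wheel_scenario(period_s_per_turn = 10, dt_s = 0.1, duration_frames = 60,
                        noise_sigma_t_mm = 0, noise_sigma_r_deg = 0)
  traj <- wheel_trajectory(scn)
  poses <- lapply(seq_len(nrow(traj)), function(i) trajectory_pose(traj, i))
  incs <- vapply(2:length(poses), function(i)
    quat_angular_distance(quat_multiply(quat_conjugate(poses[[i - 1]]$rotation),
                                        poses[[i]]$rotation), quat_identity()),
    numeric(1))
  expect_equal(incs, rep(3.6, length(incs)), tolerance = 1e-10)
  radii <- vapply(poses, function(p) sqrt(sum(p$translation^2)), numeric(1))
  expect_lt(max(abs(radii - 100)), 1e-9)
  # relative rotation between consecutive frames is constant to 1e-12
  rel <- lapply(2:length(poses), function(i)
    quat_multiply(quat_conjugate(poses[[i - 1]]$rotation), poses[[i]]$rotation))
  spread <- max(vapply(rel, function(q) quat_angular_distance(q, rel[[1]]),
                       numeric(1)))
  expect_lt(spread, 1e-10)

  static <- wheel_trajectory(wheel_scenario(period_s_per_turn = 0,
                                            duration_frames = 10,
                                            noise_sigma_t_mm = 0,
                                            noise_sigma_r_deg = 0))
  expect_equal(unique(static$tx_mm), static$tx_mm[1])
  expect_equal(unique(static$qw), static$qw[1])
})

test_that("rendering a sphere puts the centre pixel at distance minus radius", {
  sph <- sphere_mesh(radius = 50)
  fr <- render_depth_frame(sph, rt_identity(), default_intrinsics(), 400)
  K <- fr$intrinsics
  centre <- fr$depth[round(K$cy) + 1, round(K$cx) + 1]
  expect_lt(abs(centre - 350), 1)
})

test_that("rendered frames back-project onto the generating surface", {
  mesh <- make_phantom_mesh(2)
  fr <- render_depth_frame(mesh)
  cloud <- backproject_and_crop(fr)
  dense <- rt_apply(attr(fr, "camera_pose"), sample_mesh_points(mesh, 40000, seed = 1))
  nn <- arnav:::.nn_query_cpp(cloud, dense)
  # within ~2 pixel-equivalents (a pixel spans ~0.67 mm at 400 mm)
  expect_lt(quantile(nn$distance, 0.95), 2)
})

test_that("the projected mask shrinks as the phantom moves away", {
  mesh <- make_phantom_mesh(1)
  px <- vapply(c(350, 450, 550, 650), function(d)
    sum(render_depth_frame(mesh, rt_identity(), default_intrinsics(), d)$mask),
    numeric(1))
  expect_true(all(diff(px) < 0))
})

test_that("occlusion cuts reach the study's visibility factors within tolerance", {
  mesh <- make_phantom_mesh(1)
  fr <- render_depth_frame(mesh)
  ref <- fr$mask
  sc <- occlusion_scenarios()
  for (i in seq_len(nrow(sc))) {
    if (sc$name[i] == "reference") next
    occ <- apply_occlusion(fr, sc$target_visibility_pct[i],
                           keep_side = sc$keep_side[i])
    expect_lt(abs(visibility_factor(occ$mask, ref) - sc$target_visibility_pct[i]),
              2)
    expect_identical(occ$depth, fr$depth)   # depth untouched, mask-only cut
  }
  expect_identical(apply_occlusion(fr, 100)$mask, fr$mask)
  expect_error(apply_occlusion(fr, 150), "\\(0, 100\\]")
  tiny <- apply_occlusion(fr, 15, keep_side = "right")
  expect_error(apply_occlusion(tiny, 50, reference_mask = ref), "exceeds")
})

test_that("calibration scenes are self-consistent and bounded", {
  for (seed in c(1, 2, 3)) {
    scene <- make_calibration_scene(seed)
    expect_rt_equal(chain_offset(scene$calibration$T_R_C, scene$calibration$T_H_C),
                    scene$truth$T_H_R, tol = 1e-9)
    horn <- horn_fiducial_registration(scene$fiducials$points_a,
                                       scene$fiducials$points_b)
    expect_rt_equal(horn, scene$truth$T_E_R, tol = 1e-6)
    d <- rt_distance(scene$prealign_T_H_L0, scene$truth$T_H_L0)
    expect_lte(d$translation_mm, 100)
    expect_lte(d$angle_deg, 15)
  }
  s1 <- make_calibration_scene(4); s2 <- make_calibration_scene(4)
  expect_identical(rt_to_matrix(s1$calibration$T_R_C),
                   rt_to_matrix(s2$calibration$T_R_C))
})

test_that("generator seeding does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(5)
  set.seed(123); invisible(make_phantom_mesh(9))
  invisible(wheel_trajectory(wheel_scenario(duration_frames = 5, seed = 2)))
  after <- runif(5)
  expect_identical(before, after)
})
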