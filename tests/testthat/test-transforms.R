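# rigid-transform algebra against the 4x4 homogeneous-matrix oracle

test_that("composition, inversion and application agree with the matrix oracle", {
  set.seed(1)
  for (i in 1:200) {
    a <- rand_rt(); b <- rand_rt()
    Mab <- rt_to_matrix(a) %*% rt_to_matrix(b)
    expect_lt(max(abs(rt_to_matrix(rt_compose(a, b)) - Mab)), 1e-9)
    expect_lt(max(abs(rt_to_matrix(rt_invert(a)) - solve(rt_to_matrix(a)))), 1e-9)
    p <- matrix(runif(9, -50, 50), 3)
    expect_lt(max(abs(rt_apply(rt_compose(a, b), p) - rt_apply(a, rt_apply(b, p)))),
              1e-9)
  }
})

test_that("the transforms form a group: identity, inverse, associativity", {
  set.seed(2)
  I <- rt_identity()
  for (i in 1:100) {
    a <- rand_rt(); b <- rand_rt(); c <- rand_rt()
    expect_rt_equal(rt_compose(I, a), a)
    expect_rt_equal(rt_compose(a, I), a)
    expect_rt_equal(rt_compose(a, rt_invert(a)), I)
    expect_rt_equal(rt_compose(rt_compose(a, b), c), rt_compose(a, rt_compose(b, c)))
  }
})

test_that("composition of two quarter turns gives a half turn carrying the first translation", {
  a <- rigid_transform(Rz(90), c(1, 0, 0))
  b <- rigid_transform(Rz(90), c(0, 0, 0))
  ab <- rt_compose(a, b)
  expect_equal(quat_angular_distance(ab$rotation, Rz(180)), 0, tolerance = 1e-9)
  expect_equal(ab$translation, c(1, 0, 0), tolerance = 1e-12)
})

test_that("inverting a pure translation flips its sign", {
  ti <- rt_invert(rigid_transform(translation = c(3, 4, 0)))
  expect_equal(ti$translation, c(-3, -4, 0), tolerance = 1e-12)
  expect_rt_equal(rt_invert(rt_identity()), rt_identity())
})

test_that("applying a transform moves points as R p + tau and preserves distances", {
  expect_equal(rt_apply(rt_identity(), c(1, 2, 3)), c(1, 2, 3))
  expect_equal(rt_apply(rigid_transform(translation = c(0, 0, 5)), c(0, 0, 0)),
               c(0, 0, 5))
  expect_equal(rt_apply(rigid_transform(Rz(90)), c(1, 0, 0)), c(0, 1, 0),
               tolerance = 1e-12)
  set.seed(3)
  p <- matrix(runif(60, -100, 100), ncol = 3)
  q <- rt_apply(rand_rt(), p)
  expect_lt(max(abs(dist(p) - dist(q))), 1e-9)
})

test_that("slerp interpolates the geodesic and handles the double cover", {
  q <- rand_quat()
  expect_equal(quat_angular_distance(quat_slerp(q, q, 0.5), q), 0, tolerance = 1e-9)
  half <- quat_slerp(quat_identity(), Rz(90), 0.5)
  expect_equal(quat_angular_distance(half, Rz(45)), 0, tolerance = 1e-9)
  # raw -q components on the far hemisphere: same rotation, same midpoint
  set.seed(4)
  q0 <- rand_quat()
  q1 <- quat_multiply(q0, Rz(10))
  q1_flipped <- quaternion(-unclass(q1), normalize = TRUE)
  mid <- quat_slerp(q0, q1_flipped, 0.5)
  expect_equal(quat_angular_distance(mid, quat_multiply(q0, Rz(5))), 0,
               tolerance = 1e-7)
})

test_that("slerp is additive along the arc", {
  set.seed(5)
  for (i in 1:20) {
    q0 <- rand_quat(); q1 <- rand_quat()
    u <- runif(1)
    mid <- quat_slerp(q0, q1, u)
    end <- quat_slerp(mid, q1, 1)
    expect_equal(quat_angular_distance(end, q1), 0, tolerance = 1e-7)
    # composing partial arcs lands on the direct interpolation
    v <- runif(1)
    expect_equal(quat_angular_distance(
      quat_slerp(q0, q1, u + (1 - u) * v),
      quat_slerp(mid, q1, v)), 0, tolerance = 1e-6)
  }
})

test_that("quaternion powers scale the rotation angle about a fixed axis", {
  expect_equal(quat_angular_distance(quat_power(Rz(30), 2), Rz(60)), 0,
               tolerance = 1e-9)
  expect_equal(quat_angular_distance(quat_power(rand_quat(), 0), quat_identity()),
               0, tolerance = 1e-9)
  expect_equal(quat_angular_distance(quat_power(Rx(45), 0.5), Rx(22.5)), 0,
               tolerance = 1e-9)
})

test_that("angular distance is the relative rotation angle, double-cover safe", {
  q <- rand_quat()
  expect_equal(quat_angular_distance(q, q), 0)
  expect_equal(quat_angular_distance(q, quaternion(-unclass(q), normalize = TRUE)), 0)
  expect_equal(quat_angular_distance(quat_identity(), Rz(37)), 37, tolerance = 1e-9)
  expect_equal(quat_angular_distance(quat_identity(), Rz(37), half_angle = TRUE),
               18.5, tolerance = 1e-9)
})

test_that("angular distance is symmetric and satisfies the triangle inequality", {
  set.seed(6)
  for (i in 1:200) {
    a <- rand_quat(); b <- rand_quat(); c <- rand_quat()
    expect_equal(quat_angular_distance(a, b), quat_angular_distance(b, a),
                 tolerance = 1e-9)
    expect_lte(quat_angular_distance(a, c),
               quat_angular_distance(a, b) + quat_angular_distance(b, c) + 1e-7)
  }
})

test_that("matrix and JSON round trips reproduce the transform", {
  set.seed(7)
  for (i in 1:50) {
    tr <- rand_rt()
    expect_rt_equal(rt_from_matrix(rt_to_matrix(tr)), tr)
  }
  tr <- rand_rt()
  f <- withr::local_tempfile(fileext = ".json")
  write_transform_json(tr, f)
  expect_rt_equal(read_transform_json(f), tr, tol = 1e-9)
  # matrix-only payload is accepted too
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(matrix = rt_to_matrix(tr)), f2,
                       digits = NA, matrix = "rowmajor")
  expect_rt_equal(read_transform_json(f2), tr)
})

test_that("invalid rotations are rejected", {
  expect_error(quaternion(c(1, 1, 0, 0)), "norm")
  expect_error(rigid_transform(c(0.5, 0.5, 0.5, 0.4), c(0, 0, 0)), "norm")
  expect_error(rt_from_matrix(diag(c(1, 1, 2, 1))), "rotation")
  expect_error(quaternion(c(0, 0, 0, 0)), "zero")
})
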