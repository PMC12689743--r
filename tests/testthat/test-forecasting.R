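# double exponential smoothing of poses: initialization, recursions,
# exactness limits and the scalar-Holt brute-force oracle

holt_scalar <- function(x, alpha, gamma) {
  # independent reference implementation of the scalar recursion
  S <- x[1]; b <- x[2] - x[1]
  out <- numeric(0)
  for (t in 2:length(x)) {
    S_new <- alpha * x[t] + (1 - alpha) * (S + b)
    b <- gamma * (S_new - S) + (1 - gamma) * b
    S <- S_new
    out <- c(out, S + b)          # one-step forecast issued at frame t-1
  }
  out
}

test_that("state initialization follows the first two observations", {
  st <- des_init_translation(c(0, 0, 0), c(1, 0, 0), 0.5, 0.5)
  expect_equal(st$S, c(0, 0, 0)); expect_equal(st$b, c(1, 0, 0))
  expect_equal(des_init_translation(c(2, 3, 4), c(2, 3, 4), 0.5, 0.5)$b, c(0, 0, 0))
  expect_equal(des_init_translation(c(2, 3, 4), c(1, 1, 1), 0.5, 0.5)$b, c(-1, -2, -3))
  sr <- des_init_rotation(Rz(10), Rz(25), 0.5, 0.5)
  expect_equal(quat_angular_distance(sr$b, Rz(15)), 0, tolerance = 1e-9)
  expect_equal(quat_angular_distance(des_init_rotation(Rz(5), Rz(5), 0.5, 0.5)$b,
                                     quat_identity()), 0, tolerance = 1e-9)
})

test_that("one translation update matches the hand-evaluated recursion", {
  st <- des_init_translation(c(0, 0, 0), c(1, 0, 0), 0.5, 0.5)
  st <- des_update_translation(st, c(1, 0, 0))
  expect_equal(st$S, c(1, 0, 0))
  expect_equal(st$b, c(1, 0, 0))
  expect_equal(st$t, 1L)
})

test_that("alpha = 1, gamma = 0 tracks the observation with a frozen trend", {
  set.seed(1)
  st <- des_init_translation(c(0, 0, 0), c(2, -1, 3), 1, 0)
  b0 <- st$b
  for (i in 1:20) {
    obs <- runif(3, -10, 10)
    st <- des_update_translation(st, obs)
    expect_equal(st$S, obs)
    expect_equal(st$b, b0)
  }
  sr <- des_init_rotation(quat_identity(), Rz(4), 1, 0)
  q <- rand_quat()
  sr <- des_update_rotation(sr, q)
  expect_equal(quat_angular_distance(sr$S, q), 0, tolerance = 1e-9)
})

test_that("constant-velocity streams are forecast exactly for any smoothing factors", {
  v <- c(0.4, -0.7, 1.1)
  traj <- trajectory_from_transforms(
    lapply(0:60, function(t) rigid_transform(translation = t * v)))
  for (alpha in c(0.1, 0.5, 1)) {
    for (gamma in c(0.1, 0.6, 1)) {
      fc <- forecast_trajectory(traj, alpha, gamma, alpha, gamma, m = 1)
      expect_lt(max(fc$te_mm), 1e-9)
    }
  }
})

test_that("constant-increment rotation streams are forecast exactly, across the double cover", {
  # 10 degrees per frame for 50 frames sweeps past a half rotation, so the
  # raw quaternion components change hemisphere mid-stream
  th <- rotation_stream(rand_quat(), quat_from_axis_angle(c(0.3, 1, 0.2), 10), 50)
  traj <- trajectory_from_transforms(lapply(th, function(q) rigid_transform(q)))
  for (alpha in c(0.2, 0.7, 1)) {
    for (gamma in c(0.3, 0.8)) {
      fc <- forecast_trajectory(traj, 0.5, 0.5, alpha, gamma, m = 1)
      expect_lt(max(fc$re_deg), 1e-7)
    }
  }
})

test_that("each translation coordinate equals the scalar Holt recursion", {
  set.seed(2)
  n <- 40
  xs <- matrix(rnorm(3 * n, sd = 5), ncol = 3)
  traj <- trajectory_from_transforms(
    lapply(seq_len(n), function(i) rigid_transform(translation = xs[i, ])))
  alpha <- 0.6; gamma <- 0.4
  fc <- forecast_trajectory(traj, alpha, gamma, 0.5, 0.5, m = 1)
  for (j in 1:3) {
    ref <- holt_scalar(xs[, j], alpha, gamma)
    # forecast issued at frame t (1-based row t+1) targets frame t+1
    pred <- fc$forecasts[[c("tx_mm", "ty_mm", "tz_mm")[j]]]
    expect_equal(pred, ref[seq_along(pred)], tolerance = 1e-9)
  }
})

test_that("the rotation channel reduces to scalar smoothing in the small-angle limit", {
  set.seed(3)
  angles <- cumsum(runif(30, -0.8, 0.9))    # degrees, all below 1 deg per step
  traj <- trajectory_from_transforms(lapply(angles, function(a) rigid_transform(Rz(a))))
  alpha <- 0.7; gamma <- 0.3
  fc <- forecast_trajectory(traj, 0.5, 0.5, alpha, gamma, m = 1)
  ref <- holt_scalar(angles, alpha, gamma)
  got <- vapply(seq_len(nrow(fc$forecasts)), function(i) {
    q <- quaternion(as.numeric(fc$forecasts[i, c("qw", "qx", "qy", "qz")]),
                    normalize = TRUE)
    s <- sign(q[4]) * sign(q[1])
    s * quat_angular_distance(quat_identity(), q)   # signed angle about z
  }, numeric(1))
  expect_equal(got, ref[seq_along(got)], tolerance = 1e-6)
})

test_that("translation forecasts are equivariant under a global frame rotation", {
  set.seed(4)
  n <- 25
  xs <- matrix(rnorm(3 * n, sd = 10), ncol = 3)
  G <- quat_to_matrix(rand_quat())
  t1 <- trajectory_from_transforms(
    lapply(seq_len(n), function(i) rigid_transform(translation = xs[i, ])))
  t2 <- trajectory_from_transforms(
    lapply(seq_len(n), function(i) rigid_transform(translation = as.numeric(G %*% xs[i, ]))))
  f1 <- forecast_trajectory(t1, 0.6, 0.7, 0.5, 0.5, m = 1)
  f2 <- forecast_trajectory(t2, 0.6, 0.7, 0.5, 0.5, m = 1)
  p1 <- as.matrix(f1$forecasts[, c("tx_mm", "ty_mm", "tz_mm")])
  p2 <- as.matrix(f2$forecasts[, c("tx_mm", "ty_mm", "tz_mm")])
  expect_equal(p1 %*% t(G), p2, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(f1$te_mm, f2$te_mm, tolerance = 1e-9)
})

test_that("the error series has length N - m - 1 and starts at the second frame", {
  set.seed(5)
  n <- 20
  traj <- trajectory_from_transforms(lapply(seq_len(n), function(i) rand_rt()))
  for (m in c(1L, 2L, 3L)) {
    fc <- forecast_trajectory(traj, 0.5, 0.5, 0.5, 0.5, m = m)
    expect_length(fc$te_mm, n - m - 1)
    expect_equal(fc$forecasts$frame[1], m + 1)     # first prediction target
  }
  expect_error(forecast_trajectory(traj[1:2, ], 0.5, 0.5, 0.5, 0.5), "3 frames")
})

test_that("forecasting rejects mismatched channel states and bad horizons", {
  st <- des_init_translation(c(0, 0, 0), c(1, 0, 0), 0.5, 0.5)
  sr <- des_init_rotation(quat_identity(), Rz(1), 0.5, 0.5)
  st2 <- des_update_translation(st, c(2, 0, 0))
  expect_error(des_forecast(st2, sr), "frame indices")
  expect_error(des_forecast(st, sr, m = 0), "positive")
  expect_error(des_init_translation(c(0, 0, 0), c(1, 0, 0), 1.2, 0.5), "\\[0, 1\\]")
})

test_that("the m-step forecast composes level and trend", {
  st <- des_init_translation(c(1, 0, 0), c(1.5, 0, 0), 0.5, 0.5)  # S=(1,0,0), b=(0.5,0,0)
  sr <- des_init_rotation(Rz(40), Rz(43.6), 0.5, 0.5)             # S=Rz(40), b=Rz(3.6)
  fc2 <- des_forecast(st, sr, m = 2)
  expect_equal(fc2$translation, c(2, 0, 0), tolerance = 1e-12)
  expect_equal(quat_angular_distance(fc2$rotation, Rz(47.2)), 0, tolerance = 1e-9)
  fc1 <- des_forecast(st, sr, m = 1)
  expect_equal(quat_angular_distance(fc1$rotation, Rz(43.6)), 0, tolerance = 1e-9)
})

test_that("noisy turning-wheel forecasts stay in the noise regime", {
  sigma <- 0.5
  scn <- wheel_scenario(period_s_per_turn = 15, duration_frames = 200, seed = 99,
                        noise_sigma_t_mm = sigma, noise_sigma_r_deg = 0.2)
  traj <- wheel_trajectory(scn)
  fc <- forecast_trajectory(traj, 0.7, 0.7, 0.7, 0.5, m = 1)
  med <- median(fc$te_mm)
  expect_gte(med, sigma / 2)
  expect_lte(med, 4 * sigma)
})

test_that("the tuned per-scenario optima table is consistent", {
  tab <- wheel_optimum_hyperparameters()
  expect_equal(nrow(tab), 3)
  hp <- wheel_optimum_hyperparameters(10)
  expect_equal(hp$alpha_rot, 0.8)
  expect_error(wheel_optimum_hyperparameters(20), "no tuned optimum")
})
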