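# Double Exponential Smoothing (Holt's method) of registration transforms.
#
# The translation channel is the classical vector Holt recursion
#   S_t = alpha * tau_t + (1 - alpha) * (S_{t-1} + b_{t-1})
#   b_t = gamma * (S_t - S_{t-1}) + (1 - gamma) * b_{t-1}
# and the rotation channel is its Lie-group analogue on unit quaternions,
# with SLERP as the convex blend and composition as the additive structure:
#   S_t = slerp(S_{t-1} * b_{t-1}, Theta_t, alpha)
#   b_t = slerp(b_{t-1}, S_{t-1}^-1 * S_t, gamma)
# The m-step forecast is tau = S + m b and Theta = S * b^m. For m = 1 this
# pre-computes the pose of the next frame, bypassing one frame interval of
# algorithmic latency.

#' Initialize the translation smoothing state
#'
#' `S_0 = tau_0`, `b_0 = tau_1 - tau_0`; the state thus needs the first two
#' observed translations.
#'
#' @param tau0,tau1 first two observed translation vectors (mm).
#' @param alpha data smoothing factor in `[0, 1]`.
#' @param gamma trend smoothing factor in `[0, 1]`.
#' @return a `des_translation_state`.
#' @export
des_init_translation <- function(tau0, tau1, alpha, gamma) {
  tau0 <- as.numeric(tau0); tau1 <- as.numeric(tau1)
  stopifnot(length(tau0) == 3, length(tau1) == 3,
            all(is.finite(tau0)), all(is.finite(tau1)))
  check_smoothing_factor(alpha, "alpha")
  check_smoothing_factor(gamma, "gamma")
  structure(list(S = tau0, b = tau1 - tau0, alpha = alpha, gamma = gamma, t = 0L),
            class = "des_translation_state")
}

check_smoothing_factor <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
    stop(sprintf("%s must be a single value in [0, 1]", name))
  invisible(x)
}

#' Initialize the rotation smoothing state
#'
#' `S_0 = Theta_0`, `b_0 = Theta_0^-1 * Theta_1` (the per-frame rotation
#' increment), with `b_0` sign-aligned to the identity hemisphere.
#'
#' @param theta0,theta1 first two observed rotation quaternions.
#' @param alpha,gamma smoothing factors in `[0, 1]`.
#' @return a `des_rotation_state`.
#' @export
des_init_rotation <- function(theta0, theta1, alpha, gamma) {
  theta0 <- quaternion(theta0)
  theta1 <- quat_align(quaternion(theta1), theta0)
  check_smoothing_factor(alpha, "alpha")
  check_smoothing_factor(gamma, "gamma")
  b0 <- quat_align(quat_multiply(quat_conjugate(theta0), theta1), quat_identity())
  structure(list(S = theta0, b = b0, alpha = alpha, gamma = gamma, t = 0L),
            class = "des_rotation_state")
}

#' Advance the translation state with a new observation
#'
#' @param state a `des_translation_state`.
#' @param tau_t observed translation (mm) at the next frame.
#' @return the updated state (frame index incremented).
#' @export
des_update_translation <- function(state, tau_t) {
  stopifnot(inherits(state, "des_translation_state"))
  tau_t <- as.numeric(tau_t)
  stopifnot(length(tau_t) == 3, all(is.finite(tau_t)))
  S_new <- state$alpha * tau_t + (1 - state$alpha) * (state$S + state$b)
  b_new <- state$gamma * (S_new - state$S) + (1 - state$gamma) * state$b
  state$S <- S_new; state$b <- b_new; state$t <- state$t + 1L
  state
}

#' Advance the rotation state with a new observation
#'
#' @param state a `des_rotation_state`.
#' @param theta_t observed rotation quaternion at the next frame.
#' @return the updated state (frame index incremented).
#' @export
des_update_rotation <- function(state, theta_t) {
  stopifnot(inherits(state, "des_rotation_state"))
  theta_t <- quaternion(theta_t)
  pred <- quat_multiply(state$S, state$b)       # S_{t-1} * b_{t-1}
  S_new <- quat_slerp(pred, theta_t, state$alpha)
  innov <- quat_multiply(quat_conjugate(state$S), S_new)  # S_{t-1}^-1 * S_t
  b_new <- quat_slerp(state$b, innov, state$gamma)
  state$S <- S_new; state$b <- b_new; state$t <- state$t + 1L
  state
}

#' Forecast the registration transform m frame intervals ahead
#'
#' Combines the two channels: translation `S + m b`, rotation
#' `S * b^m`. `m` may be fractional (sub-frame interpolation of the
#' forecast); the default `m = 1` predicts the next frame and thereby
#' bypasses one frame interval of pipeline latency.
#'
#' @param state_tau a `des_translation_state`.
#' @param state_rot a `des_rotation_state` at the same frame index.
#' @param m forecast horizon in frame intervals (> 0).
#' @return the forecast pose as a `rigid_transform`.
#' @export
des_forecast <- function(state_tau, state_rot, m = 1) {
  stopifnot(inherits(state_tau, "des_translation_state"),
            inherits(state_rot, "des_rotation_state"))
  if (!is.numeric(m) || length(m) != 1 || !is.finite(m) || m <= 0)
    stop("forecast horizon m must be a single positive number")
  if (state_tau$t != state_rot$t)
    stop(sprintf("channel states are at different frame indices (%d vs %d)",
                 state_tau$t, state_rot$t))
  rigid_transform(quat_multiply(state_rot$S, quat_power(state_rot$b, m)),
                  state_tau$S + m * state_tau$b)
}

# ---------------------------------------------------------------------------
# Trajectories: data frames with columns
#   frame, time_s, qw, qx, qy, qz, tx_mm, ty_mm, tz_mm

#' Assemble a trajectory data frame from a list of rigid transforms
#'
#' @param transforms list of `rigid_transform` objects, one per frame.
#' @param dt_s frame interval in seconds (timestamps only; forecasting is
#'   index-based).
#' @return a trajectory `data.frame` with columns `frame`, `time_s`,
#'   `qw, qx, qy, qz`, `tx_mm, ty_mm, tz_mm`.
#' @export
trajectory_from_transforms <- function(transforms, dt_s = 0.1) {
  stopifnot(length(transforms) >= 1)
  q <- t(vapply(transforms, function(x) as.numeric(x$rotation), numeric(4)))
  tr <- t(vapply(transforms, function(x) x$translation, numeric(3)))
  n <- length(transforms)
  data.frame(frame = seq_len(n) - 1L, time_s = (seq_len(n) - 1L) * dt_s,
             qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4],
             tx_mm = tr[, 1], ty_mm = tr[, 2], tz_mm = tr[, 3])
}

#' Extract one pose of a trajectory as a rigid transform
#'
#' @param trajectory a trajectory `data.frame`.
#' @param i row index (1-based).
#' @return a `rigid_transform`.
#' @export
trajectory_pose <- function(trajectory, i) {
  rigid_transform(quaternion(as.numeric(trajectory[i, c("qw", "qx", "qy", "qz")]),
                             normalize = TRUE),
                  as.numeric(trajectory[i, c("tx_mm", "ty_mm", "tz_mm")]))
}

#' Read / write a trajectory CSV
#'
#' Columns: `frame, time_s, qw, qx, qy, qz, tx_mm, ty_mm, tz_mm`.
#'
#' @param path CSV path.
#' @return `read_trajectory_csv`: a trajectory `data.frame`.
#' @export
read_trajectory_csv <- function(path) {
  x <- utils::read.csv(path)
  need <- c("frame", "time_s", "qw", "qx", "qy", "qz", "tx_mm", "ty_mm", "tz_mm")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("trajectory CSV is missing columns: ", paste(missing, collapse = ", "))
  x
}

#' @param trajectory a trajectory `data.frame`.
#' @rdname read_trajectory_csv
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(trajectory, path, row.names = FALSE)
  invisible(path)
}

#' Forecast a whole observed trajectory and score the errors
#'
#' The smoothing states are initialized from frames 0 and 1 and then advanced
#' through the remaining observations; the first scored forecast is issued at
#' the second frame (index 1) for frame `1 + m`. Each forecast for frame
#' `t + m` is compared against the observed transform at `t + m`, giving
#' `N - m - 1` error values for an `N`-frame trajectory.
#'
#' @param observed trajectory `data.frame` with at least 3 frames.
#' @param alpha_tau,gamma_tau translation-channel smoothing factors.
#' @param alpha_rot,gamma_rot rotation-channel smoothing factors.
#' @param m integer forecast horizon in frames (default 1).
#' @return list with `forecasts` (trajectory `data.frame` of the forecast
#'   poses, with `frame` the index of the predicted frame and appended
#'   `te_mm`, `re_deg` columns), `te_mm` and `re_deg` error vectors.
#' @export
forecast_trajectory <- function(observed, alpha_tau, gamma_tau,
                                alpha_rot, gamma_rot, m = 1L) {
  n <- nrow(observed)
  if (is.null(n) || n < 3) stop("forecasting a trajectory requires at least 3 frames")
  m <- as.integer(m)
  if (m < 1) stop("forecast horizon m must be >= 1")
  poses <- lapply(seq_len(n), function(i) trajectory_pose(observed, i))
  st <- des_init_translation(poses[[1]]$translation, poses[[2]]$translation,
                             alpha_tau, gamma_tau)
  sr <- des_init_rotation(poses[[1]]$rotation, poses[[2]]$rotation,
                          alpha_rot, gamma_rot)
  n_fc <- n - m - 1L
  if (n_fc < 1) stop("trajectory too short for the requested horizon")
  fc <- vector("list", n_fc)
  te <- re <- numeric(n_fc)
  for (t in 1L:(n - 1L)) {       # 0-based frame index t; observation poses[[t+1]]
    st <- des_update_translation(st, poses[[t + 1L]]$translation)
    sr <- des_update_rotation(sr, poses[[t + 1L]]$rotation)
    k <- t                       # forecast issued at frame t, targets t + m
    if (k <= n_fc) {
      pred <- des_forecast(st, sr, m)
      fc[[k]] <- pred
      truth <- poses[[t + m + 1L]]
      err <- forecast_errors(truth, pred)
      te[k] <- err$te_mm
      re[k] <- err$re_deg
    }
  }
  forecasts <- trajectory_from_transforms(fc, dt_s = if ("time_s" %in% names(observed) && n > 1)
    observed$time_s[2] - observed$time_s[1] else 0.1)
  forecasts$frame <- seq_len(n_fc) + m     # index of the predicted frame
  forecasts$time_s <- observed$time_s[forecasts$frame + 1L]
  forecasts$te_mm <- te
  forecasts$re_deg <- re
  list(forecasts = forecasts, te_mm = te, re_deg = re)
}

#' Optimum smoothing factors for the turning-wheel motion scenarios
#'
#' Per-scenario optima of the design-of-experiments / response-surface tuning
#' study on the mechanical turning wheel, one row per rotation period
#' (seconds per turn). These are the hyperparameters the navigation runs use
#' by default for the matching motion scenario.
#'
#' @param period_s_per_turn optional period (30, 15 or 10); if given, the
#'   matching row is returned as a list.
#' @return a `data.frame` of optima (or a single-row list).
#' @export
wheel_optimum_hyperparameters <- function(period_s_per_turn = NULL) {
  tab <- data.frame(
    period_s_per_turn = c(30, 15, 10),
    alpha_tau = c(0.7, 0.7, 0.7),
    gamma_tau = c(0.7, 0.7, 0.7),
    alpha_rot = c(0.7, 0.7, 0.8),
    gamma_rot = c(0.3, 0.5, 0.6))
  if (is.null(period_s_per_turn)) return(tab)
  i <- match(period_s_per_turn, tab$period_s_per_turn)
  if (is.na(i)) stop("no tuned optimum for period ", period_s_per_turn,
                     " s per turn (have 30, 15, 10)")
  as.list(tab[i, ])
}
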