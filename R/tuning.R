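# Design-of-experiments sweep over the smoothing hyperparameters and
# quadratic response-surface fitting/minimization.

#' Full-factorial sweep of the smoothing hyperparameters
#'
#' Runs [forecast_trajectory()] for every `(alpha, gamma)` combination of the
#' level grid and records the mean (and median) translation and rotation
#' forecast errors. The translation error of a cell depends only on the
#' translation-channel factors and the rotation error only on the
#' rotation-channel factors, so one grid serves both channels; they are
#' fitted and minimized separately.
#'
#' @param trajectory observed trajectory `data.frame` (>= 3 frames).
#' @param levels hyperparameter levels in `[0, 1]` (default 0.0 to 1.0 in
#'   increments of 0.1, the 121-cell design).
#' @param m forecast horizon in frames.
#' @return an `error_surface` list with `grid` (`data.frame` of
#'   `alpha, gamma, mean_te_mm, mean_re_deg, median_te_mm, median_re_deg`),
#'   the `levels`, and `m`.
#' @export
doe_sweep <- function(trajectory, levels = seq(0, 1, by = 0.1), m = 1L) {
  if (any(levels < 0 | levels > 1)) stop("levels must lie in [0, 1]")
  design <- expand.grid(alpha = levels, gamma = levels,
                        KEEP.OUT.ATTRS = FALSE)
  res <- vapply(seq_len(nrow(design)), function(i) {
    fc <- forecast_trajectory(trajectory,
                              alpha_tau = design$alpha[i], gamma_tau = design$gamma[i],
                              alpha_rot = design$alpha[i], gamma_rot = design$gamma[i],
                              m = m)
    c(mean(fc$te_mm), mean(fc$re_deg),
      stats::median(fc$te_mm), stats::median(fc$re_deg))
  }, numeric(4))
  grid <- cbind(design,
                mean_te_mm = res[1, ], mean_re_deg = res[2, ],
                median_te_mm = res[3, ], median_re_deg = res[4, ])
  structure(list(grid = grid, levels = levels, m = m), class = "error_surface")
}

#' Fit a quadratic response surface to a sweep grid
#'
#' Ordinary least squares fit of
#' `f(alpha, gamma) = b0 + b1 a + b2 g + b3 a^2 + b4 g^2 + b5 a g`
#' (full quadratic, cubic terms neglected) to one error column of the sweep.
#'
#' @param grid sweep `data.frame` with columns `alpha`, `gamma` and the
#'   response (or an `error_surface`, whose `$grid` is used).
#' @param response column name to fit (default `"mean_te_mm"`).
#' @return coefficient vector of length 6 named
#'   `b0, b_alpha, b_gamma, b_alpha2, b_gamma2, b_alphagamma`, with the
#'   fitted `lm` in attribute `fit` and residuals in attribute `residuals`.
#' @export
fit_response_surface <- function(grid, response = "mean_te_mm") {
  if (inherits(grid, "error_surface")) grid <- grid$grid
  if (!response %in% names(grid)) stop("no response column '", response, "' in grid")
  d <- data.frame(y = grid[[response]], a = grid$alpha, g = grid$gamma)
  if (nrow(unique(d[, c("a", "g")])) < 6)
    stop("rank-deficient design: need at least 6 distinct (alpha, gamma) points")
  fit <- stats::lm(y ~ a + g + I(a^2) + I(g^2) + I(a * g), data = d)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design: quadratic surface is not identifiable")
  coeffs <- unname(stats::coef(fit))
  names(coeffs) <- c("b0", "b_alpha", "b_gamma", "b_alpha2", "b_gamma2", "b_alphagamma")
  attr(coeffs, "residuals") <- unname(stats::residuals(fit))
  attr(coeffs, "fit") <- fit
  coeffs
}

surface_value <- function(coeffs, a, g) {
  coeffs[1] + coeffs[2] * a + coeffs[3] * g + coeffs[4] * a^2 +
    coeffs[5] * g^2 + coeffs[6] * a * g
}

#' Minimize a fitted quadratic surface over the unit box
#'
#' Returns the stationary point when the Hessian is positive definite and
#' the point lies in `[0, 1]^2`; otherwise the minimum of the quadratic over
#' the box boundary (each edge is a closed-form 1-D quadratic). Optionally
#' also reports the optimum snapped to the nearest design level.
#'
#' @param coeffs 6-vector from [fit_response_surface()].
#' @param levels optional design levels for snapped reporting.
#' @return list with `alpha`, `gamma`, `value`, `interior` (whether the
#'   interior stationary point was used) and, when `levels` is given,
#'   `alpha_snapped`, `gamma_snapped`.
#' @export
minimize_surface <- function(coeffs, levels = NULL) {
  H <- matrix(c(2 * coeffs[4], coeffs[6], coeffs[6], 2 * coeffs[5]), 2, 2)
  gvec <- c(coeffs[2], coeffs[3])
  interior <- FALSE
  best <- NULL
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (all(ev > 1e-12)) {
    sp <- solve(H, -gvec)
    if (all(sp >= 0 & sp <= 1)) {
      interior <- TRUE
      best <- list(alpha = sp[1], gamma = sp[2],
                   value = unname(surface_value(coeffs, sp[1], sp[2])))
    }
  }
  if (is.null(best)) {
    # boundary search: four edges, each a 1-D quadratic with closed-form
    # candidates (vertex if it falls inside the edge, plus the endpoints)
    cand <- expand.grid(a = c(0, 1), g = c(0, 1))
    edge_candidates <- function(fixed, which_fixed) {
      if (which_fixed == "a") {   # minimize over g with a fixed
        qa <- coeffs[5]; qb <- coeffs[3] + coeffs[6] * fixed
        v <- if (abs(qa) > 1e-15) -qb / (2 * qa) else NA_real_
        if (!is.na(v) && v > 0 && v < 1) data.frame(a = fixed, g = v) else NULL
      } else {
        qa <- coeffs[4]; qb <- coeffs[2] + coeffs[6] * fixed
        v <- if (abs(qa) > 1e-15) -qb / (2 * qa) else NA_real_
        if (!is.na(v) && v > 0 && v < 1) data.frame(a = v, g = fixed) else NULL
      }
    }
    for (f in c(0, 1)) {
      cand <- rbind(cand, edge_candidates(f, "a"), edge_candidates(f, "g"))
    }
    vals <- surface_value(coeffs, cand$a, cand$g)
    i <- which.min(vals)
    best <- list(alpha = cand$a[i], gamma = cand$g[i], value = unname(vals[i]))
  }
  best$interior <- interior
  if (!is.null(levels)) {
    best$alpha_snapped <- levels[which.min(abs(levels - best$alpha))]
    best$gamma_snapped <- levels[which.min(abs(levels - best$gamma))]
  }
  best
}

#' Sweep, fit and minimize both channels of a trajectory
#'
#' Convenience wrapper running the full tuning procedure: factorial sweep,
#' quadratic response-surface fit per channel, and box-constrained
#' minimization, yielding the recommended `(alpha, gamma)` per channel.
#'
#' @inheritParams doe_sweep
#' @param objective `"mean"` (the sweep objective) or `"median"`.
#' @return list with `surface` (the `error_surface`), `coeffs_te`,
#'   `coeffs_re`, `optimum_te`, `optimum_re`.
#' @export
tune_hyperparameters <- function(trajectory, levels = seq(0, 1, by = 0.1),
                                 m = 1L, objective = c("mean", "median")) {
  objective <- match.arg(objective)
  pre <- if (objective == "mean") "mean" else "median"
  surface <- doe_sweep(trajectory, levels = levels, m = m)
  coeffs_te <- fit_response_surface(surface, paste0(pre, "_te_mm"))
  coeffs_re <- fit_response_surface(surface, paste0(pre, "_re_deg"))
  list(surface = surface,
       coeffs_te = coeffs_te, coeffs_re = coeffs_re,
       optimum_te = minimize_surface(coeffs_te, levels = levels),
       optimum_re = minimize_surface(coeffs_re, levels = levels))
}
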