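# Multi-device calibration: the transform chain linking the head-mounted
# display (H), the RGB-D sensor (R), the calibration chart (C), the tracked
# reference system (E) and the organ model (L), plus Horn's closed-form
# fiducial registration.
#
# All transforms here are column-convention frame maps: `T_A_B` maps point
# coordinates from frame B to frame A, so chains read right-to-left
# (`T_A_C = T_A_B o T_B_C`). Chart-based device calibration observes the
# chart pose in each device frame (`T_R_C`, `T_H_C`); the device offset
# follows as `T_H_R = T_H_C o T_R_C^-1`.

#' Device offset from a commonly observed calibration chart
#'
#' Both devices observe the same chart; the offset between them is the chain
#' through the chart: `T_H_R = T_H_C o T_R_C^-1`, mapping sensor-frame
#' coordinates into display-frame coordinates.
#'
#' @param T_R_C chart pose in the sensor frame (`rigid_transform`).
#' @param T_H_C chart pose in the display frame.
#' @return the display-from-sensor offset `T_H_R`.
#' @export
chain_offset <- function(T_R_C, T_H_C) {
  rt_compose(T_H_C, rt_invert(T_R_C))
}

#' Initial model pose in the sensor frame from the user pre-alignment
#'
#' The user pre-positions the virtual model in display space
#' (`T_H_L0`, the model pose seen by the display); the registration loop
#' needs the equivalent sensor-frame pose:
#' `T_R_L(0) = T_H_R^-1 o T_H_L(0)`.
#'
#' @param T_H_L0 pre-alignment model pose in the display frame.
#' @param T_H_R display-from-sensor offset from [chain_offset()].
#' @return the model pose in the sensor frame, `T_R_L(0)`.
#' @export
init_registration <- function(T_H_L0, T_H_R) {
  rt_compose(rt_invert(T_H_R), T_H_L0)
}

#' Display-space pose of the registered model
#'
#' Inverse chain of [init_registration()]:
#' `T_H_L(t) = T_H_R o T_R_L(t)`.
#'
#' @param T_R_L_t registered model pose in the sensor frame at frame `t`.
#' @param T_H_R display-from-sensor offset.
#' @return the model pose in the display frame, `T_H_L(t)`.
#' @export
to_display <- function(T_R_L_t, T_H_R) {
  rt_compose(T_H_R, T_R_L_t)
}

#' Horn's closed-form fiducial registration
#'
#' Least-squares rigid transform mapping fiducial coordinates measured in
#' frame A onto the same fiducials measured in frame B
#' (`b_i ~ R a_i + tau`), solved in closed form by the quaternion
#' eigenvector method: after centroid alignment the optimal rotation is the
#' largest-eigenvalue eigenvector of the 4x4 correlation matrix, which is the
#' global optimum of the summed squared residuals. No scale is estimated
#' (all devices share metric units).
#'
#' @param points_a N x 3 fiducial coordinates in frame A (mm), N >= 3,
#'   non-collinear.
#' @param points_b N x 3 corresponding coordinates in frame B (mm).
#' @return a `rigid_transform` `T_B_A` with attribute `fre_mm`, the fiducial
#'   registration error (RMS residual at the fiducials).
#' @export
horn_fiducial_registration <- function(points_a, points_b) {
  a <- as.matrix(points_a); b <- as.matrix(points_b)
  if (nrow(a) != nrow(b)) stop("fiducial sets must have equal point counts")
  if (nrow(a) < 3) stop("Horn's method needs at least 3 fiducials")
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  # collinearity check: rank of the centered configuration
  sv <- svd(ac)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("degenerate fiducial set: points are collinear (rank < 2), rotation is not unique")
  M <- crossprod(ac, bc)   # sum a_i' b_i'^T
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  e <- eigen(N, symmetric = TRUE)
  q <- quaternion(e$vectors[, 1], normalize = TRUE)
  R <- quat_to_matrix(q)
  tau <- cb - as.numeric(R %*% ca)
  tf <- rigid_transform(q, tau)
  res <- rt_apply(tf, a) - b
  attr(tf, "fre_mm") <- sqrt(mean(rowSums(res^2)))
  tf
}

#' Read / write a fiducial CSV
#'
#' Columns: `id, ax_mm, ay_mm, az_mm, bx_mm, by_mm, bz_mm` — the same
#' physical fiducials measured in frames A and B.
#'
#' @param path CSV path.
#' @return `read_fiducials_csv`: list with `points_a`, `points_b` (N x 3
#'   matrices) and `id`.
#' @export
read_fiducials_csv <- function(path) {
  x <- utils::read.csv(path)
  need <- c("id", "ax_mm", "ay_mm", "az_mm", "bx_mm", "by_mm", "bz_mm")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("fiducial CSV is missing columns: ", paste(missing, collapse = ", "))
  list(id = x$id,
       points_a = as.matrix(x[, c("ax_mm", "ay_mm", "az_mm")]),
       points_b = as.matrix(x[, c("bx_mm", "by_mm", "bz_mm")]))
}

#' @param fiducials list with `points_a`, `points_b` and optionally `id`.
#' @rdname read_fiducials_csv
#' @export
write_fiducials_csv <- function(fiducials, path) {
  a <- as.matrix(fiducials$points_a); b <- as.matrix(fiducials$points_b)
  id <- if (is.null(fiducials$id)) seq_len(nrow(a)) else fiducials$id
  utils::write.csv(data.frame(id = id,
                              ax_mm = a[, 1], ay_mm = a[, 2], az_mm = a[, 3],
                              bx_mm = b[, 1], by_mm = b[, 2], bz_mm = b[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Bundle / restore a calibration set as JSON
#'
#' The calibration set holds the chart observations `T_R_C` and `T_H_C`, the
#' derived device offset `T_H_R` and the sensor-to-reference alignment
#' `T_E_R` used for evaluation.
#'
#' @param calibration named list of `rigid_transform`s
#'   (`T_R_C`, `T_H_C`, `T_H_R`, `T_E_R`; missing entries allowed).
#' @param path JSON path.
#' @export
write_calibration_json <- function(calibration, path) {
  out <- lapply(calibration, function(t) {
    if (inherits(t, "rigid_transform")) transform_to_list(t) else t
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_calibration_json
#' @return `read_calibration_json`: named list of `rigid_transform`s.
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(x, function(e) {
    if (is.list(e) && (!is.null(e$quaternion_wxyz) || !is.null(e$matrix)))
      transform_from_list(e)
    else e
  })
}
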