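# Evaluation metrics: target registration error, Chamfer distance, mask
# overlap measures, forecast errors and registration success rate.

#' Target registration error of a registration transform
#'
#' RMS Euclidean distance between reference landmarks measured in the
#' external reference frame (`r_i`) and the model-side landmarks (`p_i`)
#' mapped through the registration and then the sensor-to-reference
#' alignment:
#' `TRE = sqrt( mean_i || r_i - (T_E_R o T_R_L)(p_i) ||^2 )`.
#'
#' @param model_points N x 3 landmark coordinates in the model frame (mm).
#' @param reference_points N x 3 corresponding landmarks measured in the
#'   reference frame (mm); the classical evaluation uses N = 3.
#' @param T_R_L registration transform (model pose in the sensor frame).
#' @param T_E_R sensor-to-reference alignment (identity when the landmarks
#'   are already expressed in the sensor frame).
#' @return TRE in mm.
#' @export
tre <- function(model_points, reference_points, T_R_L, T_E_R = rt_identity()) {
  p <- as.matrix(model_points); r <- as.matrix(reference_points)
  if (nrow(p) != nrow(r) || nrow(p) < 1)
    stop("landmark sets must be non-empty and of equal size")
  mapped <- rt_apply(rt_compose(T_E_R, T_R_L), p)
  sqrt(mean(rowSums((r - mapped)^2)))
}

#' Symmetric Chamfer distance between two point clouds
#'
#' Average of the two directed mean nearest-neighbour distances
#' (`a` to `b` and `b` to `a`), in mm. Symmetric by construction.
#'
#' @param a,b non-empty N x 3 point matrices (mm).
#' @return Chamfer distance in mm.
#' @export
chamfer_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("Chamfer distance requires non-empty clouds")
  .chamfer_cpp(a, b)
}

#' Intersection-over-union of two binary masks
#'
#' @param mask_a,mask_b logical matrices of identical shape.
#' @return `|A intersect B| / |A union B|` in `[0, 1]`; defined as 1 when
#'   both masks are empty.
#' @export
iou <- function(mask_a, mask_b) {
  mask_a <- as.matrix(mask_a); mask_b <- as.matrix(mask_b)
  if (!all(dim(mask_a) == dim(mask_b))) stop("mask shapes must match")
  a <- mask_a != 0; b <- mask_b != 0
  uni <- sum(a | b)
  if (uni == 0) return(1)
  sum(a & b) / uni
}

#' Visibility factor of a mask relative to an unoccluded reference
#'
#' Percentage of reference-mask pixels that remain visible:
#' `100 * |mask intersect reference| / |reference|`. This is the occlusion
#' measure used to grade the resection scenarios.
#'
#' @param mask logical matrix (possibly occluded segmentation).
#' @param reference_mask logical matrix, the unoccluded reference; must be
#'   non-empty.
#' @return visibility in percent.
#' @export
visibility_factor <- function(mask, reference_mask) {
  mask <- as.matrix(mask); reference_mask <- as.matrix(reference_mask)
  if (!all(dim(mask) == dim(reference_mask))) stop("mask shapes must match")
  ref <- reference_mask != 0
  if (!any(ref)) stop("reference mask is empty")
  100 * sum((mask != 0) & ref) / sum(ref)
}

#' Translation and rotation error between two poses
#'
#' Scores a forecast against the pose it predicted: Euclidean distance of
#' the translations (mm) and angular distance of the rotation quaternions
#' (degrees).
#'
#' @param real,predicted `rigid_transform` objects.
#' @return list with `te_mm` and `re_deg`.
#' @export
forecast_errors <- function(real, predicted) {
  stopifnot(inherits(real, "rigid_transform"), inherits(predicted, "rigid_transform"))
  list(te_mm = sqrt(sum((real$translation - predicted$translation)^2)),
       re_deg = quat_angular_distance(real$rotation, predicted$rotation))
}

#' Registration success rate over repeated trials
#'
#' A trial succeeds when its registration converged and its final error is
#' below the threshold; the rate is the percentage of successful trials.
#'
#' @param outcomes a `data.frame` (or list of lists) with elements
#'   `final_error` (mm) and `converged` (logical).
#' @param threshold_mm success threshold on the final error (default 20 mm).
#' @return success rate in percent.
#' @export
success_rate <- function(outcomes, threshold_mm = 20) {
  if (is.data.frame(outcomes)) {
    err <- outcomes$final_error; cvg <- outcomes$converged
  } else {
    if (length(outcomes) == 0) stop("success_rate needs at least one trial")
    err <- vapply(outcomes, function(x) x$final_error, numeric(1))
    cvg <- vapply(outcomes, function(x) isTRUE(x$converged), logical(1))
  }
  if (length(err) == 0) stop("success_rate needs at least one trial")
  100 * mean(cvg & err < threshold_mm)
}
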