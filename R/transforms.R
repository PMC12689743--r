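# Rigid-body transform algebra and quaternion utilities.
#
# Conventions (fixed package-wide):
#   * column vectors, left multiplication: p' = R p + tau
#   * quaternion component order w,x,y,z; unit norm enforced after every
#     construction and operation
#   * millimetres for all lengths, degrees for user-facing angles
#   * every binary quaternion operation sign-aligns its second argument to the
#     first before blending/differencing (q and -q are the same rotation)

.QUAT_TOL <- 1e-6

#' Construct a unit quaternion
#'
#' Quaternions are stored as plain numeric vectors in `w, x, y, z` order with
#' class `"quaternion"`. The input is renormalized; an input whose norm
#' deviates from 1 by more than `tol` is rejected unless `normalize = TRUE`.
#'
#' @param wxyz numeric length-4 vector `(w, x, y, z)`.
#' @param normalize if `TRUE`, accept any non-zero vector and rescale it.
#' @param tol maximum tolerated deviation of the input norm from 1 when
#'   `normalize = FALSE`.
#' @return a unit `quaternion`.
#' @export
#' @examples
#' quaternion(c(1, 0, 0, 0))               # identity rotation
#' quat_from_axis_angle(c(0, 0, 1), 90)    # 90 degrees about z
quaternion <- function(wxyz, normalize = FALSE, tol = .QUAT_TOL) {
  wxyz <- as.numeric(wxyz)
  if (length(wxyz) != 4L || !all(is.finite(wxyz)))
    stop("quaternion requires 4 finite components (w, x, y, z)")
  n <- sqrt(sum(wxyz^2))
  if (n < 1e-12)
    stop("cannot normalize a zero quaternion")
  if (!normalize && abs(n - 1) > tol)
    stop(sprintf("quaternion norm %.6g deviates from 1 beyond tolerance %g", n, tol))
  structure(wxyz / n, class = "quaternion")
}

#' @export
print.quaternion <- function(x, ...) {
  cat(sprintf("<quaternion> w=%.6f x=%.6f y=%.6f z=%.6f\n", x[1], x[2], x[3], x[4]))
  invisible(x)
}

#' Identity quaternion
#' @return the unit quaternion `(1, 0, 0, 0)`.
#' @export
quat_identity <- function() quaternion(c(1, 0, 0, 0))

#' Quaternion from axis and angle
#'
#' @param axis 3-vector rotation axis (any non-zero length).
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @return a unit `quaternion`.
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) {
    if (abs(angle_deg) < 1e-12) return(quat_identity())
    stop("rotation axis must be non-zero")
  }
  half <- angle_deg * pi / 360
  quaternion(c(cos(half), sin(half) * axis / n))
}

#' Axis-angle decomposition of a quaternion
#'
#' @param q unit quaternion.
#' @return list with `axis` (unit 3-vector) and `angle_deg` in `[0, 360)`;
#'   the axis of an identity rotation is reported as `(1, 0, 0)`.
#' @export
quat_to_axis_angle <- function(q) {
  q <- quaternion(q)
  v <- q[2:4]
  s <- sqrt(sum(v^2))
  if (s < 1e-12) return(list(axis = c(1, 0, 0), angle_deg = 0))
  angle <- 2 * atan2(s, q[1])
  list(axis = v / s, angle_deg = angle * 180 / pi)
}

#' Hamilton product of two quaternions
#' @param a,b unit quaternions.
#' @return the unit quaternion `a * b` (apply `b`'s rotation first).
#' @export
quat_multiply <- function(a, b) {
  a <- quaternion(a); b <- quaternion(b)
  quaternion(c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]))
}

#' Quaternion conjugate (inverse rotation for unit quaternions)
#' @param q unit quaternion.
#' @return the conjugate quaternion.
#' @export
quat_conjugate <- function(q) {
  q <- quaternion(q)
  quaternion(c(q[1], -q[2:4]))
}

#' Sign-align a quaternion to a reference hemisphere
#'
#' Flips the sign of `q` when `dot(reference, q) < 0` so that blending and
#' differencing operate on the short arc. `q` and `-q` encode the same
#' rotation (double cover), so this never changes the rotation.
#'
#' @param q,reference unit quaternions.
#' @return `q` or `-q`, whichever lies on `reference`'s hemisphere.
#' @export
quat_align <- function(q, reference) {
  q <- quaternion(q); reference <- quaternion(reference)
  if (sum(q * reference) < 0) quaternion(-unclass(q)) else q
}

#' Spherical linear interpolation between unit quaternions
#'
#' Constant-speed geodesic interpolation on the unit quaternion hemisphere.
#' `q1` is sign-aligned to `q0` first; nearly parallel inputs fall back to a
#' normalized linear blend.
#'
#' @param q0,q1 unit quaternions.
#' @param u interpolation fraction; 0 returns `q0`, 1 returns `q1` (up to
#'   sign). Values outside `[0, 1]` extrapolate along the same geodesic.
#' @return interpolated unit quaternion.
#' @export
quat_slerp <- function(q0, q1, u) {
  q0 <- quaternion(q0)
  q1 <- quat_align(q1, q0)
  d <- min(1, max(-1, sum(q0 * q1)))
  if (d > 1 - 1e-10) {   # same rotation: linear blend + renormalize
    return(quaternion((1 - u) * unclass(q0) + u * unclass(q1), normalize = TRUE))
  }
  omega <- acos(d)
  so <- sin(omega)
  quaternion((sin((1 - u) * omega) / so) * unclass(q0) +
             (sin(u * omega) / so) * unclass(q1), normalize = TRUE)
}

#' Real power of a unit quaternion
#'
#' Scales the rotation angle about the fixed axis: `quat_power(q, m)` rotates
#' about `q`'s axis by `m` times `q`'s angle. `m` may be fractional (used for
#' fractional forecast horizons).
#'
#' @param q unit quaternion.
#' @param m real exponent.
#' @return unit quaternion `q^m`.
#' @export
quat_power <- function(q, m) {
  q <- quaternion(q)
  aa <- quat_to_axis_angle(q)
  if (aa$angle_deg == 0) return(quat_identity())
  # shortest representation: fold angles > 180 deg onto the negative arc
  ang <- aa$angle_deg
  if (ang > 180) ang <- ang - 360
  quat_from_axis_angle(aa$axis, m * ang)
}

#' Angular distance between two rotations
#'
#' Rotation angle of the relative rotation `qa^-1 * qb`, in degrees, in
#' `[0, 180]`. Insensitive to the quaternion double cover: `q` and `-q` are
#' at distance zero. The quaternion-space half-angle
#' `acos(|<qa, qb>|)` is available via `half_angle = TRUE`.
#'
#' @param qa,qb unit quaternions.
#' @param half_angle report the quaternion-space angle (half the rotation
#'   angle) instead of the rotation angle.
#' @return angle in degrees.
#' @export
quat_angular_distance <- function(qa, qb, half_angle = FALSE) {
  qa <- quaternion(qa); qb <- quaternion(qb)
  r <- quat_multiply(quat_conjugate(qa), qb)
  # atan2 form: numerically exact near zero, unlike acos of the dot product
  half <- atan2(sqrt(sum(r[2:4]^2)), abs(r[1])) * 180 / pi
  if (half_angle) half else 2 * half
}

#' 3x3 rotation matrix of a quaternion
#' @param q unit quaternion.
#' @return 3x3 orthonormal rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- quaternion(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

#' Quaternion of a 3x3 rotation matrix
#'
#' Shepperd's numerically stable branch selection; the result has `w >= 0`.
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1 within `tol`).
#' @param tol orthonormality tolerance.
#' @return unit quaternion.
#' @export
quat_from_matrix <- function(R, tol = 1e-6) {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3, 3))) stop("rotation matrix must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > tol || det(R) < 0)
    stop("matrix is not a proper rotation (orthonormal, det +1)")
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  quaternion(q, normalize = TRUE)
}

# ---------------------------------------------------------------------------
# Rigid transforms

#' Construct a rigid transform
#'
#' A rigid transform maps points by `p' = R p + tau` (column-vector, left
#' multiplication). Rotation is a unit quaternion `(w, x, y, z)`; translation
#' is in millimetres.
#'
#' @param rotation unit quaternion (or length-4 numeric `w, x, y, z`).
#' @param translation numeric length-3 translation (mm).
#' @return a `rigid_transform`.
#' @export
#' @examples
#' T1 <- rigid_transform(quat_from_axis_angle(c(0, 0, 1), 90), c(1, 0, 0))
#' rt_apply(T1, matrix(c(1, 0, 0), 1))  # -> (1, 1, 0)
rigid_transform <- function(rotation = quat_identity(), translation = c(0, 0, 0)) {
  translation <- as.numeric(translation)
  if (length(translation) != 3L || !all(is.finite(translation)))
    stop("translation must be 3 finite components (mm)")
  structure(list(rotation = quaternion(rotation), translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  aa <- quat_to_axis_angle(x$rotation)
  cat(sprintf("<rigid_transform> angle=%.4f deg about (%.3f, %.3f, %.3f); t=(%.3f, %.3f, %.3f) mm\n",
              aa$angle_deg, aa$axis[1], aa$axis[2], aa$axis[3],
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Identity rigid transform
#' @return the identity `rigid_transform`.
#' @export
rt_identity <- function() rigid_transform()

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` applies `b` first, then `a`:
#' `rt_apply(rt_compose(a, b), p) == rt_apply(a, rt_apply(b, p))`.
#'
#' @param a,b `rigid_transform` objects.
#' @return the composed `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(quat_multiply(a$rotation, b$rotation),
                  a$translation + quat_rotate_points(a$rotation, b$translation))
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return the inverse transform (its matrix is the matrix inverse).
#' @export
rt_invert <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  qi <- quat_conjugate(t$rotation)
  rigid_transform(qi, -quat_rotate_points(qi, t$translation))
}

# rotate an N x 3 matrix (or length-3 vector) by a quaternion
quat_rotate_points <- function(q, points) {
  R <- quat_to_matrix(q)
  if (is.null(dim(points))) as.numeric(R %*% points)
  else points %*% t(R)
}

#' Apply a rigid transform to points
#'
#' @param t a `rigid_transform`.
#' @param points N x 3 numeric matrix of points (mm); a length-3 vector is
#'   treated as a single point.
#' @return transformed points in the same shape as the input.
#' @export
rt_apply <- function(t, points) {
  stopifnot(inherits(t, "rigid_transform"))
  if (is.null(dim(points))) {
    quat_rotate_points(t$rotation, points) + t$translation
  } else {
    points <- as.matrix(points)
    if (ncol(points) != 3L) stop("points must be N x 3")
    sweep(quat_rotate_points(t$rotation, points), 2, t$translation, "+")
  }
}

#' 4x4 homogeneous matrix of a rigid transform
#' @param t a `rigid_transform`.
#' @return 4x4 matrix `[R tau; 0 0 0 1]`.
#' @export
rt_to_matrix <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  M <- diag(4)
  M[1:3, 1:3] <- quat_to_matrix(t$rotation)
  M[1:3, 4] <- t$translation
  M
}

#' Rigid transform from a 4x4 homogeneous matrix
#' @param M 4x4 matrix with a proper rotation block and last row `(0,0,0,1)`.
#' @param tol orthonormality tolerance for the rotation block.
#' @return a `rigid_transform`.
#' @export
rt_from_matrix <- function(M, tol = 1e-6) {
  M <- as.matrix(M)
  if (!all(dim(M) == c(4, 4))) stop("expected a 4x4 homogeneous matrix")
  if (max(abs(M[4, ] - c(0, 0, 0, 1))) > tol)
    stop("last row of a rigid homogeneous matrix must be (0, 0, 0, 1)")
  rigid_transform(quat_from_matrix(M[1:3, 1:3], tol = tol), M[1:3, 4])
}

#' Angular and translational deviation between two rigid transforms
#'
#' @param a,b `rigid_transform` objects.
#' @return list with `angle_deg` (rotation angle of the relative rotation) and
#'   `translation_mm` (Euclidean distance between translations).
#' @export
rt_distance <- function(a, b) {
  list(angle_deg = quat_angular_distance(a$rotation, b$rotation),
       translation_mm = sqrt(sum((a$translation - b$translation)^2)))
}

# ---------------------------------------------------------------------------
# JSON serialization

#' Read a rigid transform from JSON
#'
#' Accepts either `{"matrix": <4x4 row-major list>}` or
#' `{"quaternion_wxyz": [...], "translation_mm": [...]}`.
#'
#' @param path JSON file path.
#' @return a `rigid_transform`.
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  transform_from_list(x)
}

transform_from_list <- function(x) {
  if (!is.null(x$quaternion_wxyz)) {
    rigid_transform(quaternion(as.numeric(x$quaternion_wxyz), normalize = TRUE),
                    as.numeric(x$translation_mm))
  } else if (!is.null(x$matrix)) {
    M <- x$matrix
    if (is.list(M)) M <- do.call(rbind, M)
    if (length(M) == 16 && is.null(dim(M))) M <- matrix(M, 4, 4, byrow = TRUE)
    rt_from_matrix(M)
  } else {
    stop("transform JSON needs either 'matrix' or 'quaternion_wxyz'/'translation_mm'")
  }
}

transform_to_list <- function(t) {
  list(quaternion_wxyz = as.numeric(t$rotation),
       translation_mm = t$translation,
       matrix = rt_to_matrix(t))
}

#' Write a rigid transform to JSON
#'
#' Emits both representations: the explicit `quaternion_wxyz` +
#' `translation_mm` pair and the row-major 4x4 `matrix`.
#'
#' @param t a `rigid_transform`.
#' @param path output file path.
#' @export
write_transform_json <- function(t, path) {
  stopifnot(inherits(t, "rigid_transform"))
  jsonlite::write_json(transform_to_list(t), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
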