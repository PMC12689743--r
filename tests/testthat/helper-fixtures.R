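# shared fixture builders (everything generated in code, seeded per test)

rand_quat <- function() {
  u <- runif(3)
  quaternion(c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
               sqrt(1 - u[1]) * cos(2 * pi * u[2]),
               sqrt(u[1]) * sin(2 * pi * u[3]),
               sqrt(u[1]) * cos(2 * pi * u[3])), normalize = TRUE)
}

rand_rt <- function(t_range = 100) {
  rigid_transform(rand_quat(), runif(3, -t_range, t_range))
}

expect_rt_equal <- function(a, b, tol = 1e-9) {
  d <- rt_distance(a, b)
  expect_lt(d$angle_deg, tol * 180 / pi + tol)
  expect_lt(d$translation_mm, tol * 10 + tol)
}

Rz <- function(deg) quat_from_axis_angle(c(0, 0, 1), deg)
Rx <- function(deg) quat_from_axis_angle(c(1, 0, 0), deg)

# small unit sphere mesh on the package's lat-lon triangulation
sphere_mesh <- function(radius = 50, n_lat = 24, n_lon = 36) {
  lat <- seq_len(n_lat - 1) * pi / n_lat
  lon <- (seq_len(n_lon) - 1) * 2 * pi / n_lon
  gr <- expand.grid(lon = lon, lat = lat)
  dirs <- rbind(c(0, 0, 1),
                cbind(sin(gr$lat) * cos(gr$lon), sin(gr$lat) * sin(gr$lon),
                      cos(gr$lat)),
                c(0, 0, -1))
  triangle_mesh(dirs * radius, arnav:::uv_sphere_faces(n_lat, n_lon))
}

# constant-increment rotation stream theta_t = theta0 * delta^t
rotation_stream <- function(theta0, delta, n) {
  out <- vector("list", n)
  out[[1]] <- theta0
  for (i in 2:n) out[[i]] <- quat_multiply(out[[i - 1]], delta)
  out
}

# compose a perturbation of the given exact magnitudes onto a pose
perturb_rt <- function(pose, t_mm, r_deg) {
  d <- rnorm(3); d <- d / sqrt(sum(d^2))
  rt_compose(rigid_transform(quat_from_axis_angle(rnorm(3), r_deg), d * t_mm),
             pose)
}
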