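arc_points <- function(n, L, phi) {
  # n points on a circular arc of length L subtending angle phi (radians)
  r <- L / phi
  th <- seq(0, phi, length.out = n)
  cbind(r * sin(th), r * (1 - cos(th)))
}

test_that("segment angles follow atan2 in degrees", {
  expect_equal(segment_angles(cbind(0:4, 0)), rep(0, 4))
  expect_equal(segment_angles(cbind(c(0, 1), c(0, 1))), 45)
  semi <- semicircle_points(n = 20, r = 60, n_dense = 20)
  steps <- diff(segment_angles(semi))
  steps <- ((steps + 180) %% 360) - 180  # unwrap the +/-180 crossing
  expect_true(all(abs(steps - 180 / 19) < 1e-6))
  expect_error(segment_angles(cbind(c(0, 0), c(1, 1))), "coincident")
})

test_that("body curvature is the wrapped angular change, endpoint-padded", {
  straight <- control_points(cbind(seq(0, 190, 10), 0), 190)
  expect_equal(body_curvature(straight), rep(0, 20))

  corner <- rbind(cbind(seq(0, 45, 5), 0), cbind(45, seq(5, 50, 5)))
  k <- body_curvature(corner)
  expect_equal(sum(k > 45), 1)           # a single 90-degree joint
  expect_equal(max(k), 90)
  expect_equal(length(k), nrow(corner))
  expect_error(body_curvature(cbind(0:1, 0)), "at least 3")
})

test_that("semicircle curvature matches the dense finite-difference oracle", {
  n <- 20; r <- 60
  pts <- semicircle_points(n = n, r = r, n_dense = n)
  k <- body_curvature(pts)

  # oracle: tangent angles by finite differences on a 2000-point midline,
  # d(theta)/ds integrated over one control-point spacing
  dense <- semicircle_points(n_dense = 2000, r = r)
  seg <- diff(dense)
  ang <- atan2(seg[, 2], seg[, 1])
  s_mid <- cumsum(sqrt(rowSums(seg^2))) - sqrt(rowSums(seg^2)) / 2
  dtheta <- ((diff(ang) + pi) %% (2 * pi)) - pi  # unwrap +/-pi crossings
  ds <- diff(s_mid)
  kappa_dense <- mean(dtheta / ds)          # rad / px, constant for a circle
  L <- pi * r
  oracle <- abs(kappa_dense) * L / (n - 1) * 180 / pi
  expect_lt(abs(mean(k[2:19]) - oracle) / oracle, 0.02)
  expect_lt(abs(oracle - 180 / 19) / (180 / 19), 0.01)
})

test_that("tail offset matches a sub-pixel strip oracle and is ~0.5 when straight", {
  # straight uniform-width fish
  line <- cbind(seq(0, 150, length.out = 200), 0)
  st <- strip_mask(line, w = 6)
  cp <- sample_control_points(centerline(st$points), 20)
  expect_lt(abs(tail_offset(cp, st$mask) - 0.5), 0.01)

  # semicircular bend: oracle integrates the union-of-disks strip on a
  # 0.25 px grid, independent of the rasterized mask
  semi <- semicircle_points(n_dense = 300, r = 60)
  st2 <- strip_mask(semi, w = 6)
  gx <- seq(min(st2$points[, 1]) - 8, max(st2$points[, 1]) + 8, by = 0.25)
  gy <- seq(min(st2$points[, 2]) - 8, max(st2$points[, 2]) + 8, by = 0.25)
  g <- expand.grid(x = gx, y = gy)
  d2 <- outer(g$x, st2$points[, 1], "-")^2 + outer(g$y, st2$points[, 2], "-")^2
  inside <- rowSums(d2 <= 36) > 0
  oracle_centroid <- c(mean(g$x[inside]), mean(g$y[inside]))
  cp2 <- sample_control_points(centerline(st2$points), 20)
  oracle_ratio <- sqrt(sum((cp2$points[20, ] - oracle_centroid)^2)) / cp2$body_length
  measured <- tail_offset(cp2, st2$mask)
  expect_lt(abs(measured - oracle_ratio), 0.01)
  # thin semicircular strip sits near 2r/pi from the center: ratio ~0.38
  expect_gt(measured, 0.35); expect_lt(measured, 0.41)

  # translation invariance
  st3 <- strip_mask(semi, w = 6, pad = 40)
  cp3 <- sample_control_points(centerline(st3$points), 20)
  expect_equal(tail_offset(cp3, st3$mask), measured, tolerance = 1e-3)
})

test_that("curvature and tail offset are invariant under rigid motion", {
  fx <- fixture_mask()
  cp <- extract_posture(fx$mask, run_config())
  k0 <- body_curvature(cp)
  off0 <- tail_offset(cp, fx$mask)
  th <- 33 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(37, 81)
  rot_pts <- sweep(cp$points %*% t(R), 2, shift, "+")
  rot_centroid <- as.numeric(R %*% fx$mask$centroid + shift)
  cp_rot <- control_points(rot_pts, cp$body_length)
  expect_lt(max(abs(body_curvature(cp_rot) - k0)) / max(k0), 0.01)
  expect_lt(abs(tail_offset(cp_rot, rot_centroid) - off0) / off0, 0.01)
})

test_that("summed interior curvature approximates total turning", {
  for (phi_deg in c(60, 120, 180)) {
    pts <- arc_points(20, L = 150, phi = phi_deg * pi / 180)
    expect_lt(abs(sum(body_curvature(pts)[2:19]) - phi_deg) / phi_deg, 0.10)
  }
})

test_that("larger bends give larger curvature and smaller tail offset", {
  phis <- seq(0.3, pi, length.out = 8)
  maxk <- numeric(0); off <- numeric(0)
  for (phi in phis) {
    pts <- arc_points(200, L = 150, phi = phi)
    cp <- sample_control_points(centerline(pts), 20)
    maxk <- c(maxk, max(body_curvature(cp)))
    off <- c(off, tail_offset(cp, colMeans(pts)))  # uniform thin-strip centroid
  }
  expect_true(all(diff(maxk) > -1e-9))
  expect_true(all(diff(off) < 1e-9))
})

test_that("travel distance is centroid path length with bounded gap bridging", {
  expect_equal(travel_distance(cbind(c(0, 3, 6), c(0, 4, 8))), 10)
  expect_equal(travel_distance(matrix(5, 30, 2)), 0)
  # net mode gives displacement
  zig <- cbind(c(0, 3, 0), c(0, 4, 8))
  expect_equal(travel_distance(zig, mode = "net"), 8)
  # bridging: interior NAs (up to 2 consecutive) interpolate linearly
  withgap <- cbind(c(0, NA, NA, 3, 4), c(0, NA, NA, 0, 0))
  expect_equal(travel_distance(withgap), 4)
  long_gap <- cbind(c(0, NA, NA, NA, 4, 5), c(0, NA, NA, NA, 0, 0))
  expect_error(travel_distance(long_gap), "consecutive")
  expect_error(travel_distance(cbind(1, 1)), "at least 2")
})
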