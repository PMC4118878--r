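test_that("zero amplitude gives a straight, period-invariant midline", {
  p <- swimmer_params(amplitude = 0)
  mid <- midline_at(0.123, p)
  expect_lt(max(abs(mid$y_body)), 1e-12)
  expect_lt(max(mid$curvature_deg), 1e-9)
  expect_equal(mid$length, p$body_length, tolerance = 1e-6)

  p2 <- swimmer_params()
  m1 <- midline_at(0.08, p2)
  m2 <- midline_at(0.08 + 1 / p2$frequency, p2)
  expect_equal(m1$y_body, m2$y_body, tolerance = 1e-9)
})

test_that("analytic curvature agrees with a dense finite-difference oracle", {
  p <- swimmer_params()
  mid <- midline_at(0.07, p, n_dense = 2000)
  seg <- diff(mid$xy)
  ang <- atan2(seg[, 2], seg[, 1])
  ds <- sqrt(rowSums(seg^2))
  s_mid <- cumsum(ds) - ds / 2
  kappa_fd <- abs(diff(ang)) / diff(s_mid)        # rad/px between samples
  s_inner <- (s_mid[-1] + s_mid[-length(s_mid)]) / 2
  targets <- seq(0, mid$length, length.out = p$n_points)
  kappa_at <- approx(s_inner, kappa_fd, xout = targets, rule = 2)$y
  oracle <- kappa_at * (mid$length / (p$n_points - 1)) * 180 / pi
  oracle[1] <- oracle[2]; oracle[p$n_points] <- oracle[p$n_points - 1]
  rel <- abs(mid$curvature_deg - oracle) / max(oracle)
  expect_lt(max(rel), 0.02)
})

test_that("rendering is two-valued without noise, seeded, and area-correct", {
  p <- swimmer_params(noise_sd = 0)
  mid <- midline_at(0.05, p)
  fr <- render_frame(mid, p)
  expect_setequal(unique(as.vector(fr)),
                  as.integer(c(p$background, p$fish_intensity)))

  pn <- swimmer_params(noise_sd = 5)
  f1 <- render_frame(mid, pn, seed = 99)
  f2 <- render_frame(mid, pn, seed = 99)
  expect_identical(f1, f2)
  f3 <- render_frame(mid, pn, seed = 100)
  expect_false(identical(f1, f3))

  # painted area vs analytic strip area (integral of 2 * width ds)
  seg_len <- sqrt(rowSums(diff(mid$xy)^2))
  wmid <- (mid$half_width[-1] + mid$half_width[-length(mid$half_width)]) / 2
  analytic_area <- sum(2 * wmid * seg_len)
  painted <- sum(fr == p$fish_intensity)
  expect_lt(abs(painted - analytic_area) / analytic_area, 0.10)

  # a fish leaving the frame is an error, not a clipped render
  pout <- swimmer_params(start = c(20, 10))
  expect_error(render_frame(midline_at(0, pout), pout), "exits the frame")
})

test_that("stiffness halves ground-truth peak curvature, ~linearly", {
  # compare cycle maxima: at a fixed instant the peak sits at different
  # body phases for the two stiffness values
  ts <- seq(0, 0.25, by = 1 / 250)
  m1 <- max(vapply(ts, function(tt) max(midline_at(tt, swimmer_params())$curvature_deg), numeric(1)))
  m5 <- max(vapply(ts, function(tt) max(midline_at(tt, swimmer_params(stiffness = 0.5))$curvature_deg), numeric(1)))
  expect_lt(abs(m1 / m5 - 2), 0.1)
})

test_that("a straight uniform-width swimmer has tail offset 0.5", {
  p <- swimmer_params(amplitude = 0, half_width_head = 8, half_width_mid = 8,
                      half_width_tail = 8, snout_taper = 1)
  mid <- midline_at(0.1, p)
  expect_lt(abs(mid$tail_offset - 0.5), 0.01)
})

test_that("cohort generation is counted, labelled, and deterministic", {
  # noise makes the seed matter: the geometry itself is deterministic
  pa <- swimmer_params(width = 480, height = 360, body_length = 90,
                       half_width_head = 6, half_width_mid = 7,
                       half_width_tail = 1.5, amplitude = 11, speed = 180,
                       frame_rate = 100, noise_sd = 4)
  pb <- pa; pb$stiffness <- 0.6
  c1 <- generate_cohort(n_fish = 1, cycles_per_fish = 3, normal_params = pa,
                        stiff_params = pb, seed = 7)
  expect_length(c1$videos, 2)                 # one fish per group
  expect_equal(nrow(c1$annotations), 6)       # 3 cycles each
  expect_equal(sort(unique(c1$manifest$group)), c("stiff", "wildtype"))
  expect_equal(nrow(c1$manifest), 2)

  c2 <- generate_cohort(n_fish = 1, cycles_per_fish = 3, normal_params = pa,
                        stiff_params = pb, seed = 7)
  expect_identical(c1$annotations, c2$annotations)
  fid <- c1$manifest$fish_id[1]
  expect_identical(c1$videos[[fid]]$frames[[5]], c2$videos[[fid]]$frames[[5]])
  tail1 <- c1$truth[[fid]][[10]]
  tail2 <- c2$truth[[fid]][[10]]
  expect_identical(tail1$points, tail2$points)

  c3 <- generate_cohort(n_fish = 1, cycles_per_fish = 3, normal_params = pa,
                        stiff_params = pb, seed = 8)
  expect_false(identical(c1$videos[[fid]]$frames[[5]], c3$videos[[fid]]$frames[[5]]))
})

test_that("cohort files on disk round-trip through the readers", {
  d <- file.path(tempdir(), "cohort_out")
  pa <- swimmer_params(width = 420, height = 300, body_length = 90,
                       half_width_head = 6, half_width_mid = 7,
                       half_width_tail = 1.5, amplitude = 11, speed = 180,
                       frame_rate = 100)
  pb <- pa; pb$stiffness <- 0.5
  coh <- generate_cohort(n_fish = 1, cycles_per_fish = 2, normal_params = pa,
                         stiff_params = pb, seed = 3, out_dir = d)
  expect_true(file.exists(file.path(d, "annotations.csv")))
  expect_true(file.exists(file.path(d, "manifest.csv")))
  expect_true(file.exists(file.path(d, "ground_truth.csv")))
  fid <- coh$manifest$fish_id[1]
  v <- read_video(file.path(d, paste0(fid, ".avi")))
  expect_equal(v$frame_rate, 100)
  expect_identical(v$frames[[3]], coh$videos[[fid]]$frames[[3]])
  ann <- load_cycle_annotations(file.path(d, "annotations.csv"),
                                n_frames = length(v$frames))
  expect_equal(nrow(ann), 4)
  unlink(d, recursive = TRUE)
})
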