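write_ann <- function(rows) {
  p <- file.path(tempdir(), "ann.csv")
  write.csv(rows, p, row.names = FALSE)
  p
}

test_that("cycle annotations parse, bound-check, and warn on overlap", {
  p <- write_ann(data.frame(fish_id = "f1", start_frame = c(0, 80),
                            end_frame = c(59, 111)))
  ann <- load_cycle_annotations(p, n_frames = 200)
  expect_equal(nrow(ann), 2)
  expect_error(load_cycle_annotations(p, n_frames = 100), "exceeds")

  p2 <- write_ann(data.frame(fish_id = "f1", start_frame = 10, end_frame = 5))
  expect_error(load_cycle_annotations(p2), "line 2")

  p3 <- write_ann(data.frame(fish_id = "f1", start_frame = c(0, 30),
                             end_frame = c(40, 70)))
  expect_warning(load_cycle_annotations(p3), "overlap")

  p4 <- file.path(tempdir(), "empty.csv")
  writeLines("fish_id,start_frame,end_frame", p4)
  expect_warning(ann4 <- load_cycle_annotations(p4), "no cycles")
  expect_equal(nrow(ann4), 0)
})

test_that("cycle spans normalize to exactly the target frame count", {
  expect_equal(normalize_cycle_frames(5, 34, 30, 100), 5:34)
  # 59-frame span subsamples every other frame
  expect_equal(normalize_cycle_frames(0, 58, 30, 100), seq(0, 58, by = 2))
  # 26-frame span extends 2 before and 2 after, contiguous
  expect_equal(normalize_cycle_frames(10, 35, 30, 100), 8:37)
  # odd deficit prefers frames after the cycle
  expect_equal(normalize_cycle_frames(10, 34, 30, 100), 8:37)
  # bounds push the slack to the available side
  expect_equal(normalize_cycle_frames(0, 25, 30, 100), 0:29)
  expect_equal(normalize_cycle_frames(74, 99, 30, 100), 70:99)
  expect_error(normalize_cycle_frames(0, 25, 30, 28), "too short")

  # property: always exactly target, sorted, duplicate-free, in bounds
  set.seed(9)
  for (rep in 1:50) {
    nf <- sample(40:200, 1)
    s <- sample(0:(nf - 35), 1)
    e <- min(nf - 1, s + sample(3:80, 1))
    idx <- normalize_cycle_frames(s, e, 30, nf)
    expect_length(idx, 30)
    expect_false(is.unsorted(idx, strictly = TRUE))
    expect_true(all(idx >= 0 & idx <= nf - 1))
  }
})

test_that("automatic cycle detection spans tail-offset maxima", {
  cfg <- run_config()
  # analytic tail-offset series of the default swimmer, 4 periods
  p <- swimmer_params()
  per <- 1 / (2 * p$frequency)
  tt <- seq(0, 4 * per, by = 1 / p$frame_rate)
  offs <- vapply(tt, function(t) midline_at(t, p, n_dense = 120)$tail_offset,
                 numeric(1))
  cyc <- detect_cycles_auto(offs, cfg)
  expect_gte(nrow(cyc), 3); expect_lte(nrow(cyc), 4)
  spans <- cyc$end_frame - cyc$start_frame + 1
  expect_true(all(abs(spans - per * p$frame_rate) < 5))

  expect_equal(nrow(detect_cycles_auto(rep(0.5, 80), cfg)), 0)
  expect_error(detect_cycles_auto(rep(0.5, 10), cfg), "shorter")

  # a window holding one full offset period -> exactly one cycle of about
  # one period length; the window keeps ~12 frames of fall-off on each
  # side so both maxima retain measurable prominence
  p1 <- cyc$start_frame[1]; p2 <- cyc$end_frame[1]
  offs1 <- offs[(p1 - 12 + 1):(p2 + 12 + 1)]
  cfg1 <- run_config(cycle_length = floor(length(offs1) / 2))
  cyc1 <- detect_cycles_auto(offs1, cfg1)
  expect_equal(nrow(cyc1), 1)
  expect_lt(abs(cyc1$end_frame - cyc1$start_frame + 1 - per * p$frame_rate), 4)
})

test_that("the cycle curvature matrix has the documented shape and content", {
  sw <- fixture_swimmer()
  cfg <- run_config()
  idx <- normalize_cycle_frames(sw$cycles$start_frame[1], sw$cycles$end_frame[1],
                                cfg$cycle_length, length(sw$video$frames))
  fm <- frame_metrics(sw$track, cfg, frames = idx + 1)
  prof <- cycle_curvature_matrix(fm, idx, cfg)
  expect_equal(dim(prof$C), c(20, 30))
  expect_true(all(prof$C_raw >= 0))
  expect_length(prof$offsets, 30)
  # traveling wave: the (smoothed) per-column peak location drifts tailward
  wmx <- apply(prof$C, 2, which.max)
  drift <- stats::coef(stats::lm(wmx ~ seq_along(wmx)))[2]
  expect_gt(abs(drift), 0.05)
  # missing posture metrics reject the cycle
  expect_error(cycle_curvature_matrix(fm, idx + 1000L, cfg), "missing")
})

test_that("a straight rigid body yields a near-zero curvature profile", {
  p <- swimmer_params(amplitude = 0, half_width_head = 8, half_width_mid = 8,
                      half_width_tail = 8, snout_taper = 1, seed = 3L)
  sw <- generate_swimmer(p, n_cycles = 1, fish_id = "s")
  cfg <- run_config()
  tr <- track_sequence(sw$video, cfg)
  idx <- normalize_cycle_frames(sw$cycles$start_frame[1], sw$cycles$end_frame[1],
                                cfg$cycle_length, length(sw$video$frames))
  fm <- frame_metrics(tr, cfg, frames = idx + 1)
  prof <- cycle_curvature_matrix(fm, idx, cfg)
  expect_lt(max(prof$C), 1)
  expect_true(all(abs(prof$offsets - 0.5) < 0.01))
})

test_that("group profile averaging is elementwise", {
  a <- matrix(0, 20, 30); b <- matrix(10, 20, 30)
  oa <- rep(0.5, 30); ob <- rep(0.3, 30)
  g1 <- average_group_profiles(list(a), list(oa), "g")
  expect_equal(g1$mean_profile, a)
  g2 <- average_group_profiles(list(a, b), list(oa, ob), "g")
  expect_true(all(g2$mean_profile == 5))
  expect_true(all(abs(g2$mean_offsets - 0.4) < 1e-12))
  g3 <- average_group_profiles(list(b, b, b), list(ob, ob, ob), "g")
  expect_equal(g3$mean_profile, b)
  expect_error(average_group_profiles(list(), list(), "g"), "empty")
  expect_error(average_group_profiles(list(a, matrix(0, 5, 5)), list(oa, oa), "g"),
               "dimensions")
})

test_that("cycle extrema take max curvature, min offset, travel distance", {
  C0 <- matrix(0, 20, 30)
  cent <- matrix(7, 30, 2)
  ex <- cycle_extrema(C0, rep(0.5, 30), cent)
  expect_equal(unlist(ex), c(max_curvature = 0, min_tail_offset = 0.5,
                             travel_distance = 0))
  offs <- seq(0.5, 0.3, length.out = 30)
  ex2 <- cycle_extrema(C0 + 3, offs, cent)
  expect_lte(ex2$min_tail_offset, offs[1])
})

test_that("wild-type normalization rescales metrics and is scale invariant", {
  cyc <- data.frame(group = rep(c("wildtype", "mut"), each = 4),
                    max_curvature_deg = c(9, 10, 11, 10, 4, 5, 6, 5),
                    min_tail_offset = c(rep(0.5, 4), rep(0.55, 4)),
                    travel_distance_px = c(rep(20, 4), rep(10, 4)))
  rel <- normalize_to_wildtype(cyc, "wildtype")
  expect_equal(mean(rel$max_curvature_deg[rel$group == "wildtype"]), 1)
  expect_equal(mean(rel$max_curvature_deg[rel$group == "mut"]), 0.5)
  expect_equal(mean(rel$travel_distance_px[rel$group == "mut"]), 0.5)
  cyc3 <- cyc
  for (cl in names(cyc)[-1]) cyc3[[cl]] <- cyc3[[cl]] * 3
  rel3 <- normalize_to_wildtype(cyc3, "wildtype")
  expect_equal(rel3[-1], rel[-1], tolerance = 1e-12)
  expect_error(normalize_to_wildtype(cyc, "absent"), "not present")
  cyc0 <- cyc; cyc0$travel_distance_px[cyc0$group == "wildtype"] <- 0
  expect_error(normalize_to_wildtype(cyc0, "wildtype"), "zero")
})

test_that("the group comparison is the classical pooled-variance Student t", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0); expect_equal(same$p, 1); expect_false(same$significant)

  cmp <- compare_groups(1:5, 2:6)
  expect_equal(cmp$t, -1, tolerance = 1e-12)
  expect_equal(cmp$df, 8)
  expect_equal(cmp$p, 2 * pt(-1, 8), tolerance = 1e-12)
  expect_equal(round(cmp$p, 3), 0.347)
  expect_false(cmp$significant)

  degen <- compare_groups(c(2, 2), c(3, 3))
  expect_true(degen$significant)
  expect_lt(degen$p, 1e-300)
  expect_error(compare_groups(1, 1:3), "at least 2")
})
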