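# Parametric undulatory swimmer with analytic ground truth. The midline is
# a traveling body wave whose amplitude envelope grows linearly toward the
# tail (carangiform-like), rendered as a union of disks along the midline
# with a snout/tail-tapered width profile, on a lighter static background.

#' Parameters of the synthetic swimmer
#'
#' Defaults emulate the recording conditions of the reference setup (250
#' frames/s, 480x640 px, dark adult fish on a lighter tank) with
#' field-realistic kinematics: body length 150 px (an adult fish spanning
#' about a quarter of the 640 px field of view), tail-beat half-amplitude
#' 19 px (~0.13 body lengths), wavelength 0.95 body lengths, beat frequency
#' 4 Hz so one straight-bent-straight tail-offset cycle spans 1/(2f) =
#' 31.25 frames (~30 at 250 fps), and forward speed 300 px/s (~2 body
#' lengths/s cruising). The `stiffness` factor in (0, 1] models a
#' stiff-muscle phenotype: it scales the wave amplitude and, because
#' thrust comes from the undulation, the forward speed by the same factor.
#'
#' @param body_length Body length along the body axis, pixels.
#' @param half_width_head,half_width_mid,half_width_tail Half-widths of the
#'   body at the head bulge, mid-body, and tail tip, pixels.
#' @param snout_taper Snout half-width as a fraction of the head
#'   half-width (default 0.35); 1 gives an untapered, stadium-shaped head
#'   end, useful for uniform-width test bodies.
#' @param amplitude Tail-beat half-amplitude of the body wave, pixels.
#' @param wavelength Body-wave wavelength as a fraction of body length.
#' @param frequency Beat frequency, Hz.
#' @param speed Forward swimming speed, px/s (scaled by `stiffness`).
#' @param heading Swimming direction, degrees (0 = +x).
#' @param stiffness Phenotype factor in (0, 1]; 1 = normal.
#' @param background,fish_intensity 8-bit intensities; the fish must be
#'   darker than the background by at least 3 noise SDs.
#' @param noise_sd Additive Gaussian noise SD, intensity units.
#' @param frame_rate Frames per second.
#' @param width,height Frame size in pixels.
#' @param n_points Ground-truth control points per frame.
#' @param seed Master seed for all randomness.
#' @param start Optional (x, y) head position at t = 0; `NULL` centers the
#'   swim path in the frame.
#' @return A validated `swimmer_params` list.
#' @export
swimmer_params <- function(body_length = 150,
                           half_width_head = 9,
                           half_width_mid = 10,
                           half_width_tail = 2,
                           amplitude = 19,
                           wavelength = 0.95,
                           frequency = 4,
                           speed = 300,
                           heading = 0,
                           stiffness = 1,
                           background = 200,
                           fish_intensity = 60,
                           noise_sd = 0,
                           frame_rate = 250,
                           width = 640,
                           height = 480,
                           n_points = 20,
                           seed = 1L,
                           start = NULL,
                           snout_taper = 0.35) {
  p <- list(body_length = body_length, half_width_head = half_width_head,
            half_width_mid = half_width_mid, half_width_tail = half_width_tail,
            snout_taper = snout_taper,
            amplitude = amplitude, wavelength = wavelength,
            frequency = frequency, speed = speed, heading = heading,
            stiffness = stiffness, background = background,
            fish_intensity = fish_intensity, noise_sd = noise_sd,
            frame_rate = frame_rate, width = as.integer(width),
            height = as.integer(height), n_points = as.integer(n_points),
            seed = as.integer(seed), start = start)
  stopifnot(p$amplitude >= 0, p$stiffness > 0, p$stiffness <= 1,
            p$frame_rate > 0, p$body_length > 0, p$wavelength > 0,
            p$frequency > 0, p$n_points >= 3)
  if (p$background - p$fish_intensity < 3 * p$noise_sd)
    stop("fish must be darker than background by at least 3 noise SDs",
         call. = FALSE)
  class(p) <- "swimmer_params"
  p
}

# half-width profile along the body axis coordinate u in [0, L]:
# tapered snout, head bulge at 0.15 L, mid-body, thin caudal peduncle
swimmer_half_width <- function(u, p) {
  rel <- u / p$body_length
  taper <- if (is.null(p$snout_taper)) 0.35 else p$snout_taper
  approx(c(0, 0.15, 0.5, 1),
         c(taper * p$half_width_head, p$half_width_head,
           p$half_width_mid, p$half_width_tail),
         xout = rel, rule = 2)$y
}

#' Analytic swimmer midline at a time point
#'
#' The body-frame midline is `y(u, t) = stiffness * amplitude * (u / L) *
#' sin(2 * pi * (u / (wavelength * L) - frequency * t))` with `u` the body
#' axis coordinate from head (0) to tail (L); the amplitude envelope grows
#' linearly toward the tail. The body frame is rigidly rotated by the
#' heading and translated by the (stiffness-scaled) forward motion, the
#' head leading. Ground-truth quantities are derived from the same curve:
#' arc-length-uniform control points, analytic curvature converted to
#' degrees of angular change per control-point step, the width-weighted
#' strip centroid, and the tail offset.
#'
#' @param t Time, seconds.
#' @param params A [swimmer_params()].
#' @param n_dense Number of dense samples along the body axis.
#' @return List with dense `xy`, `half_width`, `y_body`, arc `length`,
#'   ground-truth `points` (n_points x 2), `curvature_deg`, `centroid`,
#'   `tail_offset`.
#' @export
midline_at <- function(t, params, n_dense = 400) {
  p <- params
  L <- p$body_length
  A <- p$stiffness * p$amplitude
  lamL <- p$wavelength * L
  u <- seq(0, L, length.out = n_dense)
  theta <- 2 * pi * (u / lamL - p$frequency * t)
  env <- A * (u / L)
  yb <- env * sin(theta)

  hrad <- p$heading * pi / 180
  dirv <- c(cos(hrad), sin(hrad))
  perp <- c(-sin(hrad), cos(hrad))
  head0 <- if (is.null(p$start)) c(p$width / 2, p$height / 2) else as.numeric(p$start)
  head_pos <- head0 + dirv * (p$speed * p$stiffness * t)
  xy <- cbind(head_pos[1] - dirv[1] * u + perp[1] * yb,
              head_pos[2] - dirv[2] * u + perp[2] * yb)

  hw <- swimmer_half_width(u, p)
  gaps <- sqrt(rowSums((xy[-1, ] - xy[-n_dense, ])^2))
  arc <- c(0, cumsum(gaps))
  Larc <- arc[n_dense]

  targets <- seq(0, Larc, length.out = p$n_points)
  cpx <- approx(arc, xy[, 1], xout = targets, ties = "ordered")$y
  cpy <- approx(arc, xy[, 2], xout = targets, ties = "ordered")$y
  pts <- cbind(cpx, cpy)
  u_ctrl <- approx(arc, u, xout = targets, ties = "ordered")$y

  # analytic curvature of (u, y(u)) -- rigid-motion invariant
  Aprime <- A / L
  thp <- 2 * pi / lamL
  th_c <- 2 * pi * (u_ctrl / lamL - p$frequency * t)
  env_c <- A * (u_ctrl / L)
  y1 <- Aprime * sin(th_c) + env_c * cos(th_c) * thp
  y2 <- 2 * Aprime * thp * cos(th_c) - env_c * thp^2 * sin(th_c)
  kappa <- abs(y2) / (1 + y1^2)^1.5
  curvature_deg <- kappa * (Larc / (p$n_points - 1)) * 180 / pi
  # same endpoint convention as the measurement: curvature is defined on
  # interior joints; endpoints report their nearest interior neighbour
  np <- p$n_points
  curvature_deg[1] <- curvature_deg[2]
  curvature_deg[np] <- curvature_deg[np - 1]

  # centroid of the body strip: midline weighted by local width x arc element
  wgt <- hw * c(gaps[1], (gaps[-1] + gaps[-length(gaps)]) / 2, gaps[length(gaps)])
  centroid <- c(sum(xy[, 1] * wgt), sum(xy[, 2] * wgt)) / sum(wgt)
  tail_off <- sqrt(sum((pts[p$n_points, ] - centroid)^2)) / Larc

  list(t = t, u = u, xy = xy, half_width = hw, y_body = yb,
       length = Larc, points = pts, curvature_deg = curvature_deg,
       centroid = centroid, tail_offset = tail_off)
}

#' Render one frame of the synthetic swimmer
#'
#' Draws the fish as the union of disks centered on the dense midline with
#' the local half-width as radius, at the fish intensity on the constant
#' background, then adds seeded zero-mean Gaussian noise. Errors if any
#' part of the fish would leave the frame.
#'
#' @param mid Output of [midline_at()].
#' @param params The [swimmer_params()].
#' @param seed Optional seed for the noise of this frame; `NULL` uses the
#'   current RNG stream.
#' @return Integer intensity matrix (height x width).
#' @export
render_frame <- function(mid, params, seed = NULL) {
  p <- params
  xy <- mid$xy; hw <- mid$half_width
  if (min(xy[, 1] - hw) < 0 || max(xy[, 1] + hw) > p$width - 1 ||
      min(xy[, 2] - hw) < 0 || max(xy[, 2] + hw) > p$height - 1)
    stop("midline exits the frame; adjust speed/heading/start", call. = FALSE)
  # ~1 px spacing of disk centers is dense enough for the thinnest width
  keep <- unique(round(seq(1, nrow(xy), length.out = max(2, ceiling(mid$length)))))
  cx <- xy[keep, 1]; cy <- xy[keep, 2]; cr2 <- hw[keep]^2

  x0 <- floor(min(cx - hw[keep])); x1 <- ceiling(max(cx + hw[keep]))
  y0 <- floor(min(cy - hw[keep])); y1 <- ceiling(max(cy + hw[keep]))
  gx <- rep(x0:x1, times = y1 - y0 + 1)
  gy <- rep(y0:y1, each = x1 - x0 + 1)
  d2 <- outer(gx, cx, "-")^2 + outer(gy, cy, "-")^2
  hit <- rowSums(d2 <= matrix(cr2, nrow = length(gx), ncol = length(cr2),
                              byrow = TRUE)) > 0

  frame <- matrix(p$background, nrow = p$height, ncol = p$width)
  frame[cbind(gy[hit] + 1, gx[hit] + 1)] <- p$fish_intensity
  if (p$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    frame <- frame + rnorm(length(frame), 0, p$noise_sd)
  }
  frame <- pmin(pmax(round(frame), 0), 255)
  storage.mode(frame) <- "integer"
  frame
}

# analytic cycle boundaries: times when the tail crosses the body axis,
# i.e. sin(2 pi (1/wavelength - f t)) = 0 -> t = (1/wavelength - n/2) / f
swimmer_cycle_boundaries <- function(p, t_max) {
  n_lo <- ceiling(2 * (1 / p$wavelength - p$frequency * t_max))
  n_hi <- floor(2 / p$wavelength)
  ts <- (1 / p$wavelength - (n_lo:n_hi) / 2) / p$frequency
  sort(ts[ts >= 0 & ts <= t_max])
}

#' Generate a synthetic swimmer video with ground truth
#'
#' Renders `n_cycles` body-waving cycles (straight-bent-straight tail
#' excursions, each 1/(2 * frequency) seconds), places the swim path inside
#' the frame, and returns the video, per-frame ground truth, and analytic
#' cycle annotations. The video is extended (the fish keeps swimming past
#' the annotated cycles) until the fish has traversed at least
#' `min_travel_bl` body lengths: the per-pixel temporal median background
#' model is only valid when every pixel sees the background in more than
#' half the frames, which the long recordings of the reference setup
#' guarantee and a short clip of a slow fish would not. All randomness
#' comes from `params$seed`.
#'
#' @param params A [swimmer_params()].
#' @param n_cycles Number of annotated body-waving cycles.
#' @param fish_id Identifier stored with the outputs.
#' @param min_travel_bl Minimum total travel, in body lengths, required of
#'   the rendered video (default 2.75, giving a worst-case per-pixel fish
#'   occupancy of ~40%).
#' @param render Render the frames (`TRUE`, default); `FALSE` skips
#'   rendering and returns `video = NULL` with the ground truth and
#'   annotations only, so large cohorts can be re-rendered one fish at a
#'   time instead of held in memory together.
#' @return List with `video` ([frame_sequence()] or `NULL`), `truth`
#'   (per-frame list of ground-truth midlines), `cycles` (data frame
#'   `fish_id`, `start_frame`, `end_frame`), and `params` (with the start
#'   position resolved).
#' @export
generate_swimmer <- function(params, n_cycles = 3, fish_id = "fish1",
                             min_travel_bl = 2.75, render = TRUE) {
  p <- params
  pad <- 0.02
  phase0 <- (1 / p$wavelength) / p$frequency
  t_first <- phase0 %% (1 / (2 * p$frequency))
  t_cycles <- t_first + n_cycles / (2 * p$frequency) + pad
  t_travel <- min_travel_bl * p$body_length / (p$speed * p$stiffness)
  t_max <- max(t_cycles, t_travel)
  n_frames <- ceiling(t_max * p$frame_rate) + 1

  if (is.null(p$start)) {
    v <- p$speed * p$stiffness
    hrad <- p$heading * pi / 180
    dirv <- c(cos(hrad), sin(hrad))
    center <- c((p$width - 1) / 2, (p$height - 1) / 2)
    p$start <- center + dirv * (p$body_length - v * t_max) / 2
  }

  set.seed(p$seed)
  frames <- if (render) vector("list", n_frames) else NULL
  truth <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    t <- (i - 1) / p$frame_rate
    mid <- midline_at(t, p)
    if (render) frames[[i]] <- render_frame(mid, p)
    truth[[i]] <- mid[c("t", "points", "curvature_deg", "centroid",
                        "tail_offset", "length")]
  }
  video <- if (render) {
    frame_sequence(frames, frame_rate = p$frame_rate, source_id = fish_id)
  } else NULL

  bounds <- round(swimmer_cycle_boundaries(p, t_max) * p$frame_rate)
  bounds <- bounds[bounds >= 0 & bounds <= n_frames - 1]
  if (length(bounds) < n_cycles + 1)
    stop("internal: not enough cycle boundaries generated", call. = FALSE)
  cycles <- data.frame(fish_id = fish_id,
                       start_frame = as.integer(bounds[seq_len(n_cycles)]),
                       end_frame = as.integer(bounds[seq_len(n_cycles) + 1]),
                       stringsAsFactors = FALSE)
  list(video = video, truth = truth, cycles = cycles, params = p)
}

#' Generate a two-group synthetic cohort
#'
#' Stands in for a recorded cohort: `n_fish` fish per group, the second
#' group with a stiffness factor < 1 (reduced wave amplitude and forward
#' speed). Every fish gets its own seed derived from the master seed, so
#' the whole cohort is reproducible byte for byte.
#'
#' @param n_fish Fish per group.
#' @param cycles_per_fish Annotated body-waving cycles per fish.
#' @param normal_params,stiff_params [swimmer_params()] for the two groups.
#' @param seed Master seed.
#' @param group_labels Length-2 character vector of group names.
#' @param out_dir Optional directory: writes per-fish AVI videos plus
#'   annotation, manifest, and ground-truth CSVs (requires `render = TRUE`).
#' @param render Keep the rendered videos in memory (`TRUE`, default).
#'   With `FALSE` only ground truth, annotations, manifest, and the
#'   per-fish parameter sets (`fish_params`) are returned; pass
#'   [cohort_video_loader()] of the result to [analyze_cohort()] to render
#'   each fish on demand, which bounds memory use on large cohorts.
#' @return List with `videos` (named list of [frame_sequence()], or `NULL`
#'   when `render = FALSE`), `truth`, `annotations`, `manifest`,
#'   `fish_params` (named list of resolved per-fish [swimmer_params()]),
#'   `cycles_per_fish`, and `params`.
#' @export
generate_cohort <- function(n_fish = 2, cycles_per_fish = 3,
                            normal_params = swimmer_params(),
                            stiff_params = swimmer_params(stiffness = 0.5),
                            seed = 1L,
                            group_labels = c("wildtype", "stiff"),
                            out_dir = NULL, render = TRUE) {
  stopifnot(length(group_labels) == 2)
  if (!is.null(out_dir) && !render)
    stop("writing a cohort to disk requires render = TRUE", call. = FALSE)
  videos <- list(); truth <- list(); fish_params <- list()
  ann <- NULL; manifest <- NULL
  counter <- 0L
  for (g in 1:2) {
    gp <- if (g == 1) normal_params else stiff_params
    for (k in seq_len(n_fish)) {
      counter <- counter + 1L
      fid <- sprintf("%s_f%02d", group_labels[g], k)
      gp$seed <- as.integer((as.numeric(seed) * 131 + counter * 7919) %%
                              .Machine$integer.max)
      sw <- generate_swimmer(gp, n_cycles = cycles_per_fish, fish_id = fid,
                             render = render)
      if (render) videos[[fid]] <- sw$video
      truth[[fid]] <- sw$truth
      fish_params[[fid]] <- sw$params
      ann <- rbind(ann, sw$cycles)
      manifest <- rbind(manifest,
                        data.frame(fish_id = fid, group = group_labels[g],
                                   stringsAsFactors = FALSE))
    }
  }
  out <- list(videos = if (render) videos else NULL, truth = truth,
              annotations = ann, manifest = manifest,
              fish_params = fish_params, cycles_per_fish = cycles_per_fish,
              params = list(normal = normal_params, stiff = stiff_params,
                            seed = seed))
  if (!is.null(out_dir) && render) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (fid in names(videos))
      write_avi(videos[[fid]], file.path(out_dir, paste0(fid, ".avi")))
    write.csv(ann, file.path(out_dir, "annotations.csv"), row.names = FALSE)
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    gt <- do.call(rbind, lapply(names(truth), function(fid) {
      do.call(rbind, lapply(seq_along(truth[[fid]]), function(i) {
        tr <- truth[[fid]][[i]]
        data.frame(fish_id = fid, frame = i - 1L, t = tr$t,
                   body_length = tr$length, tail_offset = tr$tail_offset,
                   centroid_x = tr$centroid[1], centroid_y = tr$centroid[2],
                   max_curvature_deg = max(tr$curvature_deg))
      }))
    }))
    write.csv(gt, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  }
  out
}

#' Video loader for a lazily rendered cohort
#'
#' Returns a function mapping a fish id to its rendered video, re-creating
#' each fish deterministically from the cohort's stored per-fish
#' parameters. Pass it as the `videos` argument of [analyze_cohort()] so
#' only one rendered video is in memory at a time.
#'
#' @param cohort A [generate_cohort()] result (typically `render = FALSE`).
#' @return `function(fish_id) -> frame_sequence`.
#' @export
cohort_video_loader <- function(cohort) {
  function(fish_id) {
    p <- cohort$fish_params[[fish_id]]
    if (is.null(p)) stop("unknown fish id: ", fish_id, call. = FALSE)
    generate_swimmer(p, n_cycles = cohort$cycles_per_fish,
                     fish_id = fish_id, render = TRUE)$video
  }
}
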