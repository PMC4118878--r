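# End-to-end analysis: video -> track -> postures -> cycle profiles ->
# per-cycle metrics -> group summaries.

#' Analyze one fish video
#'
#' Runs segmentation/tracking, extracts postures for every frame used by a
#' normalized cycle, builds the smoothed spatio-temporal curvature profile
#' and tail-offset series of each cycle, and computes the per-cycle extrema
#' (largest curvature, smallest tail offset, travel distance over the cycle
#' span). Cycles whose posture extraction fails are rejected with a reason
#' rather than aborting the video.
#'
#' @param video A [frame_sequence()].
#' @param cycles Data frame with `start_frame`, `end_frame` (0-based,
#'   inclusive), e.g. from [load_cycle_annotations()] or
#'   [detect_cycles_auto()].
#' @param cfg A [run_config()].
#' @param fish_id,group Labels attached to the output rows.
#' @return List with `cycles` (per-cycle metrics data frame), `profiles`
#'   (list of smoothed curvature matrices), `offsets` (list of smoothed
#'   tail-offset series), `rejected` (data frame with reasons), `track`,
#'   and `metrics`.
#' @export
analyze_video <- function(video, cycles, cfg = run_config(),
                          fish_id = "fish1", group = "wildtype") {
  stopifnot(inherits(video, "frame_sequence"))
  n_frames <- length(video$frames)
  track <- track_sequence(video, cfg)

  norm_idx <- lapply(seq_len(nrow(cycles)), function(i) {
    normalize_cycle_frames(cycles$start_frame[i], cycles$end_frame[i],
                           target = cfg$cycle_length, n_frames = n_frames)
  })
  needed <- sort(unique(unlist(norm_idx))) + 1L  # 1-based
  metrics <- frame_metrics(track, cfg, frames = needed)

  rows <- NULL; rejected <- NULL
  profiles <- list(); offsets <- list()
  for (i in seq_len(nrow(cycles))) {
    res <- tryCatch({
      prof <- cycle_curvature_matrix(metrics, norm_idx[[i]], cfg)
      span <- (cycles$start_frame[i]:cycles$end_frame[i]) + 1L
      ext <- cycle_extrema(prof$C, prof$offsets,
                           track$centroids[span, , drop = FALSE],
                           mode = cfg$travel_mode)
      list(prof = prof, ext = ext)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rejected <- rbind(rejected,
                        data.frame(fish_id = fish_id, cycle_index = i - 1L,
                                   reason = conditionMessage(res),
                                   stringsAsFactors = FALSE))
      next
    }
    profiles[[length(profiles) + 1L]] <- res$prof$C
    offsets[[length(offsets) + 1L]] <- res$prof$offsets
    rows <- rbind(rows, data.frame(
      fish_id = fish_id, group = group, cycle_index = i - 1L,
      max_curvature_deg = res$ext$max_curvature,
      min_tail_offset = res$ext$min_tail_offset,
      travel_distance_px = res$ext$travel_distance,
      stringsAsFactors = FALSE))
  }
  if (is.null(rows))
    rows <- data.frame(fish_id = character(0), group = character(0),
                       cycle_index = integer(0), max_curvature_deg = numeric(0),
                       min_tail_offset = numeric(0),
                       travel_distance_px = numeric(0), stringsAsFactors = FALSE)
  if (is.null(rejected))
    rejected <- data.frame(fish_id = character(0), cycle_index = integer(0),
                           reason = character(0), stringsAsFactors = FALSE)
  list(cycles = rows, profiles = profiles, offsets = offsets,
       rejected = rejected, track = track, metrics = metrics)
}

#' Analyze a cohort of fish videos and compare groups
#'
#' Runs [analyze_video()] per fish, averages the cycle profiles within each
#' group, and compares each group's per-cycle metrics against wild-type
#' with Student t tests. Relative means are each group's metric mean
#' divided by the wild-type mean (wild-type = 1 by construction). By
#' default all cycles of all fish in a group are pooled, matching the
#' averaging of the reference analysis; `cfg$per_fish_averaging` averages
#' within fish first.
#'
#' @param videos Named list of [frame_sequence()] (names = fish ids), or a
#'   function `fish_id -> frame_sequence` (e.g. [cohort_video_loader()]),
#'   in which case only one video is held in memory at a time.
#' @param annotations Cycle annotation data frame (`fish_id`,
#'   `start_frame`, `end_frame`); fish with no rows get automatic cycle
#'   detection.
#' @param manifest Data frame mapping `fish_id` to `group`.
#' @param cfg A [run_config()].
#' @param wildtype Wild-type group label.
#' @return List with `cycles` (pooled per-cycle metrics), `summary` (per
#'   group x metric: n, mean, sd, relative mean, t, p, significant),
#'   `group_profiles` (per-group mean curvature matrix and tail-offset
#'   profile), `rejected`, `per_fish` (raw per-fish results).
#' @export
analyze_cohort <- function(videos, annotations, manifest,
                           cfg = run_config(), wildtype = "wildtype") {
  stopifnot(all(c("fish_id", "group") %in% names(manifest)))
  all_cycles <- NULL; all_rejected <- NULL
  per_fish <- list()
  prof_by_group <- list(); offs_by_group <- list()
  for (i in seq_len(nrow(manifest))) {
    fid <- manifest$fish_id[i]; grp <- manifest$group[i]
    video <- if (is.function(videos)) {
      tryCatch(videos(fid), error = function(e) {
        warning("loading video for fish ", fid, " failed: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    } else videos[[fid]]
    if (is.null(video)) {
      warning("no video for fish ", fid, "; skipped", call. = FALSE)
      next
    }
    cyc <- annotations[annotations$fish_id == fid, , drop = FALSE]
    if (nrow(cyc) == 0) {
      track <- track_sequence(video, cfg)
      fm <- frame_metrics(track, cfg)
      offs <- fm$tail_offset
      offs[is.na(offs)] <- mean(offs, na.rm = TRUE)
      cyc <- detect_cycles_auto(offs, cfg)
      cyc$fish_id <- fid
    }
    res <- analyze_video(video, cyc, cfg, fish_id = fid, group = grp)
    rm(video)
    res$track$masks <- NULL  # cropped masks are retained per posture, not here
    per_fish[[fid]] <- res
    all_cycles <- rbind(all_cycles, res$cycles)
    all_rejected <- rbind(all_rejected, res$rejected)
    prof_by_group[[grp]] <- c(prof_by_group[[grp]], res$profiles)
    offs_by_group[[grp]] <- c(offs_by_group[[grp]], res$offsets)
  }
  if (is.null(all_cycles) || nrow(all_cycles) == 0)
    stop("no analyzable cycles in the cohort", call. = FALSE)

  group_profiles <- lapply(names(prof_by_group), function(g)
    average_group_profiles(prof_by_group[[g]], offs_by_group[[g]], g))
  names(group_profiles) <- names(prof_by_group)

  summary <- cohort_summary(all_cycles, cfg, wildtype)
  list(cycles = all_cycles, summary = summary,
       group_profiles = group_profiles,
       rejected = if (is.null(all_rejected)) data.frame() else all_rejected,
       per_fish = per_fish)
}

metric_columns <- c(max_curvature = "max_curvature_deg",
                    min_tail_offset = "min_tail_offset",
                    travel_distance = "travel_distance_px")

cohort_summary <- function(cycles, cfg, wildtype) {
  if (!wildtype %in% cycles$group)
    stop("wild-type group '", wildtype, "' has no cycles", call. = FALSE)
  value_of <- function(grp, col) {
    sub <- cycles[cycles$group == grp, ]
    if (cfg$per_fish_averaging) {
      as.numeric(tapply(sub[[col]], sub$fish_id, mean))
    } else {
      sub[[col]]
    }
  }
  out <- NULL
  for (grp in unique(cycles$group)) {
    for (mn in names(metric_columns)) {
      col <- metric_columns[[mn]]
      v <- value_of(grp, col)
      wt <- value_of(wildtype, col)
      rel <- mean(v) / mean(wt)
      if (grp == wildtype) {
        t_stat <- NA_real_; p <- NA_real_; sig <- NA
      } else {
        cmp <- tryCatch(
          compare_groups(v, wt, alpha = cfg$alpha,
                         equal_variance = cfg$equal_variance),
          error = function(e) {
            warning("group '", grp, "', metric ", mn, ": ",
                    conditionMessage(e), call. = FALSE)
            list(t = NA_real_, p = NA_real_, significant = NA)
          })
        t_stat <- cmp$t; p <- cmp$p; sig <- cmp$significant
      }
      out <- rbind(out, data.frame(
        group = grp, metric = mn, n = length(v), mean = mean(v),
        sd = sd(v), relative_mean = rel, t = t_stat, p = p,
        significant = sig, stringsAsFactors = FALSE))
    }
  }
  out
}
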