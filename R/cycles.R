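# Body-waving cycles: annotation I/O, automatic detection, normalization to
# a common frame count, spatio-temporal curvature profiles, per-cycle
# extrema, wild-type normalization and group comparison.

#' Load manual cycle annotations
#'
#' CSV with columns `fish_id, start_frame, end_frame` (0-based, inclusive),
#' one row per body-waving cycle (the video segment in which the fish goes
#' straight, bends, and returns to straight).
#'
#' @param path Annotation CSV path.
#' @param n_frames Optional frame count of the video for bounds checking.
#' @return Data frame of cycles in file order; overlapping intervals are
#'   allowed with a warning; an empty file gives an empty data frame with a
#'   warning.
#' @export
load_cycle_annotations <- function(path, n_frames = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  empty <- data.frame(fish_id = character(0), start_frame = integer(0),
                      end_frame = integer(0), stringsAsFactors = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) <= 1) {
    warning("annotation file contains no cycles", call. = FALSE)
    return(empty)
  }
  ann <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "start_frame", "end_frame")
  if (!all(need %in% names(ann)))
    stop("annotation file must have columns fish_id, start_frame, end_frame",
         call. = FALSE)
  for (i in seq_len(nrow(ann))) {
    s <- ann$start_frame[i]; e <- ann$end_frame[i]
    if (is.na(s) || is.na(e) || s != floor(s) || e != floor(e) || s < 0 || s > e)
      stop(sprintf("malformed annotation row at line %d: start=%s end=%s",
                   i + 1L, ann$start_frame[i], ann$end_frame[i]), call. = FALSE)
    if (!is.null(n_frames) && e > n_frames - 1)
      stop(sprintf("annotation row at line %d exceeds video length (%d frames)",
                   i + 1L, n_frames), call. = FALSE)
  }
  if (nrow(ann) > 1) {
    by_fish <- split(seq_len(nrow(ann)), ann$fish_id)
    for (rows in by_fish) {
      if (length(rows) > 1) {
        o <- rows[order(ann$start_frame[rows])]
        # consecutive cycles may share a boundary frame; only a deeper
        # intrusion counts as an overlap
        if (any(ann$start_frame[o][-1] < ann$end_frame[o][-length(o)]))
          warning("overlapping cycle annotations", call. = FALSE)
      }
    }
  }
  ann$start_frame <- as.integer(ann$start_frame)
  ann$end_frame <- as.integer(ann$end_frame)
  ann
}

local_maxima <- function(s) {
  n <- length(s)
  if (n < 3) return(integer(0))
  peaks <- which(diff(sign(diff(s))) < 0) + 1L
  if (s[1] > s[2]) peaks <- c(1L, peaks)
  if (s[n] > s[n - 1]) peaks <- c(peaks, n)
  sort(unique(peaks))
}

peak_prominence <- function(s, p) {
  n <- length(s)
  left <- if (p == 1) s[1] else {
    i <- p - 1; lo <- s[p]
    while (i >= 1 && s[i] <= s[p]) { lo <- min(lo, s[i]); i <- i - 1 }
    lo
  }
  right <- if (p == n) s[n] else {
    i <- p + 1; lo <- s[p]
    while (i <= n && s[i] <= s[p]) { lo <- min(lo, s[i]); i <- i + 1 }
    lo
  }
  s[p] - max(left, right)
}

#' Detect body-waving cycles from the tail-offset series
#'
#' Convenience alternative to manual annotation: the per-frame tail-offset
#' series is smoothed (zero-phase low-pass at the temporal cutoff) and each
#' cycle spans two consecutive maxima of the smoothed series -- the fish is
#' straightest when tail offset peaks, so a maximum-to-maximum interval is
#' one straight-bent-straight excursion. Maxima below the configured
#' prominence are ignored.
#'
#' @param offsets Per-frame tail-offset series (frame 0 first).
#' @param cfg A [run_config()].
#' @return Data frame with `start_frame`, `end_frame` (0-based, inclusive);
#'   empty when no qualifying maxima exist.
#' @export
detect_cycles_auto <- function(offsets, cfg = run_config()) {
  offsets <- as.numeric(offsets)
  if (length(offsets) < 2 * cfg$cycle_length)
    stop("series shorter than two cycle lengths", call. = FALSE)
  s <- smooth_temporal(offsets, cfg$temporal_cutoff)
  peaks <- local_maxima(s)
  if (length(peaks) > 0) {
    prom <- vapply(peaks, function(p) peak_prominence(s, p), numeric(1))
    peaks <- peaks[prom >= cfg$auto_prominence]
  }
  if (length(peaks) < 2)
    return(data.frame(start_frame = integer(0), end_frame = integer(0)))
  data.frame(start_frame = peaks[-length(peaks)] - 1L,
             end_frame = peaks[-1] - 1L)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Normalize a cycle span to the target frame count
#'
#' Every body-waving cycle is represented by the same number of frames (30
#' in the reference analysis). A longer cycle is subsampled uniformly:
#' frame `k` maps to `start + round(k * (len - 1) / (target - 1))`
#' (round-half-away-from-zero; the selected frames are then no longer
#' contiguous). A shorter cycle is extended with contiguous frames before
#' and after the span, split as evenly as possible with the extra frame
#' going after on an odd deficit; when one side hits the video bounds the
#' slack moves to the other side.
#'
#' @param start_frame,end_frame Cycle span, 0-based inclusive.
#' @param target Target frame count (default 30).
#' @param n_frames Total frames in the video.
#' @return Sorted, duplicate-free integer vector of exactly `target`
#'   0-based frame indices.
#' @export
normalize_cycle_frames <- function(start_frame, end_frame, target = 30, n_frames) {
  stopifnot(start_frame <= end_frame, target >= 2)
  if (start_frame < 0 || end_frame > n_frames - 1)
    stop("cycle span outside video bounds", call. = FALSE)
  len <- end_frame - start_frame + 1
  if (len == target) return(as.integer(start_frame:end_frame))
  if (len > target) {
    k <- 0:(target - 1)
    idx <- start_frame + round_half_away(k * (len - 1) / (target - 1))
    # collapse any duplicates by shifting to the next unused index
    for (i in seq_along(idx)[-1]) {
      if (idx[i] <= idx[i - 1]) idx[i] <- idx[i - 1] + 1
    }
    if (idx[target] > end_frame) stop("cycle subsampling overflow", call. = FALSE)
    return(as.integer(idx))
  }
  deficit <- target - len
  before <- deficit %/% 2
  after <- deficit - before  # odd deficit extends after the cycle
  s <- start_frame - before
  e <- end_frame + after
  if (s < 0) { e <- e - s; s <- 0 }
  if (e > n_frames - 1) { s <- s - (e - (n_frames - 1)); e <- n_frames - 1 }
  if (s < 0)
    stop("video too short to extend the cycle to the target length", call. = FALSE)
  as.integer(s:e)
}

#' Spatio-temporal curvature profile of one cycle
#'
#' Collects the per-frame curvature vectors at the normalized frame indices
#' into the matrix C (body locations x normalized frames), then applies
#' spatial smoothing (along each column) and temporal smoothing (along each
#' row).
#'
#' @param metrics Output of [frame_metrics()] covering the needed frames.
#' @param norm_idx 0-based normalized frame indices from
#'   [normalize_cycle_frames()].
#' @param cfg A [run_config()].
#' @return List with `C` (smoothed matrix), `C_raw`, and `offsets` (the
#'   smoothed tail-offset series over the normalized frames).
#' @export
cycle_curvature_matrix <- function(metrics, norm_idx, cfg = run_config()) {
  cols <- match(norm_idx + 1L, metrics$frames)
  if (anyNA(cols))
    stop("posture metrics missing for frames: ",
         paste(norm_idx[is.na(cols)], collapse = ", "), call. = FALSE)
  C_raw <- metrics$curvature[, cols, drop = FALSE]
  offs <- metrics$tail_offset[cols]
  if (anyNA(C_raw) || anyNA(offs))
    stop("posture extraction failed within the cycle", call. = FALSE)
  C <- smooth_temporal(smooth_spatial(C_raw, cfg$spatial_cutoff), cfg$temporal_cutoff)
  list(C = C, C_raw = C_raw, offsets = smooth_temporal(offs, cfg$temporal_cutoff))
}

#' Per-cycle extrema metrics
#'
#' The scalar summaries taken from each body-waving cycle: the largest
#' smoothed body curvature, the smallest smoothed tail offset, and the
#' centroid travel distance over the cycle span.
#'
#' @param C Smoothed curvature profile matrix.
#' @param offsets Smoothed tail-offset series of the cycle.
#' @param centroids Centroid matrix over the cycle's full frame span (NA
#'   rows for undetected frames; gaps of at most 2 frames are bridged).
#' @param mode Travel-distance mode, `"path"` or `"net"`.
#' @return List with `max_curvature`, `min_tail_offset`, `travel_distance`.
#' @export
cycle_extrema <- function(C, offsets, centroids, mode = "path") {
  list(max_curvature = max(C),
       min_tail_offset = min(offsets),
       travel_distance = travel_distance(centroids, mode = mode))
}

#' Average curvature and tail-offset profiles over a group
#'
#' Elementwise mean of the per-cycle curvature matrices and tail-offset
#' series of all cycles of all fish within one group.
#'
#' @param profiles List of curvature matrices (same dimensions).
#' @param offsets List of tail-offset series (same length).
#' @param group Group label.
#' @return List with `group`, `mean_profile`, `mean_offsets`, `n_cycles`.
#' @export
average_group_profiles <- function(profiles, offsets, group = "") {
  if (length(profiles) == 0) stop("empty group", call. = FALSE)
  d <- dim(profiles[[1]])
  if (!all(vapply(profiles, function(p) identical(dim(p), d), logical(1))))
    stop("profiles must share dimensions", call. = FALSE)
  mp <- Reduce(`+`, profiles) / length(profiles)
  mo <- Reduce(`+`, offsets) / length(offsets)
  list(group = group, mean_profile = mp, mean_offsets = mo,
       n_cycles = length(profiles))
}

#' Normalize per-cycle metrics to the wild-type mean
#'
#' Divides every cycle's metric values by the wild-type group's mean of
#' that metric, so the wild-type relative mean is 1 by construction.
#'
#' @param cycles Per-cycle metrics data frame with columns `group`,
#'   `max_curvature_deg`, `min_tail_offset`, `travel_distance_px`.
#' @param wildtype Wild-type group label.
#' @return The data frame with the three metric columns rescaled.
#' @export
normalize_to_wildtype <- function(cycles, wildtype = "wildtype") {
  if (!wildtype %in% cycles$group)
    stop("wild-type group '", wildtype, "' not present", call. = FALSE)
  wt <- cycles[cycles$group == wildtype, ]
  for (col in c("max_curvature_deg", "min_tail_offset", "travel_distance_px")) {
    m <- mean(wt[[col]])
    if (!is.finite(m) || m == 0)
      stop("wild-type mean of ", col, " is zero; cannot normalize", call. = FALSE)
    cycles[[col]] <- cycles[[col]] / m
  }
  cycles
}

#' Two-sample Student t comparison against wild-type
#'
#' Classical pooled-variance two-sided Student t test (Welch optional) of a
#' group's per-cycle metric values against the wild-type values;
#' significance at `p < alpha`. Degenerate zero-variance inputs are handled
#' explicitly: equal means give t = 0, p = 1; unequal means with zero
#' pooled variance are reported significant with p at the smallest positive
#' double.
#'
#' @param x Group metric values (length >= 2).
#' @param y Wild-type metric values (length >= 2).
#' @param alpha Significance level.
#' @param equal_variance Pooled-variance Student t (default) or Welch.
#' @return List with `t`, `p`, `significant`, `df`.
#' @export
compare_groups <- function(x, y, alpha = 0.05, equal_variance = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(list(t = 0, p = 1, significant = FALSE,
                  df = length(x) + length(y) - 2))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = .Machine$double.xmin,
                significant = TRUE, df = length(x) + length(y) - 2))
  }
  tt <- stats::t.test(x, y, var.equal = equal_variance)
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < alpha, df = unname(tt$parameter))
}
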