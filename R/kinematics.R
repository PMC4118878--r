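# Per-frame body-wave measurements: segment angles, unsigned body curvature
# at each control point, tail offset T/L, and centroid travel distance.

wrap_angle_deg <- function(a) {
  # wrap to (-180, 180]
  w <- ((a + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Direction angles of consecutive midline segments
#'
#' Angle of segment i is the direction of the vector from control point i
#' to point i + 1, `atan2(dy, dx)` in degrees, range (-180, 180].
#'
#' @param p A [control_points()] (or an n x 2 coordinate matrix).
#' @return Numeric vector of n - 1 angles in degrees.
#' @export
segment_angles <- function(p) {
  pts <- if (inherits(p, "control_points")) p$points else as.matrix(p)
  if (nrow(pts) < 2) stop("need at least 2 points", call. = FALSE)
  d <- pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
  if (any(rowSums(d^2) < 1e-18))
    stop("coincident consecutive control points", call. = FALSE)
  atan2(d[, 2], d[, 1]) * 180 / pi
}

#' Unsigned body curvature at each control point
#'
#' Curvature at interior body location i is the absolute wrapped difference
#' between the directions of segments i and i - 1, in degrees: the angular
#' change between neighbouring midline segments. Larger values mean larger
#' bending. The two endpoint locations copy their nearest interior
#' neighbour so the result has one value per control point (20 by default),
#' matching the spatio-temporal profile layout.
#'
#' @param p A [control_points()] (or an n x 2 coordinate matrix, n >= 3).
#' @return Numeric vector of n unsigned curvature values in degrees.
#' @export
body_curvature <- function(p) {
  pts <- if (inherits(p, "control_points")) p$points else as.matrix(p)
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points for curvature", call. = FALSE)
  ang <- segment_angles(pts)
  interior <- abs(wrap_angle_deg(diff(ang)))
  c(interior[1], interior, interior[length(interior)])
}

#' Tail offset of a posture
#'
#' T / L, where T is the Euclidean distance from the last control point
#' (tail) to the body centroid and L the body length. Smaller values
#' indicate larger bending; a straight uniform-width fish scores about 0.5.
#' The measure depends only on the posture, not on where the fish is in the
#' tank, so it is invariant to the swimming trajectory.
#'
#' @param p A [control_points()].
#' @param m The matching `fish_mask` (supplies the centroid), or a length-2
#'   numeric (x, y) centroid.
#' @return The tail-offset ratio.
#' @export
tail_offset <- function(p, m) {
  stopifnot(inherits(p, "control_points"))
  centroid <- if (inherits(m, "fish_mask")) m$centroid else as.numeric(m)
  L <- p$body_length
  if (L <= 0) stop("body length must be > 0", call. = FALSE)
  tailp <- p$points[nrow(p$points), ]
  sqrt(sum((tailp - centroid)^2)) / L
}

#' Travel distance of the body centroid
#'
#' Path length of the centroid trajectory: the sum of Euclidean distances
#' between consecutive per-frame centroids (`mode = "net"` gives the
#' start-to-end displacement instead). Runs of at most `max_gap`
#' consecutive undetected frames are bridged by linear interpolation;
#' longer gaps are an error so the enclosing cycle can be rejected.
#'
#' @param centroids n x 2 matrix of (x, y) centroids; undetected frames NA.
#' @param mode `"path"` (default) or `"net"`.
#' @param max_gap Longest run of missing frames bridged by interpolation.
#' @return Distance in pixels.
#' @export
travel_distance <- function(centroids, mode = c("path", "net"), max_gap = 2L) {
  mode <- match.arg(mode)
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  missing <- is.na(centroids[, 1]) | is.na(centroids[, 2])
  if (sum(!missing) < 2) stop("need at least 2 valid centroids", call. = FALSE)
  if (missing[1] || missing[n])
    stop("cycle starts or ends on an undetected frame", call. = FALSE)
  if (any(missing)) {
    runs <- rle(missing)
    if (max(runs$lengths[runs$values]) > max_gap)
      stop(sprintf("more than %d consecutive undetected frames", max_gap),
           call. = FALSE)
    idx <- seq_len(n)
    centroids[, 1] <- approx(idx[!missing], centroids[!missing, 1], xout = idx)$y
    centroids[, 2] <- approx(idx[!missing], centroids[!missing, 2], xout = idx)$y
  }
  if (mode == "net") {
    sqrt(sum((centroids[n, ] - centroids[1, ])^2))
  } else {
    d <- centroids[-1, , drop = FALSE] - centroids[-n, , drop = FALSE]
    sum(sqrt(rowSums(d^2)))
  }
}

#' Per-frame posture metrics for a tracked sequence
#'
#' Extracts the posture and the per-frame measurements (curvature vector,
#' tail offset) for the requested frames, keeping head-tail orientation
#' consistent over time. Frames whose posture fails (no detection, low
#' elongation, ring skeleton) get NA metrics and are reported in
#' `$failures`.
#'
#' @param track A `fish_track` from [track_sequence()].
#' @param cfg A [run_config()].
#' @param frames 1-based frame indices to process (default: all detected).
#' @return List with `curvature` (n_points x n_frames matrix, NA columns on
#'   failure), `tail_offset`, `postures` (list), `frames`, `failures`
#'   (data frame of frame and reason).
#' @export
frame_metrics <- function(track, cfg = run_config(), frames = NULL) {
  stopifnot(inherits(track, "fish_track"))
  if (is.null(frames)) frames <- which(track$detected)
  frames <- sort(unique(as.integer(frames)))
  K <- matrix(NA_real_, nrow = cfg$n_points, ncol = length(frames))
  offs <- rep(NA_real_, length(frames))
  postures <- vector("list", length(frames))
  fail_frame <- integer(0); fail_reason <- character(0)
  prev <- NULL
  for (j in seq_along(frames)) {
    i <- frames[j]
    m <- track$masks[[i]]
    if (is.null(m)) {
      fail_frame <- c(fail_frame, i); fail_reason <- c(fail_reason, "no detection")
      next
    }
    p <- tryCatch(extract_posture(m, cfg, prev), error = function(e) e)
    if (inherits(p, "error")) {
      fail_frame <- c(fail_frame, i)
      fail_reason <- c(fail_reason, conditionMessage(p))
      next
    }
    postures[[j]] <- p
    K[, j] <- body_curvature(p)
    offs[j] <- tail_offset(p, m)
    prev <- p
  }
  list(curvature = K, tail_offset = offs, postures = postures, frames = frames,
       failures = data.frame(frame = fail_frame, reason = fail_reason,
                             stringsAsFactors = FALSE))
}
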