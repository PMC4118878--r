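# Posture model: boundary, skeleton-based centerline ordered head to tail,
# and resampling to a fixed number of arc-length-uniform control points.

#' Construct a centerline object
#'
#' @param points n x 2 matrix of (x, y) coordinates, head to tail.
#' @return A `centerline` with `points` and `arc_length`.
#' @export
centerline <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("a centerline needs at least 2 points", call. = FALSE)
  gaps <- sqrt(rowSums((points[-1, , drop = FALSE] - points[-nrow(points), , drop = FALSE])^2))
  if (any(gaps < 1e-12)) stop("consecutive centerline points must be distinct", call. = FALSE)
  structure(list(points = unname(points), arc_length = sum(gaps)), class = "centerline")
}

#' Construct a control-points posture object
#'
#' @param points n x 2 matrix of (x, y) coordinates, head first, tail last.
#' @param body_length Arc length L of the midline the points sample.
#' @return A `control_points` object.
#' @export
control_points <- function(points, body_length) {
  points <- as.matrix(points)
  if (body_length <= 0) stop("body_length must be > 0", call. = FALSE)
  structure(list(points = unname(points), body_length = as.numeric(body_length)),
            class = "control_points")
}

#' Extract the outer boundary of a fish mask
#'
#' Ordered closed contour of the outer boundary, in 0-based (x, y)
#' coordinates. Holes are filled first (with a warning) so only the outer
#' contour is returned.
#'
#' @param m A `fish_mask`.
#' @return Matrix of contour points (x, y); a single-pixel mask yields a
#'   one-point degenerate contour.
#' @export
extract_boundary <- function(m) {
  stopifnot(inherits(m, "fish_mask"))
  mask <- m$mask * 1
  filled <- EBImage::imageData(EBImage::fillHull(mask))
  if (any(filled != mask))
    warning("mask contains holes; outer contour returned", call. = FALSE)
  oc <- EBImage::ocontour(filled)[[1]]
  # ocontour is 0-based (row, col); convert to full-frame (x, y)
  cbind(x = oc[, 2] + m$offset[1], y = oc[, 1] + m$offset[2])
}

# matrix shift: out[i, j] = m[i + dy, j + dx], zero-filled at the borders
shift_mat <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dy):min(nr, nr + dy)
  cs <- max(1, 1 + dx):min(nc, nc + dx)
  out[rs - dy, cs - dx] <- m[rs, cs]
  out
}

# Zhang-Suen morphological thinning to a 1-px-wide, topology-preserving
# skeleton. Operates on a 0/1 integer matrix; the caller crops to the
# bounding box for speed.
thin_zhang_suen <- function(mask) {
  m <- mask * 1L
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- shift_mat(m, -1, 0);  p3 <- shift_mat(m, -1, 1)
      p4 <- shift_mat(m, 0, 1);   p5 <- shift_mat(m, 1, 1)
      p6 <- shift_mat(m, 1, 0);   p7 <- shift_mat(m, 1, -1)
      p8 <- shift_mat(m, 0, -1);  p9 <- shift_mat(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (sub == 1) {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# count of 8-neighbours for each skeleton pixel
neighbour_counts <- function(m) {
  shift_mat(m, -1, 0) + shift_mat(m, -1, 1) + shift_mat(m, 0, 1) +
    shift_mat(m, 1, 1) + shift_mat(m, 1, 0) + shift_mat(m, 1, -1) +
    shift_mat(m, 0, -1) + shift_mat(m, -1, -1)
}

# Longest end-to-end path through the skeleton: Dijkstra over the 8-connected
# pixel graph with Euclidean step costs, maximized over endpoint pairs.
skeleton_longest_path <- function(skel) {
  pix <- which(skel == 1, arr.ind = TRUE)
  if (nrow(pix) < 2) stop("degenerate skeleton", call. = FALSE)
  nr <- nrow(skel)
  id <- (pix[, 2] - 1L) * nr + pix[, 1]  # linear index
  idmap <- match(seq_len(nr * ncol(skel)), id)

  edges <- NULL; weights <- NULL
  offs <- list(c(0, 1, 1), c(1, 1, sqrt(2)), c(1, 0, 1), c(1, -1, sqrt(2)))
  for (o in offs) {
    nbr_r <- pix[, 1] + o[1]; nbr_c <- pix[, 2] + o[2]
    ok <- nbr_r >= 1 & nbr_r <= nr & nbr_c >= 1 & nbr_c <= ncol(skel)
    nbr_id <- (nbr_c - 1L) * nr + nbr_r
    j <- rep(NA_integer_, length(id))
    j[ok] <- idmap[nbr_id[ok]]
    sel <- !is.na(j)
    if (any(sel)) {
      edges <- rbind(edges, cbind(which(sel), j[sel]))
      weights <- c(weights, rep(o[3], sum(sel)))
    }
  }
  if (is.null(edges)) stop("disconnected skeleton pixels", call. = FALSE)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- weights

  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  members <- which(comp$membership == main)

  ncounts <- neighbour_counts(skel)
  endp <- members[ncounts[cbind(pix[members, 1], pix[members, 2])] == 1]
  if (length(endp) == 0)
    stop("skeleton has no endpoints (ring topology)", call. = FALSE)
  if (length(endp) == 1) endp <- c(endp, endp)

  d <- igraph::distances(g, v = endp, to = endp)
  best <- which(d == max(d[is.finite(d)]), arr.ind = TRUE)[1, ]
  if (endp[best[1]] == endp[best[2]]) stop("degenerate skeleton path", call. = FALSE)
  sp <- igraph::shortest_paths(g, from = endp[best[1]], to = endp[best[2]],
                               output = "vpath")$vpath[[1]]
  v <- as.integer(sp)
  cbind(x = pix[v, 2] - 1, y = pix[v, 1] - 1)
}

mask_elongation <- function(mask) {
  pix <- which(mask, arr.ind = TRUE)
  if (nrow(pix) < 3) return(1)
  cv <- stats::cov(pix)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 1e-9] <- 1e-9
  sqrt(ev[1] / ev[2])
}

# 5-point moving average with shrinking windows at the ends; the two
# endpoints themselves are kept fixed so the path still terminates at the
# skeleton endpoints. Residual pixel noise is handled by the spatial and
# temporal low-pass smoothing of the curvature profiles.
smooth_polyline <- function(pts, half = 2L) {
  n <- nrow(pts)
  if (n <= 4) return(pts)
  out <- pts
  for (i in 2:(n - 1)) {
    w <- max(1, i - half):min(n, i + half)
    out[i, ] <- colMeans(pts[w, , drop = FALSE])
  }
  keep <- c(TRUE, sqrt(rowSums((out[-1, , drop = FALSE] - out[-n, , drop = FALSE])^2)) > 1e-9)
  out[keep, , drop = FALSE]
}

#' Extract the fish centerline from a mask
#'
#' Thins the mask to a topology-preserving skeleton (Zhang-Suen), takes the
#' longest end-to-end path through the skeleton pixel graph (which discards
#' fin/noise spurs without explicit pruning parameters), smooths the
#' resulting polyline with a 5-point moving average to suppress staircase
#' artifacts, and extends both ends along the local tangent to the mask
#' boundary to recover the tip regions that thinning erodes. The mask must
#' be elongated (major/minor axis ratio >= 1.5) for the medial-axis
#' assumption to hold.
#'
#' @param m A `fish_mask`.
#' @return A [centerline()] (orientation arbitrary; see
#'   [orient_head_to_tail()]).
#' @export
extract_centerline <- function(m) {
  stopifnot(inherits(m, "fish_mask"))
  elong <- mask_elongation(m$mask)
  if (elong < 1.5)
    stop(sprintf("mask elongation %.2f below 1.5; medial axis unreliable", elong),
         call. = FALSE)
  pix <- which(m$mask, arr.ind = TRUE)
  r0 <- max(1, min(pix[, 1]) - 1); r1 <- min(nrow(m$mask), max(pix[, 1]) + 1)
  c0 <- max(1, min(pix[, 2]) - 1); c1 <- min(ncol(m$mask), max(pix[, 2]) + 1)
  sub <- m$mask[r0:r1, c0:c1] * 1L
  skel <- thin_zhang_suen(sub)
  path <- skeleton_longest_path(skel)
  path[, 1] <- path[, 1] + (c0 - 1)  # back to mask-local 0-based coords
  path[, 2] <- path[, 2] + (r0 - 1)
  if (nrow(path) < 2) stop("degenerate centerline", call. = FALSE)
  dm <- EBImage::imageData(EBImage::distmap(m$mask * 1))
  pts <- refine_polyline(smooth_polyline(path), m$mask)
  pts <- extend_to_mask(pts, m$mask, dm)
  centerline(sweep(pts, 2, m$offset, "+"))  # to full-frame coords
}

# bilinear interpolation of a binary mask at continuous 0-based (x, y);
# pixel (r, c) is centred at (x, y) = (c - 1, r - 1)
mask_bilinear <- function(mask, x, y) {
  nr <- nrow(mask); nc <- ncol(mask)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  val <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- numeric(length(r))
    v[ok] <- mask[cbind(r[ok], c[ok])]
    v
  }
  (1 - fy) * ((1 - fx) * val(y0 + 1, x0 + 1) + fx * val(y0 + 1, x0 + 2)) +
    fy * ((1 - fx) * val(y0 + 2, x0 + 1) + fx * val(y0 + 2, x0 + 2))
}

# Midpoint of the mask cross-section through `pos` perpendicular to
# `dirv`, with the two boundary positions located to sub-pixel precision
# by linear interpolation of the bilinear mask profile across 0.5.
# Returns NULL when `pos` itself is outside the mask.
cross_section_midpoint <- function(pos, dirv, mask, reach = 12, step = 0.5) {
  perp <- c(-dirv[2], dirv[1])
  ts <- seq(-reach, reach, by = step)
  v <- mask_bilinear(mask, pos[1] + perp[1] * ts, pos[2] + perp[2] * ts)
  i0 <- which(ts == 0)
  if (v[i0] < 0.5) return(NULL)
  lo <- i0; while (lo > 1 && v[lo - 1] >= 0.5) lo <- lo - 1
  hi <- i0; while (hi < length(ts) && v[hi + 1] >= 0.5) hi <- hi + 1
  tlo <- if (lo > 1 && v[lo] > v[lo - 1]) {
    ts[lo] - step * (v[lo] - 0.5) / (v[lo] - v[lo - 1])
  } else ts[lo]
  thi <- if (hi < length(ts) && v[hi] > v[hi + 1]) {
    ts[hi] + step * (v[hi] - 0.5) / (v[hi] - v[hi + 1])
  } else ts[hi]
  pos + perp * (tlo + thi) / 2
}

# Sub-pixel refinement: shift every path point to the midpoint of the mask
# cross-section along the local normal. The thinned skeleton lies on the
# integer pixel grid, which biases it by up to half a pixel relative to
# the true medial axis; the cross-section midpoint restores sub-pixel
# placement and matches the rule used for tip extension.
refine_polyline <- function(pts, mask, reach = 12) {
  n <- nrow(pts)
  if (n < 5) return(pts)
  out <- pts
  for (i in seq_len(n)) {
    a <- max(1, i - 2); b <- min(n, i + 2)
    tang <- pts[b, ] - pts[a, ]
    nd <- sqrt(sum(tang^2))
    if (nd < 1e-9) next
    mid <- cross_section_midpoint(pts[i, ], tang / nd, mask, reach)
    if (!is.null(mid)) out[i, ] <- mid
  }
  keep <- c(TRUE, sqrt(rowSums((out[-1, , drop = FALSE] - out[-n, , drop = FALSE])^2)) > 1e-9)
  out[keep, , drop = FALSE]
}

# Morphological thinning retracts the skeleton from each body tip by about
# the local half-width. March from each path end toward the mask boundary,
# re-centering every step on the midpoint of the local mask cross-section
# so the extension follows a curving tail instead of freezing the tangent;
# the centerline then spans snout to tail tip and body length is not
# systematically underestimated.
extend_to_mask <- function(pts, mask, dm, step = 1) {
  nr <- nrow(mask); nc <- ncol(mask)
  # thinning retracts each end by ~the local half-width, which is the
  # distance-transform value at the skeleton endpoint
  ext_budget <- function(endpt) {
    rr <- min(max(round(endpt[2]) + 1, 1), nr)
    cc <- min(max(round(endpt[1]) + 1, 1), nc)
    dm[rr, cc] + 3
  }
  inside <- function(xy) {
    rr <- round(xy[2]) + 1; cc <- round(xy[1]) + 1
    rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && mask[rr, cc]
  }
  recenter <- function(pos, dirv, reach = 10) {
    mid <- cross_section_midpoint(pos, dirv, mask, reach)
    if (is.null(mid)) pos else mid
  }
  extend_tail <- function(pts) {
    n <- nrow(pts)
    k <- min(n - 1, 4)
    dirv <- pts[n, ] - pts[n - k, ]
    nd <- sqrt(sum(dirv^2))
    if (nd < 1e-9) return(pts)
    dirv <- dirv / nd
    pos <- pts[n, ]
    max_ext <- ext_budget(pos)
    added <- NULL
    # march outward, re-centering each step on the local mask cross-section
    # and letting the direction follow the re-centered path so a curling
    # tip is tracked; the distance-transform budget keeps the march from
    # rounding the end cap
    total <- 0
    repeat {
      cand <- pos + dirv * step
      total <- total + step
      if (total > max_ext || !inside(cand)) break
      cand <- recenter(cand, dirv)
      stepv <- cand - pos
      nd2 <- sqrt(sum(stepv^2))
      if (nd2 < 1e-9) break
      dirv2 <- dirv + stepv / nd2   # averaged direction update
      dirv <- dirv2 / sqrt(sum(dirv2^2))
      pos <- cand
      added <- rbind(added, cand)
    }
    if (is.null(added)) pts else rbind(pts, added)
  }
  pts <- extend_tail(pts)
  pts <- extend_tail(pts[nrow(pts):1, , drop = FALSE])
  pts[nrow(pts):1, , drop = FALSE]
}

mean_width_near <- function(pts, dm, frac = 0.1) {
  gaps <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(gaps))
  sel <- s <= frac * s[length(s)]
  p <- pts[sel, , drop = FALSE]
  rr <- pmin(pmax(round(p[, 2]) + 1, 1), nrow(dm))
  cc <- pmin(pmax(round(p[, 1]) + 1, 1), ncol(dm))
  mean(dm[cbind(rr, cc)])
}

#' Orient a centerline head to tail
#'
#' Index 0 becomes the head. With a previous-frame posture available, the
#' orientation minimizing the summed endpoint-to-endpoint distances is kept
#' (temporal consistency). On a first frame the wider end is the head
#' (adult zebrafish heads are wider than the caudal peduncle): the mean
#' distance-transform value over the 10% of arc length nearest each
#' endpoint decides. Exactly equal widths fall back to the deterministic
#' rule head = endpoint with smaller x (tie: smaller y).
#'
#' @param c A [centerline()].
#' @param m The `fish_mask` the centerline came from.
#' @param prev Previous frame's oriented [control_points()], or `NULL`.
#' @return The centerline, possibly reversed.
#' @export
orient_head_to_tail <- function(c, m, prev = NULL) {
  stopifnot(inherits(c, "centerline"))
  pts <- c$points
  n <- nrow(pts)
  flip <- FALSE
  if (!is.null(prev)) {
    stopifnot(inherits(prev, "control_points"))
    ph <- prev$points[1, ]; pt <- prev$points[nrow(prev$points), ]
    d_keep <- sqrt(sum((pts[1, ] - ph)^2)) + sqrt(sum((pts[n, ] - pt)^2))
    d_flip <- sqrt(sum((pts[n, ] - ph)^2)) + sqrt(sum((pts[1, ] - pt)^2))
    flip <- d_flip < d_keep
  } else {
    dm <- EBImage::imageData(EBImage::distmap(m$mask * 1))
    local <- sweep(pts, 2, m$offset)   # distance map is mask-local
    w_first <- mean_width_near(local, dm)
    w_last <- mean_width_near(local[n:1, , drop = FALSE], dm)
    if (abs(w_first - w_last) > 1e-9) {
      flip <- w_last > w_first
    } else {
      e1 <- pts[1, ]; e2 <- pts[n, ]
      flip <- (e2[1] < e1[1]) || (e2[1] == e1[1] && e2[2] < e1[2])
    }
  }
  if (flip) centerline(pts[n:1, , drop = FALSE]) else c
}

#' Resample a centerline to uniformly spaced control points
#'
#' Places `n` points at arc lengths `k * L / (n - 1)`, `k = 0..n-1`, by
#' linear interpolation along the polyline; the first and last points are
#' the head and tail endpoints exactly. Resampling an already uniform
#' n-point polyline is idempotent.
#'
#' @param c A head-to-tail oriented [centerline()].
#' @param n Number of control points (>= 2; the posture model uses 20).
#' @return A [control_points()] with `body_length = c$arc_length`.
#' @export
sample_control_points <- function(c, n = 20) {
  stopifnot(inherits(c, "centerline"))
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  pts <- c$points
  gaps <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(gaps))
  L <- s[length(s)]
  if (L <= 0) stop("degenerate centerline with zero length", call. = FALSE)
  targets <- seq(0, L, length.out = n)
  x <- approx(s, pts[, 1], xout = targets, ties = "ordered")$y
  y <- approx(s, pts[, 2], xout = targets, ties = "ordered")$y
  out <- cbind(x, y)
  out[1, ] <- pts[1, ]; out[n, ] <- pts[nrow(pts), ]
  control_points(out, body_length = L)
}

#' Full posture extraction for one frame
#'
#' Convenience wrapper: centerline, head-tail orientation, control-point
#' resampling.
#'
#' @param m A `fish_mask`.
#' @param cfg A [run_config()].
#' @param prev Previous frame's [control_points()] or `NULL`.
#' @return A [control_points()].
#' @export
extract_posture <- function(m, cfg = run_config(), prev = NULL) {
  cl <- extract_centerline(m)
  cl <- orient_head_to_tail(cl, m, prev)
  sample_control_points(cl, cfg$n_points)
}
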