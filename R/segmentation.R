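# Fish detection: per-pixel temporal median background, absolute-difference
# thresholding, morphological cleanup, largest connected component.

#' Per-pixel temporal median background model
#'
#' Each background pixel is the median over all frames of that pixel's
#' intensity; with an even number of frames the lower median is used
#' (element at index `floor((n-1)/2)` of the 0-based sorted series), which
#' keeps an actually observed intensity and preserves integer rasters. The
#' model is invariant under any permutation of the frame order.
#'
#' @param seq A [frame_sequence()].
#' @return A `background_model` with field `background` (matrix).
#' @export
compute_background <- function(seq) {
  stopifnot(inherits(seq, "frame_sequence"))
  n <- length(seq$frames)
  h <- seq$height; w <- seq$width
  k <- (n - 1L) %/% 2L + 1L  # lower median (1-based)
  if (n == 1) {
    bg <- seq$frames[[1]]
  } else if (all(vapply(seq$frames, is.integer, logical(1)))) {
    bg <- median_integer_frames(seq$frames, k, h, w)
  } else {
    bg <- median_generic_frames(seq$frames, k, h, w)
  }
  structure(list(background = bg), class = "background_model")
}

# Counting-sort median for 8-bit integer frames: one pass per frame plus one
# pass per intensity level, no per-pixel sort.
median_integer_frames <- function(frames, k, h, w) {
  npix <- h * w
  counts <- matrix(0L, nrow = npix, ncol = 256)
  for (f in frames) {
    v <- as.integer(f)
    v[v < 0L] <- 0L; v[v > 255L] <- 255L
    idx <- seq_len(npix) + npix * v
    counts[idx] <- counts[idx] + 1L
  }
  med <- integer(npix)
  cum <- integer(npix)
  done <- logical(npix)
  for (b in 0:255) {
    cum <- cum + counts[, b + 1L]
    hit <- !done & cum >= k
    med[hit] <- b
    done <- done | hit
    if (all(done)) break
  }
  out <- matrix(med, nrow = h, ncol = w)
  storage.mode(out) <- "integer"
  out
}

median_generic_frames <- function(frames, k, h, w) {
  npix <- h * w
  n <- length(frames)
  out <- numeric(npix)
  chunk <- max(1L, 2000000L %/% n)
  starts <- seq(1L, npix, by = chunk)
  for (s in starts) {
    e <- min(s + chunk - 1L, npix)
    block <- vapply(frames, function(f) f[s:e], numeric(e - s + 1L))
    if (is.null(dim(block))) block <- matrix(block, nrow = 1L)
    out[s:e] <- apply(block, 1L, function(v) sort.int(v, partial = k)[k])
  }
  matrix(out, nrow = h, ncol = w)
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected, so
# labels touching only diagonally are merged with a union-find pass.
label_components8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  nmax <- max(lab)
  if (nmax <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]   # up-right diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  parent <- seq_len(nmax)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(pairs) > 0) {
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nmax), find, integer(1))
  compact <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- compact[lab[lab > 0]]
  out
}

brush3 <- function() EBImage::makeBrush(3, shape = "box")

#' Segment the fish in one frame
#'
#' Thresholds the absolute difference between the frame and the background,
#' applies one binary opening then closing with a 3x3 structuring element,
#' labels 8-connected components, discards those below `cfg$min_area`, and
#' keeps the largest (ties broken by the component whose first foreground
#' pixel comes earliest in row-major order). Because only the difference is
#' thresholded, the result is invariant to adding a constant offset to both
#' frame and background.
#'
#' @param frame Intensity matrix.
#' @param bg A `background_model` with matching dimensions.
#' @param cfg A [run_config()].
#' @param frame_index Index recorded in the result (0-based).
#' @return A `fish_mask` (fields `frame_index`, `mask`, `centroid` = (x, y),
#'   `area`) or `NULL` when no component qualifies.
#' @export
segment_fish <- function(frame, bg, cfg = run_config(), frame_index = 0L) {
  stopifnot(inherits(bg, "background_model"))
  if (!identical(dim(frame), dim(bg$background)))
    stop("frame and background dimensions differ", call. = FALSE)
  diffm <- abs(frame - bg$background)
  fg <- (diffm >= cfg$threshold) * 1
  if (!any(fg > 0)) return(NULL)
  kern <- brush3()
  fg <- EBImage::imageData(EBImage::closing(EBImage::opening(fg, kern), kern))
  if (!any(fg > 0)) return(NULL)
  lab <- label_components8(fg)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= cfg$min_area)
  if (length(keep) == 0) return(NULL)
  best <- keep[areas[keep] == max(areas[keep])]
  if (length(best) > 1) {
    # row-major scan order: y (row) first, then x (col)
    first_pos <- vapply(best, function(lb) {
      idx <- which(lab == lb, arr.ind = TRUE)
      min((idx[, 1] - 1) * ncol(lab) + (idx[, 2] - 1))
    }, numeric(1))
    best <- best[which.min(first_pos)]
  }
  mask <- (lab == best)
  pix <- which(mask, arr.ind = TRUE)
  if ((1 %in% pix[, 1]) || (nrow(mask) %in% pix[, 1]) ||
      (1 %in% pix[, 2]) || (ncol(mask) %in% pix[, 2]))
    warning("fish touches the image border; centerline endpoints may be clipped",
            call. = FALSE)
  # store only the bounding box (1 px pad): a full-frame mask per frame
  # would dominate memory on long videos
  r0 <- max(1L, min(pix[, 1]) - 1L); r1 <- min(nrow(mask), max(pix[, 1]) + 1L)
  c0 <- max(1L, min(pix[, 2]) - 1L); c1 <- min(ncol(mask), max(pix[, 2]) + 1L)
  fish_mask(mask[r0:r1, c0:c1, drop = FALSE], frame_index = frame_index,
            offset = c(c0 - 1L, r0 - 1L))
}

#' Construct a fish mask object
#'
#' @param mask Logical matrix (single connected component expected), which
#'   may be cropped to the fish's bounding box.
#' @param frame_index 0-based frame index.
#' @param offset 0-based (x, y) position of the mask's top-left pixel in
#'   the full frame; `c(0, 0)` for an uncropped mask.
#' @return A `fish_mask` with the unweighted foreground-pixel centroid in
#'   0-based full-frame (x, y) coordinates.
#' @export
fish_mask <- function(mask, frame_index = 0L, offset = c(0L, 0L)) {
  pix <- which(mask, arr.ind = TRUE)
  if (nrow(pix) == 0) stop("empty mask", call. = FALSE)
  offset <- as.numeric(offset)
  centroid <- c(x = mean(pix[, 2]) - 1 + offset[1],
                y = mean(pix[, 1]) - 1 + offset[2])
  structure(list(frame_index = as.integer(frame_index), mask = mask,
                 offset = offset, centroid = centroid, area = nrow(pix)),
            class = "fish_mask")
}

#' Track the fish across a whole sequence
#'
#' Builds the median background once, segments every frame, and assembles
#' the centroid trajectory. Frames without a qualifying detection are
#' flagged (`detected = FALSE`, NA centroid); downstream cycle rules decide
#' whether they are bridged or cause rejection. More than 50% undetected
#' frames is a tracking failure.
#'
#' @param seq A [frame_sequence()].
#' @param cfg A [run_config()].
#' @param bg Optional precomputed `background_model`.
#' @return A `fish_track`: list with `masks` (per-frame `fish_mask` or
#'   `NULL`), `centroids` (n x 2 matrix, columns x and y), `detected`
#'   (logical), `areas`, and `background`.
#' @export
track_sequence <- function(seq, cfg = run_config(), bg = NULL) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (is.null(bg)) bg <- compute_background(seq)
  n <- length(seq$frames)
  masks <- vector("list", n)
  centroids <- matrix(NA_real_, nrow = n, ncol = 2,
                      dimnames = list(NULL, c("x", "y")))
  areas <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fm <- segment_fish(seq$frames[[i]], bg, cfg, frame_index = i - 1L)
    if (!is.null(fm)) {
      masks[[i]] <- fm
      centroids[i, ] <- fm$centroid
      areas[i] <- fm$area
    }
  }
  detected <- !is.na(areas)
  if (mean(detected) < 0.5)
    stop(sprintf("tracking failure: fish detected in only %d of %d frames",
                 sum(detected), n), call. = FALSE)
  structure(list(masks = masks, centroids = centroids, detected = detected,
                 areas = areas, background = bg),
            class = "fish_track")
}
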