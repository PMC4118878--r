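# Shared fixtures, built in code and memoized so expensive renders and
# tracking runs happen once per test session.

.fixture_cache <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# default-scale swimmer (3 annotated cycles) plus its track
fixture_swimmer <- function() {
  memoize("swimmer", {
    sw <- generate_swimmer(swimmer_params(seed = 11L), n_cycles = 3,
                           fish_id = "fx1")
    sw$track <- track_sequence(sw$video, run_config())
    sw
  })
}

# a single mid-swim fish mask + matching truth, for posture tests
fixture_mask <- function() {
  sw <- fixture_swimmer()
  i <- sw$cycles$start_frame[1] + 16L
  list(mask = sw$track$masks[[i + 1L]], truth = sw$truth[[i + 1L]],
       frame = i)
}

# does the (possibly cropped) fish mask contain full-frame pixel (x, y)?
mask_has_pixel <- function(fm, x, y) {
  r <- y - fm$offset[2] + 1
  c <- x - fm$offset[1] + 1
  r >= 1 && r <= nrow(fm$mask) && c >= 1 && c <= ncol(fm$mask) && fm$mask[r, c]
}

# simple geometric masks in a h x w canvas (0-based coords elsewhere)
rect_mask <- function(h = 30, w = 80, rh = 8, rw = 60) {
  m <- matrix(FALSE, h, w)
  r0 <- (h - rh) %/% 2; c0 <- (w - rw) %/% 2
  m[(r0 + 1):(r0 + rh), (c0 + 1):(c0 + rw)] <- TRUE
  m
}

disk_mask <- function(r = 20, pad = 4) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  d <- outer(seq_len(n) - ctr, seq_len(n) - ctr,
             function(y, x) sqrt(x^2 + y^2))
  d <= r
}

# L-shaped tube: horizontal arm then vertical arm, both 7 px wide
ltube_mask <- function() {
  m <- matrix(FALSE, 70, 70)
  m[30:36, 10:60] <- TRUE
  m[30:60, 54:60] <- TRUE
  m
}

# n points uniformly spaced on a semicircle of radius r (upper half,
# counter-clockwise from (r, 0))
semicircle_points <- function(n = 20, r = 60, n_dense = n) {
  th <- seq(0, pi, length.out = n_dense)
  cbind(x = r * cos(th), y = r * sin(th))
}

# rasterized strip of half-width w around a polyline, as a fish_mask
strip_mask <- function(pts, w = 6, pad = 10) {
  pts <- sweep(pts, 2, apply(pts, 2, min)) + pad
  wdt <- ceiling(max(pts[, 1])) + pad
  hgt <- ceiling(max(pts[, 2])) + pad
  gx <- rep(0:(wdt - 1), times = hgt)
  gy <- rep(0:(hgt - 1), each = wdt)
  d2 <- outer(gx, pts[, 1], "-")^2 + outer(gy, pts[, 2], "-")^2
  hit <- rowSums(d2 <= w^2) > 0
  m <- matrix(FALSE, hgt, wdt)
  m[cbind(gy[hit] + 1, gx[hit] + 1)] <- TRUE
  list(mask = fish_mask(m), points = pts)
}
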