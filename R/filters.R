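# Zero-phase low-pass smoothing. A 4th-order Butterworth is applied forward
# and backward with odd-reflection padding and steady-state initial
# conditions, so DC is preserved exactly and short series (a 20-point body
# profile, a 30-frame cycle) have no start-up transients.

# direct form II transposed IIR filter with initial state zi
lfilter_df2t <- function(b, a, x, zi = NULL) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b))) / a[1]
  a <- c(a, rep(0, nf - length(a))) / a[1]
  z <- if (is.null(zi)) rep(0, nf - 1) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nf > 2) {
      for (j in 1:(nf - 2)) z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
    }
    z[nf - 1] <- b[nf] * xi - a[nf] * yi
    y[i] <- yi
  }
  y
}

# steady-state state vector of the filter for a unit-step input
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b))) / a[1]
  a <- c(a, rep(0, nf - length(a))) / a[1]
  n <- nf - 1
  companion <- matrix(0, n, n)
  companion[1, ] <- -a[2:nf]
  if (n > 1) companion[cbind(2:n, 1:(n - 1))] <- 1
  B <- b[2:nf] - a[2:nf] * b[1]
  solve(diag(n) - t(companion), B)
}

#' Zero-phase low-pass filter a series
#'
#' Butterworth low-pass of the given order applied forward-backward
#' (zero phase), with odd-reflection end padding and steady-state initial
#' conditions. Unity gain at DC: a constant series is returned unchanged.
#'
#' @param x Numeric series.
#' @param cutoff Normalized cutoff frequency in (0, 0.5] (1 = sampling
#'   rate); 0.5 is the Nyquist frequency.
#' @param order Filter order (default 4).
#' @return Filtered series, same length.
#' @export
lowpass_zero_phase <- function(x, cutoff, order = 4) {
  if (cutoff <= 0 || cutoff > 0.5)
    stop("cutoff must be a normalized frequency in (0, 0.5]", call. = FALSE)
  n <- length(x)
  if (n < 2 || stats::var(x) == 0) return(x)
  if (cutoff == 0.5) return(x)  # passband spans the whole spectrum
  bt <- signal::butter(order, cutoff * 2)  # signal uses Nyquist-normalized W
  b <- bt$b; a <- bt$a
  padlen <- min(3 * (max(length(a), length(b)) - 1), n - 1)
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  zi <- lfilter_zi(b, a)
  y <- lfilter_df2t(b, a, ext, zi * ext[1])
  y <- rev(lfilter_df2t(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

#' Spatial smoothing of a curvature matrix
#'
#' Low-pass filters each column (the curvature values along the body within
#' one frame) with a zero-phase Butterworth filter at the configured
#' normalized cutoff.
#'
#' @param C Matrix, body locations x frames.
#' @param cutoff Normalized cutoff in (0, 0.5].
#' @return Matrix of the same dimensions.
#' @export
smooth_spatial <- function(C, cutoff = 0.2) {
  C <- as.matrix(C)
  if (nrow(C) < 5) stop("need at least 5 body locations for spatial smoothing",
                        call. = FALSE)
  apply(C, 2, lowpass_zero_phase, cutoff = cutoff)
}

#' Temporal smoothing of a curvature matrix or series
#'
#' Low-pass filters each row (the time course of curvature at one body
#' location) with a zero-phase Butterworth filter. A plain numeric vector
#' (e.g. the per-frame tail-offset series) is filtered directly.
#'
#' @param C Matrix (body locations x frames) or numeric series.
#' @param cutoff Normalized cutoff in (0, 0.5].
#' @return Same shape as the input.
#' @export
smooth_temporal <- function(C, cutoff = 0.15) {
  if (is.null(dim(C))) return(lowpass_zero_phase(as.numeric(C), cutoff))
  C <- as.matrix(C)
  t(apply(C, 1, lowpass_zero_phase, cutoff = cutoff))
}

#' Fourier magnitude spectrum of a series
#'
#' The one-sided magnitude of the discrete Fourier transform against
#' normalized frequency, the diagnostic used to choose low-pass cutoffs by
#' visual inspection.
#'
#' @param x Numeric series.
#' @return Data frame with `frequency` (cycles/sample, 0 to 0.5) and
#'   `magnitude`.
#' @export
series_spectrum <- function(x) {
  n <- length(x)
  mag <- Mod(fft(x)) / n
  half <- seq_len(floor(n / 2) + 1)
  data.frame(frequency = (half - 1) / n, magnitude = mag[half])
}
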