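# Diagnostic figures: spatio-temporal curvature heatmaps, tail-offset
# profiles, and Fourier-magnitude spectra for cutoff inspection.

#' Heatmap of a spatio-temporal curvature profile
#'
#' Body locations (head at the top) against normalized cycle frames;
#' warmer colours mean larger bending.
#'
#' @param C Curvature matrix, body locations x frames, degrees.
#' @param main Plot title.
#' @export
plot_curvature_profile <- function(C, main = "body curvature profile") {
  C <- as.matrix(C)
  n <- nrow(C); t_len <- ncol(C)
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  image(x = seq_len(t_len), y = seq_len(n), z = t(C[n:1, , drop = FALSE]),
        col = pal, xlab = "normalized cycle frame",
        ylab = "body location (tail ... head)", main = main, useRaster = TRUE)
  invisible(NULL)
}

#' Plot a mean tail-offset profile
#'
#' @param offsets Tail-offset series over the normalized cycle.
#' @param main Plot title.
#' @export
plot_tail_offset_profile <- function(offsets, main = "tail offset profile") {
  plot(seq_along(offsets) - 1, offsets, type = "l", lwd = 2,
       xlab = "normalized cycle frame", ylab = "tail offset T/L", main = main)
  invisible(NULL)
}

#' Plot the Fourier magnitude spectrum of a series
#'
#' The inspection plot used to choose the low-pass cutoffs: magnitude of
#' the discrete Fourier transform against normalized frequency, with the
#' current cutoff marked.
#'
#' @param x Numeric series.
#' @param cutoff Optional normalized cutoff to mark.
#' @param main Plot title.
#' @return Invisibly, the spectrum data frame from [series_spectrum()].
#' @export
plot_series_spectrum <- function(x, cutoff = NULL, main = "magnitude spectrum") {
  sp <- series_spectrum(x)
  plot(sp$frequency, sp$magnitude, type = "h", lwd = 2,
       xlab = "normalized frequency (cycles/sample)", ylab = "|X(f)|",
       main = main)
  if (!is.null(cutoff)) abline(v = cutoff, lty = 2)
  invisible(sp)
}
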