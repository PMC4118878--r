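#' Construct a frame sequence
#'
#' The uniform in-memory video representation: a list of same-sized 8-bit
#' grayscale rasters plus acquisition metadata. Frames are numeric or
#' integer matrices in `[0, 255]`, indexed `frame[row, col]`.
#'
#' @param frames List of matrices, all with identical dimensions.
#' @param frame_rate Frames per second (> 0).
#' @param source_id Free-text identifier of the source.
#' @return A `frame_sequence` object.
#' @export
frame_sequence <- function(frames, frame_rate, source_id = "") {
  if (length(frames) < 1) stop("a frame sequence needs at least one frame", call. = FALSE)
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop("frame_rate must be > 0", call. = FALSE)
  d <- dim(frames[[1]])
  if (is.null(d) || length(d) != 2) stop("frames must be 2-D matrices", call. = FALSE)
  same <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(same)) stop("all frames must share identical dimensions", call. = FALSE)
  structure(
    list(frames = frames, frame_rate = as.numeric(frame_rate),
         width = d[2], height = d[1], source_id = as.character(source_id)),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames, %dx%d px, %.6g fps, source: %s\n",
              length(x$frames), x$width, x$height, x$frame_rate,
              if (nzchar(x$source_id)) x$source_id else "<none>"))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' Duration of a frame sequence in seconds
#'
#' Frame count divided by frame rate; a 4000-frame recording at 250
#' frames/s lasts 16 s.
#'
#' @param seq A `frame_sequence`.
#' @return Duration in seconds.
#' @export
sequence_duration <- function(seq) {
  stopifnot(inherits(seq, "frame_sequence"))
  length(seq$frames) / seq$frame_rate
}

## ITU-R BT.601 luminance; silhouette analysis is colour-invariant by design
rgb_to_gray <- function(arr) {
  0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
}

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  if (length(dim(arr)) == 3) {
    arr <- if (dim(arr)[3] >= 3) rgb_to_gray(arr) else arr[, , 1]
  }
  m <- round(arr * 255)
  storage.mode(m) <- "integer"
  m
}

#' Read a video or numbered image sequence
#'
#' Accepts an uncompressed AVI file, a directory of numbered PNG/TIFF
#' frames, or a glob pattern matching them. Colour input is converted to
#' grayscale by ITU-R BT.601 luminance. Container metadata is untrusted:
#' `expected_rate`, when given, overrides the header frame rate (high-speed
#' cameras often write wrong nominal rates). Image sequences carry no rate
#' metadata; without `expected_rate` the nominal 250 frames/s of the
#' recording setup is assumed, with a message.
#'
#' @param path AVI path, directory, or glob pattern.
#' @param expected_rate Frames per second to impose, or `NULL` to trust the
#'   container.
#' @return A [frame_sequence()].
#' @export
read_video <- function(path, expected_rate = NULL) {
  if (length(path) != 1 || !is.character(path)) stop("path must be a single string", call. = FALSE)
  is_avi <- grepl("\\.avi$", path, ignore.case = TRUE)
  if (is_avi) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    seq <- read_avi(path)
    if (!is.null(expected_rate)) seq$frame_rate <- as.numeric(expected_rate)
    return(seq)
  }
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE, full.names = TRUE)
  } else {
    Sys.glob(path)
  }
  files <- sort(files)
  if (length(files) == 0) stop("no frames found at: ", path, call. = FALSE)
  if (is.null(expected_rate)) {
    message("image sequences carry no frame-rate metadata; assuming 250 frames/s")
    expected_rate <- 250
  }
  frames <- lapply(files, read_one_image)
  frame_sequence(frames, frame_rate = expected_rate, source_id = path)
}

#' Write a frame sequence as numbered PNG files
#'
#' @param seq A `frame_sequence`.
#' @param dir Output directory (created if absent).
#' @param prefix Filename prefix.
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(seq, dir, prefix = "frame") {
  stopifnot(inherits(seq, "frame_sequence"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(seq$frames)
  fmt <- paste0(prefix, "_%0", max(4, nchar(n)), "d.png")
  paths <- file.path(dir, sprintf(fmt, seq_len(n) - 1L))
  for (i in seq_len(n)) {
    png::writePNG(pmin(pmax(seq$frames[[i]], 0), 255) / 255, paths[i])
  }
  invisible(paths)
}

#' Write per-cycle metrics to CSV
#'
#' One row per body-waving cycle with a fixed, deterministic column order:
#' `fish_id, group, cycle_index, max_curvature_deg, min_tail_offset,
#' travel_distance_px`.
#'
#' @param records Data frame of per-cycle metrics (non-empty).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_metrics <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("records must be a non-empty data frame", call. = FALSE)
  cols <- c("fish_id", "group", "cycle_index",
            "max_curvature_deg", "min_tail_offset", "travel_distance_px")
  missing <- setdiff(cols, names(records))
  if (length(missing) > 0)
    stop("records missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  write.csv(records[, cols], path, row.names = FALSE)
  invisible(path)
}
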