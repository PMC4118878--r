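# Minimal RIFF/AVI support for uncompressed 8-bit DIB video, the format the
# high-speed recordings use ("stored in AVI format without applying video
# compression"). Only what the pipeline needs: single 'vids' stream,
# biBitCount = 8 with a grayscale palette, bottom-up rows, 4-byte row stride.

u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
fourcc <- function(s) charToRaw(s)

avi_row_stride <- function(w) ((w + 3L) %/% 4L) * 4L

#' Write a frame sequence as an uncompressed 8-bit AVI
#'
#' Writes a single-stream RIFF AVI with uncompressed palettized 8-bit DIB
#' frames (identity grayscale palette) and a standard `idx1` index. The
#' result round-trips losslessly through [read_avi()].
#'
#' @param seq A [frame_sequence()] with intensities in `[0, 255]`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_avi <- function(seq, path) {
  stopifnot(inherits(seq, "frame_sequence"))
  w <- seq$width; h <- seq$height; n <- length(seq$frames)
  stride <- avi_row_stride(w)
  frame_bytes <- stride * h

  dib_frame <- function(m) {
    m <- pmin(pmax(round(m), 0), 255)
    out <- matrix(as.raw(0), nrow = stride, ncol = h)
    # bottom-up row order
    out[seq_len(w), ] <- as.raw(t(m[h:1, , drop = FALSE]))
    as.vector(out)
  }

  rate_num <- round(seq$frame_rate * 1000)
  avih <- c(
    u32(round(1e6 / seq$frame_rate)),            # dwMicroSecPerFrame
    u32(frame_bytes * round(seq$frame_rate)),    # dwMaxBytesPerSec
    u32(0), u32(0x10),                           # padding, flags (HASINDEX)
    u32(n), u32(0), u32(1),                      # totalframes, initial, streams
    u32(frame_bytes), u32(w), u32(h),
    u32(0), u32(0), u32(0), u32(0)               # reserved
  )
  strh <- c(
    fourcc("vids"), fourcc("DIB "),
    u32(0), u16(0), u16(0), u32(0),
    u32(1000), u32(rate_num),                    # dwScale, dwRate
    u32(0), u32(n), u32(frame_bytes), u32(-1), u32(0),
    u16(0), u16(0), u16(w), u16(h)               # rcFrame
  )
  palette <- as.raw(rbind(0:255, 0:255, 0:255, rep(0, 256)))  # BGR0 quads
  strf <- c(
    u32(40), u32(w), u32(h), u16(1), u16(8),
    u32(0),                                      # BI_RGB
    u32(frame_bytes), u32(0), u32(0), u32(256), u32(0),
    palette
  )
  wrap <- function(id, payload) c(fourcc(id), u32(length(payload)), payload,
                                  if (length(payload) %% 2 == 1) as.raw(0))
  wrap_list <- function(type, payload) wrap("LIST", c(fourcc(type), payload))

  strl <- wrap_list("strl", c(wrap("strh", strh), wrap("strf", strf)))
  hdrl <- wrap_list("hdrl", c(wrap("avih", avih), strl))

  chunks <- lapply(seq$frames, function(m) wrap("00db", dib_frame(m)))
  movi_payload <- do.call(c, chunks)
  movi <- wrap_list("movi", movi_payload)

  # idx1: offsets are relative to the start of the 'movi' fourcc
  idx <- raw(0)
  off <- 4L
  for (i in seq_len(n)) {
    idx <- c(idx, fourcc("00db"), u32(0x10), u32(off), u32(frame_bytes))
    off <- off + 8L + frame_bytes + (frame_bytes %% 2L)
  }
  idx1 <- wrap("idx1", idx)

  body <- c(fourcc("AVI "), hdrl, movi, idx1)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(fourcc("RIFF"), con)
  writeBin(length(body), con, size = 4, endian = "little")
  writeBin(body, con)
  invisible(path)
}

read_u32 <- function(r, at) {
  v <- as.numeric(r[at]) + 256 * as.numeric(r[at + 1]) +
    65536 * as.numeric(r[at + 2]) + 16777216 * as.numeric(r[at + 3])
  v
}

#' Read an uncompressed 8-bit AVI file
#'
#' Parses the RIFF structure, takes the frame rate from the first video
#' stream header (`dwRate / dwScale`), and decodes `00db`/`00dc` chunks as
#' bottom-up 8-bit DIB rasters through the embedded palette. Compressed
#' streams are rejected.
#'
#' @param path AVI file path.
#' @return A [frame_sequence()].
#' @export
read_avi <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 12 || rawToChar(r[1:4]) != "RIFF" || rawToChar(r[9:12]) != "AVI ")
    stop("not an AVI (RIFF) file: ", path, call. = FALSE)

  state <- new.env(parent = emptyenv())
  state$avih <- NULL; state$strh <- NULL; state$strf <- NULL
  state$frames_raw <- list()

  walk <- function(pos, end) {
    while (pos + 8 <= end + 1) {
      id <- rawToChar(r[pos:(pos + 3)])
      size <- read_u32(r, pos + 4)
      data_start <- pos + 8
      if (id == "LIST" || id == "RIFF") {
        walk(data_start + 4, data_start + size - 1)
      } else if (id == "avih" && is.null(state$avih)) {
        state$avih <- r[data_start:(data_start + size - 1)]
      } else if (id == "strh" && is.null(state$strh)) {
        state$strh <- r[data_start:(data_start + size - 1)]
      } else if (id == "strf" && is.null(state$strf)) {
        state$strf <- r[data_start:(data_start + size - 1)]
      } else if (grepl("^..d[bc]$", id)) {
        state$frames_raw[[length(state$frames_raw) + 1L]] <-
          r[data_start:(data_start + size - 1)]
      }
      pos <- data_start + size + (size %% 2)
    }
  }
  walk(13, length(r))

  if (is.null(state$avih) || is.null(state$strf))
    stop("malformed AVI: missing headers", call. = FALSE)
  if (length(state$frames_raw) == 0) stop("AVI contains zero frames", call. = FALSE)

  w <- read_u32(state$strf, 5); h <- read_u32(state$strf, 9)
  bitcount <- as.numeric(state$strf[15]) + 256 * as.numeric(state$strf[16])
  compression <- read_u32(state$strf, 17)
  if (compression != 0 || bitcount != 8)
    stop("only uncompressed 8-bit AVI is supported (got biBitCount=",
         bitcount, ", biCompression=", compression, ")", call. = FALSE)
  palette_gray <- as.integer(state$strf[seq(41, by = 4, length.out = 256) + 1])

  rate <- NULL
  if (!is.null(state$strh) && rawToChar(state$strh[1:4]) == "vids") {
    scale <- read_u32(state$strh, 21); num <- read_u32(state$strh, 25)
    if (scale > 0 && num > 0) rate <- num / scale
  }
  if (is.null(rate)) {
    mspf <- read_u32(state$avih, 1)
    if (mspf > 0) rate <- 1e6 / mspf
  }
  if (is.null(rate) || rate <= 0) stop("AVI frame rate missing", call. = FALSE)

  stride <- avi_row_stride(w)
  frames <- lapply(state$frames_raw, function(buf) {
    if (length(buf) < stride * h) stop("truncated AVI frame chunk", call. = FALSE)
    m <- matrix(as.integer(buf[seq_len(stride * h)]), nrow = stride)[seq_len(w), , drop = FALSE]
    out <- matrix(palette_gray[t(m) + 1L], nrow = h, ncol = w)[h:1, , drop = FALSE]
    storage.mode(out) <- "integer"
    out
  })
  frame_sequence(frames, frame_rate = rate, source_id = path)
}
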