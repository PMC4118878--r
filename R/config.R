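#' Analysis run configuration
#'
#' Bundles every tunable of the pipeline with validated defaults. Values are
#' chosen for dark fish on a lighter, nearly static tank background recorded
#' at high frame rate (nominally 250 frames/s, 480x640 px).
#'
#' @param threshold Segmentation threshold on the absolute difference between
#'   a frame and the median background, in 8-bit intensity units.
#' @param min_area Minimum connected-component area (pixels) considered a
#'   fish candidate.
#' @param spatial_cutoff,temporal_cutoff Normalized low-pass cutoff
#'   frequencies in (0, 0.5] (1 = sampling rate) for smoothing curvature
#'   along the body (columns) and over time (rows), respectively.
#' @param cycle_length Number of frames every body-waving cycle is
#'   normalized to (30 in the reference analysis).
#' @param n_points Number of midline control points (20 in the posture
#'   model).
#' @param alpha Significance level of the group comparisons.
#' @param seed Integer seed for all randomness in a run.
#' @param travel_mode `"path"` sums per-frame centroid displacements
#'   (default); `"net"` uses start-to-end displacement.
#' @param equal_variance Use the classical pooled-variance Student t test
#'   (default); `FALSE` selects Welch.
#' @param per_fish_averaging Average cycle metrics within fish before group
#'   statistics instead of pooling all cycles (default pools cycles).
#' @param auto_prominence Minimum prominence of tail-offset maxima (ratio
#'   units) used by automatic cycle detection; about a quarter of the
#'   straight-to-bent excursion of a moderate swimmer, and well above the
#'   post-smoothing noise ripple.
#'
#' @return An object of class `swim_config` (a validated named list).
#' @examples
#' cfg <- run_config()
#' cfg$n_points
#' @export
run_config <- function(threshold = 25,
                       min_area = 100,
                       spatial_cutoff = 0.2,
                       temporal_cutoff = 0.15,
                       cycle_length = 30,
                       n_points = 20,
                       alpha = 0.05,
                       seed = 1L,
                       travel_mode = c("path", "net"),
                       equal_variance = TRUE,
                       per_fish_averaging = FALSE,
                       auto_prominence = 0.005) {
  travel_mode <- match.arg(travel_mode)
  cfg <- list(
    threshold = as.numeric(threshold),
    min_area = as.numeric(min_area),
    spatial_cutoff = as.numeric(spatial_cutoff),
    temporal_cutoff = as.numeric(temporal_cutoff),
    cycle_length = as.integer(cycle_length),
    n_points = as.integer(n_points),
    alpha = as.numeric(alpha),
    seed = as.integer(seed),
    travel_mode = travel_mode,
    equal_variance = isTRUE(equal_variance),
    per_fish_averaging = isTRUE(per_fish_averaging),
    auto_prominence = as.numeric(auto_prominence)
  )
  validate_config(cfg)
  class(cfg) <- "swim_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$threshold > 0, cfg$min_area >= 1)
  if (cfg$spatial_cutoff <= 0 || cfg$spatial_cutoff > 0.5)
    stop("spatial_cutoff must be in (0, 0.5]", call. = FALSE)
  if (cfg$temporal_cutoff <= 0 || cfg$temporal_cutoff > 0.5)
    stop("temporal_cutoff must be in (0, 0.5]", call. = FALSE)
  if (cfg$cycle_length < 2) stop("cycle_length must be >= 2", call. = FALSE)
  if (cfg$n_points < 3) stop("n_points must be >= 3", call. = FALSE)
  stopifnot(cfg$alpha > 0, cfg$alpha < 1)
  invisible(cfg)
}

#' @export
print.swim_config <- function(x, ...) {
  cat("<swim_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Unknown keys are
#' an error so typos fail loudly. Missing keys keep their defaults.
#'
#' @param path Path to the config file.
#' @return A `swim_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defaults <- run_config()
  vals <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(unclass(defaults)))
      stop("unknown config key: ", key, call. = FALSE)
    vals[[key]] <- val
  }
  args <- unclass(defaults)
  for (key in names(vals)) {
    args[[key]] <- switch(key,
      travel_mode = vals[[key]],
      equal_variance = ,
      per_fish_averaging = as.logical(vals[[key]]),
      cycle_length = ,
      n_points = ,
      seed = as.integer(vals[[key]]),
      as.numeric(vals[[key]])
    )
  }
  do.call(run_config, args)
}
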