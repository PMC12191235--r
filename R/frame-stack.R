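#' Multi-channel image frame
#'
#' A `frame_stack` holds one field of view at one timepoint: a named list of
#' equally sized 2-D intensity matrices (one per fluorescence channel) plus
#' acquisition metadata. Channel names follow the reporter conventions of the
#' GEDI / 53BP1 assays: `"red"` (mApple), `"green"` (GC150 or gamma-H2AX) and
#' `"blue"` (DAPI).
#'
#' @param channels Named list of numeric matrices, all the same dimension,
#'   finite and non-negative.
#' @param timepoint Acquisition time in hours post-irradiation.
#' @param fov Field-of-view identifier.
#' @param pixel_size Optional pixel edge length in micrometres.
#'
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(channels, timepoint = NA_real_, fov = "fov1",
                        pixel_size = NA_real_) {
  if (!is.list(channels) || length(channels) == 0 ||
      is.null(names(channels)) || any(names(channels) == "")) {
    abort("`channels` must be a non-empty named list of matrices")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1)))) {
    abort("every channel must be a matrix")
  }
  if (length(unique(lapply(dims, identity))) != 1) {
    abort("all channels must have identical dimensions")
  }
  for (nm in names(channels)) check_image(channels[[nm]], nm)
  if (any(vapply(channels, function(m) any(m < 0), logical(1)))) {
    abort("channel intensities must be non-negative")
  }
  structure(
    list(
      channels = channels,
      timepoint = as.numeric(timepoint),
      fov = as.character(fov),
      pixel_size = as.numeric(pixel_size)
    ),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "<frame_stack> %d x %d px, channels: %s, t = %s h, fov = %s\n",
    d[1], d[2], paste(names(x$channels), collapse = "/"),
    format(x$timepoint), x$fov
  ))
  invisible(x)
}

#' Extract a channel matrix from a frame
#'
#' @param frame A [frame_stack()].
#' @param channel Channel name.
#' @return Numeric matrix.
#' @export
get_channel <- function(frame, channel) {
  stopifnot(inherits(frame, "frame_stack"))
  if (!channel %in% names(frame$channels)) {
    abort(sprintf(
      "channel '%s' not present (have: %s)",
      channel, paste(names(frame$channels), collapse = ", ")
    ))
  }
  frame$channels[[channel]]
}

# Intensity scale used when serialising to TIFF: pixel values are divided by
# this before writing (TIFF pages store [0, 1]) and multiplied back on read.
.tiff_scale_default <- 65536

#' Write a time-lapse series as a multi-page TIFF
#'
#' Pages are ordered timepoint-major, then channel, matching the acquisition
#' order of a plate imager. Channel names, timepoints, field id, pixel size
#' and the intensity scale are recorded in a JSON sidecar (`<path>.json`) so
#' the series round-trips through [read_timelapse_tiff()].
#'
#' @param frames List of [frame_stack()] objects (one per timepoint, same
#'   channels in the same order).
#' @param path Output TIFF path.
#' @param scale Intensity scale: pixel values are stored as `value / scale`.
#' @return `path`, invisibly.
#' @export
write_timelapse_tiff <- function(frames, path, scale = .tiff_scale_default) {
  stopifnot(is.list(frames), length(frames) > 0)
  ch_names <- names(frames[[1]]$channels)
  pages <- list()
  for (fr in frames) {
    stopifnot(inherits(fr, "frame_stack"))
    if (!identical(names(fr$channels), ch_names)) {
      abort("all frames must share the same channel set and order")
    }
    for (nm in ch_names) {
      pages[[length(pages) + 1L]] <- pmin(fr$channels[[nm]] / scale, 1)
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    channels = ch_names,
    timepoints = vapply(frames, function(f) f$timepoint, numeric(1)),
    fov = frames[[1]]$fov,
    scale = scale
  )
  if (is.finite(frames[[1]]$pixel_size)) {
    meta$pixel_size <- frames[[1]]$pixel_size
  }
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a time-lapse series written by [write_timelapse_tiff()]
#'
#' @param path TIFF path (the `<path>.json` sidecar must be present).
#' @return List of [frame_stack()] objects, one per timepoint.
#' @export
read_timelapse_tiff <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) {
    abort(sprintf("metadata sidecar not found: %s", meta_path))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  n_ch <- length(meta$channels)
  n_t <- length(meta$timepoints)
  if (length(pages) != n_ch * n_t) {
    abort("page count does not match sidecar channels x timepoints")
  }
  lapply(seq_len(n_t), function(ti) {
    ch <- lapply(seq_len(n_ch), function(ci) {
      pages[[(ti - 1L) * n_ch + ci]] * meta$scale
    })
    names(ch) <- meta$channels
    frame_stack(ch,
      timepoint = meta$timepoints[ti],
      fov = meta$fov,
      pixel_size = meta$pixel_size %||% NA_real_
    )
  })
}
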