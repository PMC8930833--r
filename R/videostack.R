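#' Time-lapse video stack
#'
#' Container for one channel of an episodic two-photon recording: an 8-bit
#' intensity array (height x width x frames), per-frame timestamps in
#' seconds, the frame index at which the pressure pulse was delivered, and
#' optional pixel size.
#'
#' @param frames Numeric array `height x width x n_frames` with values in
#'   \[0, 255\].
#' @param timestamps Numeric vector of frame times in seconds, strictly
#'   increasing. Alternatively supply `frame_rate`.
#' @param frame_rate Frames per second; used to build timestamps starting at
#'   0 when `timestamps` is missing.
#' @param channel Channel label, e.g. `"green"` (lumen dye) or `"red"`
#'   (pipette dye).
#' @param pulse_frame Index (1-based) of the pressure-pulse frame.
#' @param pixel_size Optional pixel size in micrometres per pixel.
#' @return An object of class `VideoStack`.
#' @export
video_stack <- function(frames, timestamps = NULL, frame_rate = NULL,
                        channel = "green", pulse_frame = 1L,
                        pixel_size = NULL) {
  if (length(dim(frames)) != 3) stopf("frames must be a 3-d array")
  nf <- dim(frames)[3]
  if (is.null(timestamps)) {
    if (is.null(frame_rate)) stopf("supply timestamps or frame_rate")
    timestamps <- (seq_len(nf) - 1) / frame_rate
  }
  if (length(timestamps) != nf) stopf("timestamps length != frame count")
  if (any(diff(timestamps) <= 0)) stopf("timestamps must be strictly increasing")
  if (pulse_frame < 1 || pulse_frame > nf) stopf("pulse_frame out of range")
  rng <- range(frames)
  if (rng[1] < 0 || rng[2] > 255) stopf("frame values must lie in [0, 255]")
  structure(
    list(frames = frames, timestamps = as.numeric(timestamps),
         channel = channel, pulse_frame = as.integer(pulse_frame),
         pixel_size = pixel_size),
    class = "VideoStack"
  )
}

#' @export
print.VideoStack <- function(x, ...) {
  d <- dim(x$frames)
  fr <- 1 / stats::median(diff(x$timestamps))
  cat(sprintf(
    "VideoStack [%s]: %d x %d px, %d frames (~%.1f Hz), pulse at frame %d (t = %.2f s)\n",
    x$channel, d[1], d[2], d[3], fr, x$pulse_frame,
    x$timestamps[x$pulse_frame]))
  invisible(x)
}

#' @export
dim.VideoStack <- function(x) dim(x$frames)

n_frames <- function(stack) dim(stack$frames)[3]

frame_rate_of <- function(stack) 1 / stats::median(diff(stack$timestamps))

#' Write a video stack as multi-page TIFF plus a metadata sidecar
#'
#' The image data go to `<path>.tif` (8-bit, one page per frame) and the
#' acquisition metadata (channel, pulse frame, timestamps, pixel size) to
#' `<path>.yaml`.
#'
#' @param stack A [video_stack()].
#' @param path Output path without extension.
#' @return Invisibly, the TIFF path.
#' @export
write_video <- function(stack, path) {
  pages <- lapply(seq_len(n_frames(stack)),
                  function(i) stack$frames[, , i] / 255)
  tif <- paste0(path, ".tif")
  tiff::writeTIFF(pages, tif, bits.per.sample = 8L)
  meta <- list(channel = stack$channel,
               pulse_frame = stack$pulse_frame,
               pixel_size = stack$pixel_size,
               timestamps = stack$timestamps)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(tif)
}

#' Read a video stack written by [write_video()]
#'
#' @param path Path without extension (expects `<path>.tif` and
#'   `<path>.yaml`).
#' @return A [video_stack()].
#' @export
read_video <- function(path) {
  pages <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  frames <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    frames[, , i] <- round(p * 255)
  }
  video_stack(frames, timestamps = unlist(meta$timestamps),
              channel = meta$channel, pulse_frame = meta$pulse_frame,
              pixel_size = meta$pixel_size)
}
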