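#' Standardize a video to the pipeline's reference geometry
#'
#' Resamples a recording to a fixed size: spatially by bilinear
#' interpolation, temporally by non-overlapping block averaging when
#' downsampling and by linear interpolation when upsampling. The reference
#' geometry defaults to 544 x 336 pixels by 1400 frames, and output values
#' are re-quantized to 8 bits. A stack already at the target geometry is
#' returned value-identical.
#'
#' @param raw A [video_stack()] with at least 2 frames.
#' @param width,height Target frame size in pixels.
#' @param depth Target frame count.
#' @return A standardized [video_stack()] with resampled timestamps and a
#'   remapped pulse frame.
#' @export
standardize_video <- function(raw, width = 544, height = 336, depth = 1400) {
  stopifnot(inherits(raw, "VideoStack"))
  d <- dim(raw$frames)
  if (d[3] < 2) stopf("empty or single-frame stack cannot be standardized")
  pulse_time <- raw$timestamps[raw$pulse_frame]

  frames <- raw$frames
  ts <- raw$timestamps
  n_in <- d[3]
  if (n_in > depth) {
    # non-overlapping block average ("Average" reduction)
    block <- floor((seq_len(n_in) - 1) * depth / n_in) + 1L
    out <- array(0, c(d[1], d[2], depth))
    ts_out <- numeric(depth)
    for (b in seq_len(depth)) {
      idx <- which(block == b)
      out[, , b] <- if (length(idx) == 1) frames[, , idx] else
        rowMeans(frames[, , idx, drop = FALSE], dims = 2)
      ts_out[b] <- mean(ts[idx])
    }
    frames <- out; ts <- ts_out
  } else if (n_in < depth) {
    # linear interpolation in time
    ts_out <- seq(ts[1], ts[n_in], length.out = depth)
    lo <- findInterval(ts_out, ts, rightmost.closed = TRUE)
    lo[lo < 1] <- 1L; lo[lo >= n_in] <- n_in - 1L
    wgt <- (ts_out - ts[lo]) / (ts[lo + 1] - ts[lo])
    out <- array(0, c(d[1], d[2], depth))
    for (b in seq_len(depth)) {
      out[, , b] <- (1 - wgt[b]) * frames[, , lo[b]] + wgt[b] * frames[, , lo[b] + 1]
    }
    frames <- out; ts <- ts_out
  }

  if (d[1] != height || d[2] != width) {
    out <- array(0, c(height, width, dim(frames)[3]))
    for (i in seq_len(dim(frames)[3])) {
      out[, , i] <- EBImage::resize(frames[, , i], w = height, h = width)
    }
    frames <- out
  }
  frames <- quantize8(frames)
  pulse_frame <- which.min(abs(ts - pulse_time))
  video_stack(frames, timestamps = ts, channel = raw$channel,
              pulse_frame = pulse_frame, pixel_size = raw$pixel_size)
}
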