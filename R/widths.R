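# Width readouts: mixture-binarized per-frame width, the pilot FWHM
# profile readout, and 1-s binning with baseline normalization.

#' Per-frame vessel width from a binarized kymograph
#'
#' Binarizes each non-excluded line profile at the mixture threshold; the
#' width is the extent of the longest contiguous foreground run (robust to
#' speckle), with the run boundaries refined to sub-pixel positions by
#' linear interpolation of the threshold crossing, which removes the
#' 1-sample discretization bias of a raw run count. Frames with no
#' foreground, and excluded frames, are returned as `NA`.
#'
#' @param kymo A `Kymograph` (typically after [smooth_kymograph()]).
#' @param fit A [fit_intensity_mixture()] result (or a numeric threshold).
#' @return Numeric vector of widths in pixels, one per frame.
#' @export
width_per_frame <- function(kymo, fit) {
  stopifnot(inherits(kymo, "Kymograph"))
  thr <- if (inherits(fit, "MixtureFit")) fit$threshold else as.numeric(fit)
  nf <- ncol(kymo$grid)
  widths <- rep(NA_real_, nf)
  for (j in seq_len(nf)) {
    if (kymo$excluded[j]) next
    p <- kymo$grid[, j]
    fg <- p >= thr
    if (!any(fg)) next
    r <- rle(fg)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    s <- starts[best]; e <- ends[best]
    left <- if (s > 1) {
      s - 1 + (thr - p[s - 1]) / (p[s] - p[s - 1])
    } else s - 0.5
    right <- if (e < length(p)) {
      e + (p[e] - thr) / (p[e] - p[e + 1])
    } else e + 0.5
    widths[j] <- right - left
  }
  widths
}

#' Full-width-at-half-maximum of a line profile
#'
#' Width between the two half-maximum crossings around the global maximum,
#' with linear sub-pixel interpolation. The profile baseline is the mean of
#' the first and last 10 percent of samples.
#'
#' @param profile Numeric intensity profile along the scan line.
#' @return Width in pixels, or `NA` if a crossing is missing on either side.
#' @export
fwhm_width <- function(profile) {
  n <- length(profile)
  if (n < 5) return(NA_real_)
  ntail <- max(1L, ceiling(0.1 * n))
  base <- mean(c(profile[seq_len(ntail)], profile[(n - ntail + 1):n]))
  imax <- which.max(profile)
  pk <- profile[imax]
  if (pk <= base) return(NA_real_)
  half <- (pk + base) / 2
  left <- NA_real_
  for (i in rev(seq_len(imax - 1))) {
    if (profile[i] < half) {
      left <- i + (half - profile[i]) / (profile[i + 1] - profile[i])
      break
    }
  }
  right <- NA_real_
  if (imax < n) {
    for (i in (imax + 1):n) {
      if (profile[i] < half) {
        right <- i - 1 + (profile[i - 1] - half) / (profile[i - 1] - profile[i])
        break
      }
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  right - left
}

#' Bin widths per second and normalize to the pre-pulse baseline
#'
#' Averages the raw width series into non-overlapping 1-s bins whose edges
#' are anchored at the pulse time (so the 3 s before the pulse are exactly 3
#' whole bins), takes the baseline width `w0` as the mean of the 3 bins
#' immediately pre-pulse, and expresses every bin as percent change,
#' `100 * (w - w0) / w0`. Bins with no retained frames are missing.
#'
#' @param widths Raw per-frame widths in pixels (`NA` = missing).
#' @param timestamps Frame times in seconds.
#' @param pulse_time Pulse time in seconds; needs >= 3 s of pre-pulse data.
#' @return A `WidthTrace`: `bin_time` (bin centers, s), `pct` (percent
#'   change), `missing` (logical), `w0` (baseline width, px), `pulse_time`.
#' @export
bin_and_normalize <- function(widths, timestamps, pulse_time) {
  stopifnot(length(widths) == length(timestamps))
  if (timestamps[1] > pulse_time - 3)
    stopf("need >= 3 s of pre-pulse data")
  k <- floor(timestamps - pulse_time)  # bin index: [pulse + k, pulse + k + 1)
  kk <- seq(min(k), max(k))
  means <- vapply(kk, function(b) {
    v <- widths[k == b]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  base_idx <- match(c(-3, -2, -1), kk)
  base_vals <- means[base_idx]
  if (all(is.na(base_vals))) stopf("all baseline bins missing")
  w0 <- mean(base_vals, na.rm = TRUE)
  if (!is.finite(w0) || w0 <= 0) stopf("non-positive baseline width")
  structure(
    list(bin_time = pulse_time + kk + 0.5,
         pct = 100 * (means - w0) / w0,
         missing = is.na(means),
         w0 = w0, pulse_time = pulse_time),
    class = "WidthTrace"
  )
}

#' @export
print.WidthTrace <- function(x, ...) {
  cat(sprintf(
    "WidthTrace: %d 1-s bins (%d missing), baseline %.2f px, pulse at %.1f s\n",
    length(x$pct), sum(x$missing), x$w0, x$pulse_time))
  invisible(x)
}

#' Write a width trace as tidy CSV
#'
#' @param trace A `WidthTrace`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_width_trace <- function(trace, path) {
  utils::write.csv(
    data.frame(bin_time_s = trace$bin_time, pct_change = trace$pct,
               missing = trace$missing, w0_px = trace$w0,
               pulse_time_s = trace$pulse_time),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a width trace written by [write_width_trace()]
#'
#' @param path CSV path.
#' @return A `WidthTrace`.
#' @export
read_width_trace <- function(path) {
  d <- utils::read.csv(path)
  structure(
    list(bin_time = d$bin_time_s, pct = d$pct_change,
         missing = as.logical(d$missing), w0 = d$w0_px[1],
         pulse_time = d$pulse_time_s[1]),
    class = "WidthTrace"
  )
}
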