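# Dilation-peak detection and metrics on normalized width traces. Baseline
# is zero and only dilations (positive excursions) are quantified.

# Split post-pulse bins into segments separated by gaps of >= 2 missing
# bins; bridge single missing bins by linear interpolation.
post_pulse_segments <- function(trace) {
  post <- which(trace$bin_time > trace$pulse_time)
  x <- trace$bin_time[post]
  y <- trace$pct[post]
  miss <- trace$missing[post]
  # bridge isolated missing bins
  for (i in which(miss)) {
    if (i > 1 && i < length(y) && !miss[i - 1] && !miss[i + 1]) {
      y[i] <- (y[i - 1] + y[i + 1]) / 2
      miss[i] <- FALSE
    }
  }
  ok <- !miss
  if (!any(ok)) return(list())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  segs <- list()
  for (j in which(r$values)) {
    idx <- starts[j]:ends[j]
    segs[[length(segs) + 1]] <- list(x = x[idx], y = y[idx])
  }
  segs
}

# Positive excursions of a piecewise-linear segment: exact zero-crossing
# start/end and trapezoid area above zero.
segment_peaks <- function(x, y) {
  n <- length(x)
  peaks <- list()
  if (n == 0) return(peaks)
  pos <- y > 0
  if (!any(pos)) return(peaks)
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (j in which(r$values)) {
    i1 <- starts[j]; i2 <- ends[j]
    # start: zero crossing between i1-1 and i1 (or the segment edge)
    if (i1 > 1) {
      x0 <- x[i1 - 1] + (0 - y[i1 - 1]) * (x[i1] - x[i1 - 1]) / (y[i1] - y[i1 - 1])
      y_start <- 0
    } else {
      x0 <- x[i1]; y_start <- y[i1]
    }
    if (i2 < n) {
      x1 <- x[i2] + (0 - y[i2]) * (x[i2 + 1] - x[i2]) / (y[i2 + 1] - y[i2])
      y_end <- 0
    } else {
      x1 <- x[i2]; y_end <- y[i2]
    }
    xx <- c(x0, x[i1:i2], x1)
    yy <- c(y_start, y[i1:i2], y_end)
    keep <- !duplicated(xx)
    xx <- xx[keep]; yy <- yy[keep]
    auc <- sum(diff(xx) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
    imax <- which.max(yy)
    peaks[[length(peaks) + 1]] <- structure(
      list(start = x0, end = x1, t_max = xx[imax], max_change = max(yy),
           auc = auc),
      class = "Peak")
  }
  peaks
}

#' Detect dilation peaks on a width trace
#'
#' Peaks are maximal contiguous runs of post-pulse bins above zero, merged
#' across single missing bins (linear interpolation); gaps of two or more
#' missing bins split the trace. Start and end are placed at the linear
#' zero-crossings, area is the exact trapezoid integral above zero, and
#' peaks whose maximum falls below `min_peak_frac` of the trace's global
#' maximum above zero are discarded (minimum-height filter; 0 disables).
#'
#' @param trace A [bin_and_normalize()] result.
#' @param min_peak_frac Minimum peak height as a fraction of the global
#'   maximum above zero.
#' @return List of `Peak`s (`start`, `end`, `t_max`, `max_change`, `auc`);
#'   empty if there is no positive excursion.
#' @export
detect_peaks <- function(trace, min_peak_frac = 0.1) {
  stopifnot(inherits(trace, "WidthTrace"))
  segs <- post_pulse_segments(trace)
  peaks <- list()
  for (s in segs) peaks <- c(peaks, segment_peaks(s$x, s$y))
  if (length(peaks) == 0 || min_peak_frac <= 0) return(peaks)
  gmax <- max(vapply(peaks, `[[`, numeric(1), "max_change"))
  Filter(function(p) p$max_change >= min_peak_frac * gmax, peaks)
}

#' Largest peak by area
#'
#' @param peaks List of `Peak`s from [detect_peaks()].
#' @return The peak with maximal AUC (ties broken by earlier start), or
#'   `NULL` for an empty list.
#' @export
largest_peak <- function(peaks) {
  if (length(peaks) == 0) return(NULL)
  aucs <- vapply(peaks, `[[`, numeric(1), "auc")
  starts <- vapply(peaks, `[[`, numeric(1), "start")
  best <- which(aucs == max(aucs))
  peaks[[best[which.min(starts[best])]]]
}

#' Percent flow change implied by a percent diameter change
#'
#' Under laminar (Poiseuille) flow, volumetric flow scales with the fourth
#' power of vessel radius, so a percent diameter change `d` maps to a flow
#' change of `100 * ((1 + d/100)^4 - 1)` percent.
#'
#' @param pct_diameter_change Percent diameter change (> -100); vectorized.
#' @return Percent flow change.
#' @export
poiseuille_flow_change <- function(pct_diameter_change) {
  if (any(pct_diameter_change <= -100))
    stopf("percent diameter change must exceed -100")
  100 * ((1 + pct_diameter_change / 100)^4 - 1)
}

# Post-pulse data-quality summaries used by the QC rules: seconds of
# retained data, longest missing gap (seconds), and trace maximum.
trace_quality <- function(trace) {
  post <- which(trace$bin_time > trace$pulse_time)
  miss <- trace$missing[post]
  gap <- if (any(miss)) {
    r <- rle(miss)
    max(r$lengths[r$values])
  } else 0L
  list(coverage_s = sum(!miss), max_gap_s = as.numeric(gap),
       trace_max = if (all(miss)) NA_real_ else
         max(trace$pct[post][!miss]))
}
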