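#' Build a kymograph for one scan line
#'
#' For every frame, samples the intensity by bilinear interpolation at
#' unit-spaced positions along the line and assembles the position-by-time
#' grid. Samples falling outside the frame are clipped to the border (with a
#' warning).
#'
#' @param stack A [video_stack()].
#' @param line A `ScanLine` from [place_scan_lines()].
#' @return A `Kymograph`: list with `grid` (positions x frames), `line_id`,
#'   `excluded` (per-frame logical mask, initially all `FALSE`),
#'   `timestamps` and `pulse_frame`.
#' @export
build_kymograph <- function(stack, line) {
  stopifnot(inherits(stack, "VideoStack"))
  h <- dim(stack$frames)[1]; w <- dim(stack$frames)[2]
  d <- line$p2 - line$p1
  len <- sqrt(sum(d^2))
  npos <- max(2L, floor(len / line$spacing) + 1L)
  u <- (seq_len(npos) - 1) * line$spacing / len
  xs <- line$p1[1] + u * d[1]
  ys <- line$p1[2] + u * d[2]
  if (any(xs < 1 | xs > w | ys < 1 | ys > h)) {
    warnf("scan line exits the frame; samples clipped to the border")
    xs <- pmin(pmax(xs, 1), w)
    ys <- pmin(pmax(ys, 1), h)
  }
  x0 <- pmin(floor(xs), w - 1); y0 <- pmin(floor(ys), h - 1)
  fx <- xs - x0; fy <- ys - y0
  ww <- cbind((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  flat <- matrix(stack$frames, nrow = h * w)
  idx <- cbind(y0 + (x0 - 1) * h, y0 + x0 * h,
               y0 + 1 + (x0 - 1) * h, y0 + 1 + x0 * h)
  grid <- ww[, 1] * flat[idx[, 1], , drop = FALSE] +
    ww[, 2] * flat[idx[, 2], , drop = FALSE] +
    ww[, 3] * flat[idx[, 3], , drop = FALSE] +
    ww[, 4] * flat[idx[, 4], , drop = FALSE]
  structure(
    list(grid = grid, line_id = line$index,
         excluded = rep(FALSE, dim(stack$frames)[3]),
         timestamps = stack$timestamps, pulse_frame = stack$pulse_frame),
    class = "Kymograph"
  )
}

#' Mark excluded frames on a kymograph
#'
#' @param kymo A [build_kymograph()] result.
#' @param excluded Logical per-frame mask (e.g. from
#'   [flag_artifact_frames()]).
#' @return The kymograph with its exclusion mask set.
#' @export
set_excluded_frames <- function(kymo, excluded) {
  stopifnot(inherits(kymo, "Kymograph"),
            length(excluded) == ncol(kymo$grid))
  kymo$excluded <- as.logical(excluded)
  kymo
}

#' Spatial mean filter on a kymograph
#'
#' Box-mean filter over the position x time grid with edge replication.
#' Excluded frames neither contribute to nor receive smoothing: their
#' columns are left untouched and remain masked.
#'
#' @param kymo A [build_kymograph()] result.
#' @param kernel Kernel size as `c(positions, frames)`; both odd.
#' @return The smoothed kymograph.
#' @export
smooth_kymograph <- function(kymo, kernel = c(3, 3)) {
  stopifnot(inherits(kymo, "Kymograph"))
  if (any(kernel %% 2 == 0)) stopf("kernel must be odd in both dimensions")
  if (kernel[1] > nrow(kymo$grid) || kernel[2] > ncol(kymo$grid))
    stopf("kernel larger than the kymograph grid")
  a <- (kernel[1] - 1) / 2
  b <- (kernel[2] - 1) / 2
  g <- kymo$grid
  valid <- matrix(rep(!kymo$excluded, each = nrow(g)), nrow = nrow(g))
  num <- matrix(0, nrow(g), ncol(g))
  den <- matrix(0, nrow(g), ncol(g))
  for (di in -a:a) {
    for (dj in -b:b) {
      num <- num + shift_mat(g * valid, di, dj)
      den <- den + shift_mat(valid * 1, di, dj)
    }
  }
  sm <- num / pmax(den, 1e-12)
  sm[, kymo$excluded] <- g[, kymo$excluded]
  kymo$grid <- sm
  kymo
}
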