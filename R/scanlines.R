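# Scan-line placement: up to 8 lines perpendicular to the smoothed
# centerline tangent, at equally spaced stations along its central span.

# Nearest-pixel lookup of a mask at real coordinates (x, y); FALSE outside.
mask_at <- function(mask, x, y) {
  r <- round(y); c <- round(x)
  ok <- r >= 1 & r <= nrow(mask) & c >= 1 & c <= ncol(mask)
  out <- logical(length(x))
  out[ok] <- mask[cbind(r[ok], c[ok])]
  out
}

# Width of the mask's foreground run containing `pt`, measured along the
# unit direction `nrm` at unit sample spacing.
local_mask_width <- function(mask, pt, nrm, max_reach = 200) {
  count <- 1L
  for (s in c(1, -1)) {
    for (k in seq_len(max_reach)) {
      p <- pt + s * k * nrm
      if (!mask_at(mask, p[1], p[2])) break
      count <- count + 1L
    }
  }
  count
}

#' Place scan lines perpendicular to the centerline
#'
#' Places up to `n_max` lines at equally spaced stations along the central
#' portion of the centerline, each perpendicular to the local smoothed
#' tangent, with length `length_factor` times the local mask width. Lines
#' whose mask profile lacks a foreground run of at least `min_run` pixels
#' are eliminated.
#'
#' @param centerline Centerline list (`points`, `tangents`) from
#'   [segment_vessels()].
#' @param mask Logical vessel mask.
#' @param n_max Maximum number of lines (protocol default: 8).
#' @param center_frac Fraction of the centerline length used for stations
#'   (centered), avoiding end effects.
#' @param length_factor Line length as a multiple of the local mask width.
#' @param min_run Minimum foreground run (pixels) for a line to count as
#'   crossing the vessel.
#' @param min_spacing Minimum station spacing in pixels; short centerlines
#'   yield fewer than `n_max` lines.
#' @return List of `ScanLine`s: `index`, endpoints `p1`, `p2` (x, y), and
#'   `spacing` (1 px). Errors if every line is eliminated (the recording is
#'   then excluded as "unable to draw lines").
#' @export
place_scan_lines <- function(centerline, mask, n_max = 8, center_frac = 0.8,
                             length_factor = 3, min_run = 3,
                             min_spacing = 4) {
  pts <- centerline$points
  tgs <- centerline$tangents
  n <- nrow(pts)
  if (n < 2) stopf("centerline too short")
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  len <- s[n]
  lo <- len * (1 - center_frac) / 2
  hi <- len - lo
  span <- hi - lo
  k <- min(n_max, max(1L, floor(span / min_spacing) + 1L))
  stations <- if (k == 1) (lo + hi) / 2 else seq(lo, hi, length.out = k)

  lines <- list()
  for (i in seq_along(stations)) {
    j <- findInterval(stations[i], s, rightmost.closed = TRUE)
    j <- min(max(j, 1L), n - 1L)
    f <- if (seg[j] > 0) (stations[i] - s[j]) / seg[j] else 0
    pt <- pts[j, ] * (1 - f) + pts[j + 1, ] * f
    tg <- tgs[j, ] * (1 - f) + tgs[j + 1, ] * f
    tg <- tg / sqrt(sum(tg^2))
    nrm <- c(-tg[2], tg[1])
    w <- local_mask_width(mask, pt, nrm)
    half <- length_factor * w / 2
    p1 <- pt - half * nrm
    p2 <- pt + half * nrm
    # profile of the mask along the line at unit spacing
    npos <- max(2L, floor(2 * half) + 1L)
    u <- seq(0, 1, length.out = npos)
    prof <- mask_at(mask, p1[1] + u * (p2[1] - p1[1]),
                    p1[2] + u * (p2[2] - p1[2]))
    if (longest_run(prof) < min_run) next
    lines[[length(lines) + 1]] <- structure(
      list(index = length(lines) + 1L, p1 = p1, p2 = p2, spacing = 1),
      class = "ScanLine")
  }
  if (length(lines) == 0) stopf("unable to draw lines across the vessel")
  lines
}
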