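# Scene renderer: a top-hat tube around the centerline convolved with a
# Gaussian PSF, plus noise and 8-bit quantization. The red channel carries
# only what ejection verification needs: a static pipette wedge and a
# transient dye puff at its tip.

# Per-pixel distance to a polyline (min over segments of point-segment
# distance). Pixel centers at integer coordinates, x = column, y = row.
distance_to_polyline <- function(height, width, pts) {
  xs <- matrix(rep(seq_len(width), each = height), nrow = height)
  ys <- matrix(rep(seq_len(height), times = width), nrow = height)
  d2 <- matrix(Inf, height, width)
  for (k in seq_len(nrow(pts) - 1)) {
    a <- pts[k, ]; b <- pts[k + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    tt <- ((xs - a[1]) * ab[1] + (ys - a[2]) * ab[2]) / len2
    tt[tt < 0] <- 0; tt[tt > 1] <- 1
    px <- a[1] + tt * ab[1]; py <- a[2] + tt * ab[2]
    d2 <- pmin(d2, (xs - px)^2 + (ys - py)^2)
  }
  sqrt(d2)
}

# Location of the pipette tip: offset from the centerline midpoint,
# mimicking the ~40 um pipette-to-vessel working distance.
pipette_tip <- function(config) {
  pts <- config$centerline
  mid <- pts[ceiling(nrow(pts) / 2), ]
  c(x = as.numeric(mid[1]),
    y = max(4, as.numeric(mid[2]) - config$vessel_baseline_diameter / 2 -
              0.15 * config$image_height))
}

#' Region of interest at the pipette tip
#'
#' @param config A [scene_config()].
#' @param radius Region radius in pixels.
#' @return List with `x`, `y` (tip centre) and `radius`, as used by
#'   [verify_ejection()].
#' @export
pipette_tip_region <- function(config, radius = 6) {
  tip <- pipette_tip(config)
  list(x = tip[["x"]], y = tip[["y"]], radius = radius)
}

# Partial-volume tube: pixel intensity scales with the fraction of the
# pixel inside the tube, so the half-maximum crossing sits at exactly
# diameter/2 from the centerline.
render_one_frame <- function(dist_map, diameter, config) {
  cover <- pmin(pmax(diameter / 2 - dist_map + 0.5, 0), 1)
  config$bg + (config$fg - config$bg) * cover
}

#' Render a two-channel synthetic vessel video
#'
#' The green channel is a top-hat tube of half-width `diameter/2` around the
#' centerline, convolved with a Gaussian PSF, with additive Gaussian noise,
#' quantized to 8 bits. The red channel holds a static pipette wedge plus a
#' transient dye puff at the pipette tip spanning the pulse frame. Frames
#' listed in `artifact_frames` are rendered with added blur and translation.
#' Output is fully determined by the config's seed.
#'
#' @param truth A [simulate_diameter_trace()] result consistent with
#'   `config`.
#' @param config The [scene_config()] used to build `truth`.
#' @param puff_frame Frame index at which the dye puff is released; defaults
#'   to the pulse frame. Set earlier to emulate a pipette leak, or `NA` to
#'   omit the puff.
#' @return List with elements `green` and `red`, both [video_stack()]s.
#' @export
render_vessel_video <- function(truth, config, puff_frame = truth$pulse_frame) {
  stopifnot(inherits(truth, "SceneTruth"), inherits(config, "SceneConfig"))
  h <- config$image_height; w <- config$image_width
  if (max(truth$diameter_trace) >= min(h, w))
    stopf("vessel wider than the frame; rejecting config")
  nf <- length(truth$diameter_trace)
  dist_map <- distance_to_polyline(h, w, config$centerline)

  tip <- pipette_tip(config)
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  # wedge: triangle from the tip widening to the top edge
  half_w <- 0.06 * w
  in_wedge <- ys <= tip[["y"]] &
    abs(xs - tip[["x"]]) <= half_w * (tip[["y"]] - ys) / max(tip[["y"]], 1)
  puff_blob <- exp(-((xs - tip[["x"]])^2 + (ys - tip[["y"]])^2) / (2 * 3^2))
  puff_len <- max(1L, round(0.5 * config$frame_rate))

  green <- array(0, c(h, w, nf))
  red <- array(0, c(h, w, nf))
  with_seed(config$rng_seed, {
    for (i in seq_len(nf)) {
      g <- render_one_frame(dist_map, truth$diameter_trace[i], config)
      r <- config$bg / 2 + 90 * in_wedge
      if (!is.na(puff_frame) && i >= puff_frame && i < puff_frame + puff_len) {
        r <- r + 140 * exp(-(i - puff_frame) / puff_len) * puff_blob
      }
      if (config$psf_sigma > 0) {
        g <- EBImage::gblur(g, sigma = config$psf_sigma, boundary = "replicate")
        r <- EBImage::gblur(r, sigma = config$psf_sigma, boundary = "replicate")
      }
      if (i %in% config$artifact_frames) {
        g <- shift_mat(EBImage::gblur(g, sigma = 4, boundary = "replicate"), 3L, 3L)
        r <- shift_mat(r, 3L, 3L)
      }
      if (config$noise_sd > 0) {
        g <- g + stats::rnorm(h * w, sd = config$noise_sd)
        r <- r + stats::rnorm(h * w, sd = config$noise_sd)
      }
      green[, , i] <- quantize8(g)
      red[, , i] <- quantize8(r)
    }
  })
  ts <- truth$timestamps
  list(
    green = video_stack(green, timestamps = ts, channel = "green",
                        pulse_frame = truth$pulse_frame),
    red = video_stack(red, timestamps = ts, channel = "red",
                      pulse_frame = truth$pulse_frame)
  )
}

#' Write a rendered scene to disk
#'
#' Writes one multi-page TIFF per channel, the acquisition sidecars, and the
#' ground-truth diameter trace as CSV.
#'
#' @param rendered Output of [render_vessel_video()].
#' @param truth The matching [simulate_diameter_trace()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_scene <- function(rendered, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_video(rendered$green, file.path(dir, "green"))
  write_video(rendered$red, file.path(dir, "red"))
  utils::write.csv(
    data.frame(time_s = truth$timestamps,
               diameter_px = truth$diameter_trace,
               pct_change = truth$pct_trace),
    file.path(dir, "truth_trace.csv"), row.names = FALSE)
  invisible(dir)
}
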