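# Focus-based artifact rejection and pressure-ejection verification.

# Tenengrad focus measure: mean squared Sobel gradient magnitude, optionally
# restricted to a pixel subset.
tenengrad <- function(m, roi = NULL) {
  gx <- shift_mat(m, -1, -1) + 2 * shift_mat(m, 0, -1) + shift_mat(m, 1, -1) -
    shift_mat(m, -1, 1) - 2 * shift_mat(m, 0, 1) - shift_mat(m, 1, 1)
  gy <- shift_mat(m, -1, -1) + 2 * shift_mat(m, -1, 0) + shift_mat(m, -1, 1) -
    shift_mat(m, 1, -1) - 2 * shift_mat(m, 1, 0) - shift_mat(m, 1, 1)
  g2 <- gx^2 + gy^2
  if (is.null(roi)) mean(g2) else mean(g2[roi])
}

# Background region for the focus feature: everything outside a generously
# dilated vessel mask, so genuine vasomotion (sub-pixel edge shifts change
# the gradient energy of the vessel itself) is not mistaken for a focus
# change. Falls back to the whole frame when no clear vessel exists or the
# background would be too small.
focus_background_roi <- function(stack, mask_dilate = 15, min_frac = 0.2) {
  avg <- rowMeans(stack$frames, dims = 2) / 255
  if (diff(range(avg)) < 1e-6) return(NULL)
  thr <- EBImage::otsu(EBImage::Image(avg))
  mask <- avg > thr
  if (!any(mask) || all(mask)) return(NULL)
  grown <- EBImage::dilate(mask, EBImage::makeBrush(mask_dilate, "disc")) > 0
  bg <- !grown
  if (mean(bg) < min_frac) return(NULL)
  bg
}

#' Flag motion/focus-corrupted frames
#'
#' Computes a per-frame focus feature (Tenengrad: mean squared Sobel
#' gradient magnitude), z-scores it against the baseline window, and
#' excludes frames whose feature lies more than three standard deviations
#' above or below the baseline. The feature is evaluated outside a dilated
#' vessel mask whenever one can be segmented: blur and motion degrade the
#' whole field, while genuine diameter changes alter the gradient content
#' of the vessel itself and must not be flagged. Without a segmentable
#' vessel (or with too little background) the whole frame is used.
#'
#' @param stack A [video_stack()].
#' @param baseline_frames Frame indices forming the baseline window;
#'   defaults to all pre-pulse frames. Needs at least 3 frames with
#'   non-degenerate spread.
#' @param z_limit Exclusion threshold in baseline standard deviations.
#' @return Logical vector, `TRUE` for excluded frames. The per-frame focus
#'   feature and z-scores are attached as attributes `"focus"` and `"z"`.
#' @export
flag_artifact_frames <- function(stack, baseline_frames = NULL, z_limit = 3) {
  stopifnot(inherits(stack, "VideoStack"))
  if (is.null(baseline_frames)) {
    baseline_frames <- seq_len(max(stack$pulse_frame - 1, 0))
  }
  if (length(baseline_frames) < 3) stopf("baseline window needs >= 3 frames")
  nf <- n_frames(stack)
  roi <- focus_background_roi(stack)
  f <- vapply(seq_len(nf), function(i) tenengrad(stack$frames[, , i], roi),
              numeric(1))
  mu <- mean(f[baseline_frames])
  sd0 <- stats::sd(f[baseline_frames])
  if (sd0 == 0) stopf("degenerate baseline: focus feature has zero spread")
  z <- (f - mu) / sd0
  excluded <- abs(z) > z_limit
  attr(excluded, "focus") <- f
  attr(excluded, "z") <- z
  excluded
}

#' Locate the pipette tip from the red channel
#'
#' Estimates the tip position as the location of the largest smoothed
#' increase in red fluorescence at the pulse frame relative to the pre-pulse
#' mean (pressure ejection releases a visible dye puff at the tip).
#'
#' @param red The red-channel [video_stack()].
#' @param radius Region radius in pixels.
#' @return List with `x`, `y`, `radius`, suitable for [verify_ejection()].
#' @export
detect_tip_region <- function(red, radius = 6) {
  stopifnot(inherits(red, "VideoStack"))
  pf <- red$pulse_frame
  nf <- n_frames(red)
  post <- pf:min(pf + 2, nf)
  pre <- seq_len(max(pf - 1, 1))
  diff <- rowMeans(red$frames[, , post, drop = FALSE], dims = 2) -
    rowMeans(red$frames[, , pre, drop = FALSE], dims = 2)
  diff <- EBImage::gblur(diff, sigma = 2, boundary = "replicate")
  ij <- which(diff == max(diff), arr.ind = TRUE)[1, ]
  list(x = unname(ij[2]), y = unname(ij[1]), radius = radius)
}

#' Verify pressure ejection (and check for pipette leaks)
#'
#' Ejection is confirmed when the red-channel mean in the pipette-tip region
#' rises, after the pulse, more than `k` baseline standard deviations above
#' the pre-pulse mean. A leak is reported when the same criterion is already
#' met in a sham window before the pulse.
#'
#' @param red The red-channel [video_stack()].
#' @param tip_region List with `x`, `y`, `radius` (pixels), e.g. from
#'   [pipette_tip_region()].
#' @param pulse_frame Pulse frame index; defaults to the stack's.
#' @param k Detection threshold in baseline standard deviations.
#' @param window_s Averaging window length in seconds.
#' @return List with logicals `ejected` and `leak_before_pulse`.
#' @export
verify_ejection <- function(red, tip_region, pulse_frame = red$pulse_frame,
                            k = 3, window_s = 1) {
  stopifnot(inherits(red, "VideoStack"))
  h <- dim(red$frames)[1]; w <- dim(red$frames)[2]
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  sel <- (xs - tip_region$x)^2 + (ys - tip_region$y)^2 <= tip_region$radius^2
  if (!any(sel)) stopf("empty pipette-tip region")
  nf <- n_frames(red)
  r <- vapply(seq_len(nf), function(i) mean(red$frames[, , i][sel]),
              numeric(1))
  fr <- frame_rate_of(red)
  wlen <- max(1L, round(window_s * fr))
  pre <- seq_len(max(pulse_frame - 1, 0))
  if (length(pre) < 2 * wlen + 2) stopf("too few pre-pulse frames")
  ref <- pre[seq_len(ceiling(length(pre) / 2))]
  sham <- setdiff(pre, ref)
  thr <- mean(r[ref]) + k * max(stats::sd(r[ref]), 1e-9)
  post <- pulse_frame:min(pulse_frame + wlen - 1, nf)
  ejected <- mean(r[post]) > thr
  # sliding window over the sham period
  leak <- FALSE
  if (length(sham) >= wlen) {
    for (s in seq_len(length(sham) - wlen + 1)) {
      if (mean(r[sham[s:(s + wlen - 1)]]) > thr) {
        leak <- TRUE
        break
      }
    }
  }
  list(ejected = ejected, leak_before_pulse = leak)
}
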