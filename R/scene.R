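#' Configure a synthetic arteriole scene
#'
#' Describes one episodic recording: a single bright tubular vessel on a dark
#' background whose diameter follows a programmable baseline plus transient
#' dilations, imaged with an episodic protocol (5 s baseline, brief
#' pressure pulse, 2 min acquisition at 10-20 Hz).
#'
#' @param frame_rate Sampling rate in Hz; must lie in \[10, 20\].
#' @param duration Total recording length in seconds (baseline + acquisition).
#' @param baseline_s Pre-pulse baseline period in seconds.
#' @param pulse_time Time of the pressure pulse in seconds (defaults to the
#'   end of the baseline period).
#' @param image_height,image_width Frame size in pixels.
#' @param vessel_baseline_diameter Resting lumen diameter in pixels.
#' @param centerline Control points of the vessel centerline as an `n x 2`
#'   matrix of (x, y) pixel coordinates (origin top-left, x rightward,
#'   y downward). Default: a horizontal line through mid-height.
#' @param psf_sigma Gaussian point-spread-function sigma in pixels.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise.
#' @param artifact_frames Frame indices rendered with extra blur and
#'   translation, emulating focus/motion corruption.
#' @param dilation_peaks List of peaks, each a list with fields `onset_s`
#'   (seconds), `time_to_max_s` (seconds), `max_pct` (peak percent diameter
#'   change, > -100) and `decay_s` (exponential decay constant, seconds).
#'   Defaults emulate the observed response scale: a single 5.8 percent
#'   dilation peaking roughly 45 s after the pulse.
#' @param peak_shape Rise waveform: `"linear"` (default) or `"halfcos"`.
#' @param fg,bg Foreground (lumen) and background 8-bit intensities.
#' @param rng_seed Integer seed; together with the config it fully
#'   determines the rendered output.
#' @return A `SceneConfig` list.
#' @export
scene_config <- function(frame_rate = 10, duration = 125, baseline_s = 5,
                         pulse_time = baseline_s,
                         image_height = 96, image_width = 128,
                         vessel_baseline_diameter = 20,
                         centerline = NULL,
                         psf_sigma = 1, noise_sd = 5,
                         artifact_frames = integer(0),
                         dilation_peaks = list(list(
                           onset_s = pulse_time + 35, time_to_max_s = 10,
                           max_pct = 5.8, decay_s = 6)),
                         peak_shape = c("linear", "halfcos"),
                         fg = 200, bg = 30, rng_seed = 1L) {
  peak_shape <- match.arg(peak_shape)
  if (frame_rate < 10 || frame_rate > 20)
    stopf("frame_rate must lie in [10, 20] Hz")
  if (duration < baseline_s) stopf("duration must be >= baseline_s")
  for (p in dilation_peaks) {
    if (!all(c("onset_s", "time_to_max_s", "max_pct", "decay_s") %in% names(p)))
      stopf("each dilation peak needs onset_s, time_to_max_s, max_pct, decay_s")
    if (p$max_pct <= -100) stopf("peak max_pct must exceed -100")
  }
  if (is.null(centerline)) {
    centerline <- cbind(x = c(1, image_width), y = rep(image_height / 2, 2))
  }
  structure(
    list(frame_rate = frame_rate, duration = duration,
         baseline_s = baseline_s, pulse_time = pulse_time,
         image_height = image_height, image_width = image_width,
         vessel_baseline_diameter = vessel_baseline_diameter,
         centerline = centerline, psf_sigma = psf_sigma,
         noise_sd = noise_sd, artifact_frames = as.integer(artifact_frames),
         dilation_peaks = dilation_peaks, peak_shape = peak_shape,
         fg = fg, bg = bg, rng_seed = as.integer(rng_seed)),
    class = "SceneConfig"
  )
}

peak_pct_at <- function(t, peak, shape) {
  t_max <- peak$onset_s + peak$time_to_max_s
  out <- numeric(length(t))
  rising <- t >= peak$onset_s & t <= t_max
  if (peak$time_to_max_s > 0) {
    u <- (t[rising] - peak$onset_s) / peak$time_to_max_s
    out[rising] <- peak$max_pct *
      if (shape == "linear") u else (1 - cos(pi * u)) / 2
  } else {
    out[rising] <- peak$max_pct
  }
  decaying <- t > t_max
  out[decaying] <- peak$max_pct * exp(-(t[decaying] - t_max) / peak$decay_s)
  out
}

#' Simulate a ground-truth diameter trace
#'
#' Builds the per-frame lumen diameter implied by a scene configuration: the
#' baseline diameter before each peak onset, a linear (or half-cosine) rise
#' to the peak maximum over its time-to-max, then exponential decay. Peaks
#' superpose additively on the percent-change scale.
#'
#' @param config A [scene_config()].
#' @return A `SceneTruth` list with `diameter_trace` (pixels, one entry per
#'   frame), `pct_trace` (percent change from baseline), `timestamps`,
#'   `centerline`, `pulse_frame` and `artifact_frames`.
#' @export
simulate_diameter_trace <- function(config) {
  stopifnot(inherits(config, "SceneConfig"))
  nf <- round(config$duration * config$frame_rate)
  t <- (seq_len(nf) - 1) / config$frame_rate
  pct <- numeric(nf)
  for (p in config$dilation_peaks) {
    pct <- pct + peak_pct_at(t, p, config$peak_shape)
  }
  diam <- config$vessel_baseline_diameter * (1 + pct / 100)
  if (any(diam <= 0))
    stopf("dilation peaks drive the diameter to <= 0; rejecting config")
  pulse_frame <- which.min(abs(t - config$pulse_time))
  structure(
    list(diameter_trace = diam, pct_trace = pct, timestamps = t,
         centerline = config$centerline, pulse_frame = pulse_frame,
         artifact_frames = config$artifact_frames),
    class = "SceneTruth"
  )
}
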