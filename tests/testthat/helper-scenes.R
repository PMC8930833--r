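# Shared fixture builders. Scenes are small (96 x 128 px, tens of seconds)
# so the suite stays fast; geometry and protocol mirror the episodic study
# design (pre-pulse baseline, pulse, acquisition at 10 Hz).

# cache: expensive rendered fixtures built once per test run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

quiet_scene <- function(duration = 20, noise_sd = 0, diameter = 20, ...) {
  scene_config(duration = duration, noise_sd = noise_sd,
               baseline_s = min(5, duration / 2),
               vessel_baseline_diameter = diameter,
               dilation_peaks = list(), ...)
}

rendered_tube <- function(duration = 20, noise_sd = 0, diameter = 20, ...) {
  sc <- quiet_scene(duration = duration, noise_sd = noise_sd,
                    diameter = diameter, ...)
  truth <- simulate_diameter_trace(sc)
  c(render_vessel_video(truth, sc), list(truth = truth, config = sc))
}

# A directly constructed WidthTrace (bypasses imaging) for peak/QC tests:
# `pct` are the post-pulse bin values; three zero baseline bins precede the
# pulse at t = 0.
synthetic_trace <- function(pct, missing = rep(FALSE, length(pct)),
                            pulse_time = 0, w0 = 20) {
  n <- length(pct)
  structure(
    list(bin_time = pulse_time + c(-2.5, -1.5, -0.5, seq_len(n) - 0.5),
         pct = c(0, 0, 0, ifelse(missing, NA_real_, pct)),
         missing = c(FALSE, FALSE, FALSE, missing),
         w0 = w0, pulse_time = pulse_time),
    class = "WidthTrace"
  )
}

# Line records with controllable QC fields, defaulting to a clean record.
qc_record <- function(animal = "a1", agent = "Saline", field = 1, pulse = 1,
                      line = 1, auc = 10, max_change = 5, n_peaks = 1,
                      coverage_s = 110, max_gap_s = 2, trace_max = 5,
                      drawable = TRUE, sex = "M") {
  data.frame(animal = animal, sex = sex, agent = agent, field = field,
             pulse = pulse, line = line, auc = auc, max_change = max_change,
             t_max = 10, duration = 8, n_peaks = n_peaks,
             coverage_s = coverage_s, max_gap_s = max_gap_s,
             trace_max = trace_max, drawable = drawable)
}

# A full pulse of `n` clean lines for one animal.
qc_pulse <- function(animal, n = 8, agent = "Saline", pulse = 1, ...) {
  do.call(rbind, lapply(seq_len(n), function(i)
    qc_record(animal = animal, agent = agent, pulse = pulse, line = i, ...)))
}
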