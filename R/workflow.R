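# End-to-end orchestration: simulate -> measure -> peaks/QC -> stats under
# one config and seed, with a provenance manifest.

#' Measure one recording
#'
#' Runs the measurement stages on a two-channel stack: artifact flagging on
#' the green channel, vessel segmentation, random arteriole selection, scan
#' line placement, per-line kymographs, spatial smoothing, two-Gaussian
#' binarization, per-frame widths and 1-s baseline-normalized traces.
#'
#' @param green,red Green and red [video_stack()]s (already standardized).
#' @param seed Seed for the random arteriole choice.
#' @param n_lines Maximum number of scan lines.
#' @param min_peak_frac Passed through to downstream peak detection via the
#'   returned traces (stored for reference).
#' @return List with `traces` (one `WidthTrace` per retained line),
#'   `lines`, `excluded` (frame mask), `ejection` (red-channel check), and
#'   `arteriole` (chosen candidate).
#' @export
measure_recording <- function(green, red = NULL, seed = 1L, n_lines = 8,
                              min_peak_frac = 0.1) {
  excluded <- flag_artifact_frames(green)
  cands <- segment_vessels(green)
  art <- select_arteriole(cands, seed = seed)
  lines <- place_scan_lines(art$centerline, art$mask, n_max = n_lines)
  pulse_time <- green$timestamps[green$pulse_frame]
  traces <- lapply(lines, function(ln) {
    ky <- build_kymograph(green, ln)
    ky <- set_excluded_frames(ky, excluded)
    ky <- smooth_kymograph(ky)
    fit <- fit_intensity_mixture(ky)
    w <- width_per_frame(ky, fit)
    bin_and_normalize(w, ky$timestamps, pulse_time)
  })
  ejection <- if (!is.null(red)) {
    tryCatch(verify_ejection(red, detect_tip_region(red)),
             error = function(e) NULL)
  }
  list(traces = traces, lines = lines, excluded = excluded,
       ejection = ejection, arteriole = art,
       min_peak_frac = min_peak_frac)
}

#' Configure an end-to-end synthetic experiment
#'
#' One config (and one seed) governs the whole run. The episodic protocol
#' defaults to the standard protocol: 5 s baseline, a pressure pulse, 120 s
#' acquisition at 10 Hz, 3 pulses per field.
#'
#' @param mode `"table"` simulates per-line ln-AUC tables directly from the
#'   random-intercept model; `"imaging"` renders and measures synthetic
#'   videos end to end.
#' @param agents For `"table"`: named list of ln-scale cell means (passed to
#'   [lnauc_sim_config()]). For `"imaging"`: named list of peak maxima
#'   (percent diameter change) per agent.
#' @param ref_agent Reference (control) agent.
#' @param animals_per_agent Animals per agent.
#' @param sigma2_between,sigma2_within Variance components on the ln scale
#'   (table mode).
#' @param n_pulses,lines_per_pulse,n_fields Design sizes.
#' @param frame_rate,baseline_s,acquisition_s,image_height,image_width,
#'   vessel_baseline_diameter,psf_sigma,noise_sd Imaging-mode scene
#'   parameters.
#' @param qc Named list of QC thresholds passed to [apply_qc()] (imaging
#'   mode). Defaults to the standard rules; shorter test acquisitions should
#'   scale `min_coverage_s` with `acquisition_s`.
#' @param seed Master seed for the run.
#' @return A `RunConfig` list.
#' @export
run_config <- function(mode = c("table", "imaging"),
                       agents = list(Saline = 0, `L-THA` = 1.741),
                       ref_agent = "Saline",
                       animals_per_agent = 6,
                       sigma2_between = 1.24, sigma2_within = 4.51,
                       n_pulses = 3, lines_per_pulse = 8, n_fields = 1,
                       frame_rate = 10, baseline_s = 5, acquisition_s = 120,
                       image_height = 96, image_width = 128,
                       vessel_baseline_diameter = 20,
                       psf_sigma = 1, noise_sd = 4, qc = list(),
                       seed = 1L) {
  mode <- match.arg(mode)
  if (!ref_agent %in% names(agents)) stopf("ref_agent must be one of the agents")
  structure(
    list(mode = mode, agents = agents, ref_agent = ref_agent,
         animals_per_agent = animals_per_agent,
         sigma2_between = sigma2_between, sigma2_within = sigma2_within,
         n_pulses = n_pulses, lines_per_pulse = lines_per_pulse,
         n_fields = n_fields, frame_rate = frame_rate,
         baseline_s = baseline_s, acquisition_s = acquisition_s,
         image_height = image_height, image_width = image_width,
         vessel_baseline_diameter = vessel_baseline_diameter,
         psf_sigma = psf_sigma, noise_sd = noise_sd, qc = qc,
         seed = as.integer(seed)),
    class = "RunConfig"
  )
}

simulate_imaging_records <- function(config) {
  agents <- names(config$agents)
  records <- list()
  an_id <- 0
  for (ai in seq_along(agents)) {
    ag <- agents[ai]
    for (a in seq_len(config$animals_per_agent)) {
      an_id <- an_id + 1
      animal <- sprintf("%s_%02d", ag, a)
      sex <- if (a %% 2 == 1) "M" else "F"
      # animal-level responsiveness multiplier (lognormal)
      mult <- with_seed(config$seed + 7919L * an_id,
                        exp(stats::rnorm(1, 0, 0.3)))
      for (p in seq_len(config$n_pulses)) {
        sc_seed <- config$seed + 7919L * an_id + 101L * p
        sc <- scene_config(
          frame_rate = config$frame_rate,
          duration = config$baseline_s + config$acquisition_s,
          baseline_s = config$baseline_s,
          image_height = config$image_height,
          image_width = config$image_width,
          vessel_baseline_diameter = config$vessel_baseline_diameter,
          psf_sigma = config$psf_sigma, noise_sd = config$noise_sd,
          dilation_peaks = list(list(
            onset_s = config$baseline_s + 10, time_to_max_s = 15,
            max_pct = config$agents[[ag]] * mult, decay_s = 8)),
          rng_seed = sc_seed)
        truth <- simulate_diameter_trace(sc)
        vid <- render_vessel_video(truth, sc)
        meas <- measure_recording(vid$green, vid$red, seed = sc_seed)
        for (li in seq_along(meas$traces)) {
          records[[length(records) + 1]] <- make_line_record(
            meas$traces[[li]],
            list(animal = animal, sex = sex, agent = ag, field = 1L,
                 pulse = p, line = li))
        }
      }
    }
  }
  do.call(rbind, records)
}

#' Run a full synthetic experiment
#'
#' Executes every stage under one seed: data generation (table- or
#' imaging-mode), QC, the ln-scale mixed model, per-agent combined and
#' per-pulse contrasts versus the reference agent, and the forest table.
#' When `out_dir` is given, writes the analytic table, contrast table,
#' forest table, QC audit and a provenance manifest (config hash, seed,
#' package and R versions) sufficient to reproduce every output.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return List with `table` (`AnalyticTable` or data frame), `fit`
#'   (`LmmFit`), `contrasts`, `forest`, `audit` and `manifest`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  stage <- "simulate"
  res <- tryCatch({
    if (config$mode == "table") {
      sim <- lnauc_sim_config(
        cell_means = config$agents,
        sigma2_between = config$sigma2_between,
        sigma2_within = config$sigma2_within,
        animals_per_agent = config$animals_per_agent,
        n_pulses = config$n_pulses,
        lines_per_pulse = config$lines_per_pulse,
        n_fields = config$n_fields, rng_seed = config$seed)
      records <- simulate_lnauc_table(sim)
      table <- records
      audit <- data.frame()
      stage <- "stats"
      fit <- fit_lmm(records, response = "ln_auc", log = FALSE,
                     ref_agent = config$ref_agent)
    } else {
      records <- simulate_imaging_records(config)
      stage <- "qc"
      table <- do.call(apply_qc, c(list(records), config$qc))
      audit <- table$audit
      stage <- "stats"
      fit <- fit_lmm(table, response = "auc", log = TRUE,
                     ref_agent = config$ref_agent)
    }
    others <- setdiff(fit$levels$agent, config$ref_agent)
    if (length(others) == 0)
      stopf("only one agent level left after QC; no contrasts to estimate")
    contrasts <- do.call(rbind, lapply(others, function(ag)
      contrast_table(fit, ag, config$ref_agent)))
    forest <- export_forest(contrasts)
    list(table = table, fit = fit, contrasts = contrasts, forest = forest,
         audit = audit)
  }, error = function(e) {
    stopf("stage '%s' failed: %s", stage, conditionMessage(e))
  })

  manifest <- list(
    seed = config$seed,
    mode = config$mode,
    package_version = as.character(utils::packageVersion("vasokymo")),
    r_version = R.version.string)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_path <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(unclass(config), cfg_path)
    manifest$config_md5 <- unname(tools::md5sum(cfg_path))
    recs <- if (inherits(res$table, "AnalyticTable")) res$table$records else res$table
    utils::write.csv(recs, file.path(out_dir, "analytic_table.csv"),
                     row.names = FALSE)
    utils::write.csv(res$contrasts, file.path(out_dir, "contrasts.csv"),
                     row.names = FALSE)
    utils::write.csv(res$forest, file.path(out_dir, "forest.csv"),
                     row.names = FALSE)
    utils::write.csv(res$audit, file.path(out_dir, "qc_audit.csv"),
                     row.names = FALSE)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  res$manifest <- manifest
  res
}
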