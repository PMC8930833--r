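# Dataset assembly and quality control: one record per scan line x pulse,
# largest-peak metrics, and the six exclusion rules.

#' Build one analytic record from a width trace
#'
#' Computes largest-peak metrics and data-quality summaries for one scan
#' line under one pulse, tagged with its experimental metadata.
#'
#' @param trace A [bin_and_normalize()] result.
#' @param meta List or one-row data frame with fields `animal`, `sex`,
#'   `agent`, `field`, `pulse`, `line`.
#' @param min_peak_frac Passed to [detect_peaks()].
#' @return One-row data frame (a `LineRecord`): metadata, `auc`,
#'   `max_change`, `t_max`, `duration`, `n_peaks`, `coverage_s`,
#'   `max_gap_s`, `trace_max`, `drawable`.
#' @export
make_line_record <- function(trace, meta, min_peak_frac = 0.1) {
  stopifnot(inherits(trace, "WidthTrace"))
  pk <- largest_peak(detect_peaks(trace, min_peak_frac))
  q <- trace_quality(trace)
  data.frame(
    animal = meta$animal, sex = meta$sex, agent = meta$agent,
    field = meta$field, pulse = meta$pulse, line = meta$line,
    auc = if (is.null(pk)) NA_real_ else pk$auc,
    max_change = if (is.null(pk)) NA_real_ else pk$max_change,
    t_max = if (is.null(pk)) NA_real_ else pk$t_max - trace$pulse_time,
    duration = if (is.null(pk)) NA_real_ else pk$end - pk$start,
    n_peaks = length(detect_peaks(trace, min_peak_frac)),
    coverage_s = q$coverage_s, max_gap_s = q$max_gap_s,
    trace_max = q$trace_max,
    drawable = TRUE)
}

#' Apply the dataset quality-control rules
#'
#' Excludes records per six rules: the program could not draw
#' lines across the vessel (`drawable` is `FALSE`); a missing-data gap
#' longer than `gap_max_s`; less than `min_coverage_s` of retained data out
#' of the acquisition window; trace maximum change above
#' `max_change_limit` percent (an artifact guard); no positive peak; and a
#' whole pulse is dropped when fewer than `min_lines` of its lines survive
#' the line-level rules. Rules are evaluated independently, so the retained
#' set does not depend on their order, and the audit log lists every
#' exclusion with all the rules it violated.
#'
#' @param records Data frame of [make_line_record()] rows.
#' @param gap_max_s Maximum tolerated missing gap, seconds.
#' @param min_coverage_s Minimum retained data, seconds.
#' @param max_change_limit Maximum plausible percent change.
#' @param min_lines Minimum usable lines per pulse.
#' @return An `AnalyticTable`: list with `records` (QC-passing rows),
#'   `audit` (excluded row metadata + semicolon-joined rules), and `counts`.
#' @export
apply_qc <- function(records, gap_max_s = 20, min_coverage_s = 60,
                     max_change_limit = 30, min_lines = 5) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  rules <- vector("list", n)
  add_rule <- function(i, rule) {
    rules[[i]] <<- c(rules[[i]], rule)
  }
  drawable <- if ("drawable" %in% names(records)) records$drawable else TRUE
  for (i in seq_len(n)) {
    if (!isTRUE(drawable[i])) add_rule(i, "lines_not_drawable")
    if (is.finite(records$max_gap_s[i]) && records$max_gap_s[i] > gap_max_s)
      add_rule(i, "gap_gt_20s")
    if (is.finite(records$coverage_s[i]) &&
        records$coverage_s[i] < min_coverage_s)
      add_rule(i, "coverage_lt_60s")
    if (is.finite(records$trace_max[i]) &&
        records$trace_max[i] > max_change_limit)
      add_rule(i, "max_change_gt_30pct")
    if (records$n_peaks[i] == 0 || is.na(records$auc[i]))
      add_rule(i, "no_positive_peak")
  }
  line_ok <- lengths(rules) == 0
  # pulse-level rule: at least `min_lines` usable lines per pulse
  key <- interaction(records$animal, records$agent, records$field,
                     records$pulse, drop = TRUE)
  usable_per_pulse <- tapply(line_ok, key, sum)
  for (i in seq_len(n)) {
    if (usable_per_pulse[[as.character(key[i])]] < min_lines)
      add_rule(i, "fewer_than_5_lines")
  }
  keep <- lengths(rules) == 0
  audit <- records[!keep, c("animal", "agent", "field", "pulse", "line"),
                   drop = FALSE]
  audit$rules <- vapply(rules[!keep], paste, character(1), collapse = ";")
  rownames(audit) <- NULL
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(
    list(records = out, audit = audit,
         counts = c(input = n, retained = sum(keep), excluded = sum(!keep))),
    class = "AnalyticTable"
  )
}

#' @export
print.AnalyticTable <- function(x, ...) {
  cat(sprintf("AnalyticTable: %d/%d line records retained (%d excluded)\n",
              x$counts[["retained"]], x$counts[["input"]],
              x$counts[["excluded"]]))
  invisible(x)
}

#' Animal-level usability summary
#'
#' Summarizes, per animal, whether any line record survived QC, and reports
#' the fraction of usable animals as a percentage rounded to the nearest
#' integer (the convention used for cohort reporting).
#'
#' @param table An [apply_qc()] result.
#' @return List with `n_total`, `n_usable` and `pct_usable`.
#' @export
usable_animal_summary <- function(table) {
  stopifnot(inherits(table, "AnalyticTable"))
  all_animals <- unique(c(table$records$animal, table$audit$animal))
  usable <- unique(table$records$animal)
  list(n_total = length(all_animals), n_usable = length(usable),
       pct_usable = round(100 * length(usable) / length(all_animals)))
}
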