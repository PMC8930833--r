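# ln-scale mixed-effects analysis: random-intercept model per animal,
# Satterthwaite-corrected Wald contrasts reported as exponentiated ratios,
# and difference-of-differences treatment effects for DMSO-dissolved agents.

#' Fit the ln-scale random-intercept mixed model
#'
#' Fits `ln(response) ~ agent * pulse + field + (1 | animal)` by REML: agent,
#' pulse (factor) and their interaction plus field as fixed effects, and a
#' random intercept per animal so repeated lines, pulses and fields on the
#' same animal are correlated and the animal is the independent unit. A
#' single model is fit over all agents so every contrast shares the same
#' controls. Terms with a single observed level (e.g. one field) are
#' dropped automatically.
#'
#' @param table An `AnalyticTable` from [apply_qc()], or a data frame with
#'   columns `animal`, `agent`, `field`, `pulse` and the response.
#' @param response Name of the response column (`"auc"` or `"max_change"`,
#'   or any positive column).
#' @param log Log-transform the response (`TRUE`, the default)? Set to
#'   `FALSE` when the column is already on the ln scale (e.g. `"ln_auc"`).
#' @param ref_agent Reference agent for treatment coding; contrasts are
#'   built from cell means, so this cannot change any reported contrast.
#' @return An `LmmFit`: list with the `lmerTest` model, the analysis data,
#'   factor levels, and the response label.
#' @export
fit_lmm <- function(table, response = "auc", log = TRUE,
                    ref_agent = "Saline") {
  data <- if (inherits(table, "AnalyticTable")) table$records else table
  stopifnot(is.data.frame(data))
  need <- c("animal", "agent", "field", "pulse", response)
  if (!all(need %in% names(data)))
    stopf("missing columns: %s", paste(setdiff(need, names(data)), collapse = ", "))
  if (length(unique(data$animal)) < 2) stopf("need >= 2 animals")
  y <- data[[response]]
  if (log) {
    if (any(y <= 0))
      stopf("response must be positive before log transform (QC should have removed nonpositive peaks)")
    y <- base::log(y)
  }
  d <- data.frame(
    .y = y,
    animal = factor(data$animal),
    agent = factor(data$agent),
    pulse = factor(data$pulse),
    field = factor(data$field))
  if (ref_agent %in% levels(d$agent))
    d$agent <- stats::relevel(d$agent, ref = ref_agent)
  terms <- c(
    if (nlevels(d$agent) > 1 && nlevels(d$pulse) > 1) "agent * pulse"
    else c(if (nlevels(d$agent) > 1) "agent", if (nlevels(d$pulse) > 1) "pulse"),
    if (nlevels(d$field) > 1) "field")
  rhs <- paste(c(if (length(terms)) terms else "1", "(1 | animal)"),
               collapse = " + ")
  form <- stats::as.formula(paste(".y ~", rhs))
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore")
  model <- lmerTest::lmer(form, data = d, REML = TRUE, control = ctrl)
  if (lme4::isSingular(model))
    warnf("singular fit: between-animal variance estimated as 0")
  structure(
    list(model = model, data = d, response = response, log = log,
         levels = list(agent = levels(d$agent), pulse = levels(d$pulse),
                       field = levels(d$field))),
    class = "LmmFit"
  )
}

#' Variance components of a fitted model
#'
#' @param fit An [fit_lmm()] result.
#' @return Named vector: `between` (random-intercept variance) and `within`
#'   (residual variance), in (ln units)^2.
#' @export
var_components <- function(fit) {
  stopifnot(inherits(fit, "LmmFit"))
  vc <- lme4::VarCorr(fit$model)
  c(between = as.numeric(vc$animal[1, 1]),
    within = attr(vc, "sc")^2)
}

# Fixed-effect design row for the (agent, pulse) cell at the reference
# field level. Field is additive, so it cancels in any between-cell
# contrast.
fixed_row <- function(fit, agent, pulse) {
  lv <- fit$levels
  if (!agent %in% lv$agent) stopf("agent '%s' not in the fitted model", agent)
  if (!as.character(pulse) %in% lv$pulse)
    stopf("pulse '%s' not in the fitted model", pulse)
  nd <- data.frame(
    agent = factor(agent, levels = lv$agent),
    pulse = factor(as.character(pulse), levels = lv$pulse),
    field = factor(lv$field[1], levels = lv$field))
  ff <- stats::delete.response(stats::terms(lme4::nobars(stats::formula(fit$model))))
  drop(stats::model.matrix(ff, nd))
}

contrast_from_vector <- function(fit, L, label, pulse_label) {
  if (all(abs(L) < 1e-14)) {
    return(data.frame(label = label, pulse = pulse_label, estimate_ln = 0,
                      se = 0, df = NA_real_, p = 1, ratio = 1,
                      ci_lo = 1, ci_hi = 1))
  }
  ct <- lmerTest::contest1D(fit$model, L, confint = FALSE)
  est <- ct$Estimate
  se <- ct$`Std. Error`
  df <- ct$df
  tcrit <- stats::qt(0.975, df)
  data.frame(label = label, pulse = pulse_label, estimate_ln = est, se = se,
             df = df, p = ct$`Pr(>|t|)`, ratio = exp(est),
             ci_lo = exp(est - tcrit * se), ci_hi = exp(est + tcrit * se))
}

#' Agent contrast as a ratio with 95% CI
#'
#' Estimates the ln-scale mean difference between two agents from the fitted
#' cell means, either at one pulse or averaged over the three pulses, with a
#' Satterthwaite-corrected two-sided Wald test; the difference and its CI
#' are exponentiated to a ratio. No multiplicity adjustment is applied.
#'
#' @param fit An [fit_lmm()] result.
#' @param agent,ref Agent levels to compare (`agent` vs `ref`).
#' @param pulse A pulse level, or `NULL` (default) for the pulse-averaged
#'   contrast.
#' @param label Row label; defaults to `"<agent> to <ref>"`.
#' @return A one-row data frame (`ContrastResult`): `label`, `pulse`,
#'   `estimate_ln`, `se`, `df`, `p`, `ratio`, `ci_lo`, `ci_hi`.
#' @export
contrast <- function(fit, agent, ref, pulse = NULL, label = NULL) {
  stopifnot(inherits(fit, "LmmFit"))
  if (is.null(label)) label <- paste(agent, "to", ref)
  per_pulse <- function(p) fixed_row(fit, agent, p) - fixed_row(fit, ref, p)
  if (is.null(pulse)) {
    L <- Reduce(`+`, lapply(fit$levels$pulse, per_pulse)) /
      length(fit$levels$pulse)
    contrast_from_vector(fit, L, label, "combined")
  } else {
    contrast_from_vector(fit, per_pulse(pulse), label, as.character(pulse))
  }
}

#' Combined and per-pulse contrasts for one comparison
#'
#' @inheritParams contrast
#' @return Data frame with one `"combined"` row followed by one row per
#'   pulse (the forest-plot layout).
#' @export
contrast_table <- function(fit, agent, ref, label = NULL) {
  rows <- c(list(contrast(fit, agent, ref, pulse = NULL, label = label)),
            lapply(fit$levels$pulse, function(p)
              contrast(fit, agent, ref, pulse = p, label = label)))
  do.call(rbind, rows)
}

#' Difference-of-differences contrast for a DMSO-dissolved agent
#'
#' For an agent whose vehicle is Saline/DMSO, removes both vehicle effects
#' by taking the difference of (agent + substrate vs DMSO vehicle) and
#' (substrate vs saline): `(agent - DMSO) - (L-THA - Saline)`, per pulse or
#' pulse-averaged, with the SE from the combined contrast vector.
#'
#' @param fit An [fit_lmm()] result.
#' @param agent The agent + substrate cell (e.g. `"Indo+L-THA"`).
#' @param vehicle The DMSO vehicle control level.
#' @param substrate The substrate-alone level (e.g. `"L-THA"`).
#' @param control The saline control level.
#' @param pulse A pulse level, or `NULL` for pulse-averaged.
#' @param label Row label.
#' @return A one-row `ContrastResult` data frame.
#' @export
dod_contrast <- function(fit, agent, vehicle = "DMSO", substrate = "L-THA",
                         control = "Saline", pulse = NULL, label = NULL) {
  stopifnot(inherits(fit, "LmmFit"))
  cells <- c(agent, vehicle, substrate, control)
  missing <- setdiff(cells, fit$levels$agent)
  if (length(missing))
    stopf("missing cell(s): %s", paste(missing, collapse = ", "))
  if (is.null(label))
    label <- sprintf("%s-D to %s-%s", agent, substrate, control)
  per_pulse <- function(p) {
    (fixed_row(fit, agent, p) - fixed_row(fit, vehicle, p)) -
      (fixed_row(fit, substrate, p) - fixed_row(fit, control, p))
  }
  if (is.null(pulse)) {
    L <- Reduce(`+`, lapply(fit$levels$pulse, per_pulse)) /
      length(fit$levels$pulse)
    contrast_from_vector(fit, L, label, "combined")
  } else {
    contrast_from_vector(fit, per_pulse(pulse), label, as.character(pulse))
  }
}

#' Difference-of-differences from two component differences
#'
#' Pure arithmetic used when combining already-estimated ln-scale
#' differences: subtracts the substrate-vs-control difference from the
#' agent-vs-vehicle difference and exponentiates.
#'
#' @param agent_vs_vehicle ln-scale difference of agent + substrate vs the
#'   DMSO vehicle.
#' @param substrate_vs_control ln-scale difference of substrate vs saline.
#' @return List with `delta` (ln scale) and `ratio` (`exp(delta)`).
#' @export
dod_from_differences <- function(agent_vs_vehicle, substrate_vs_control) {
  delta <- agent_vs_vehicle - substrate_vs_control
  list(delta = delta, ratio = exp(delta))
}

#' Likelihood-ratio test for the agent-by-pulse interaction
#'
#' Refits the model (and a reduced model without the interaction) by ML and
#' compares twice the log-likelihood difference to a chi-squared
#' distribution with the number of dropped parameters as degrees of
#' freedom.
#'
#' @param fit The full-model [fit_lmm()] result.
#' @param reduced Optional reduced-model `LmmFit`; by default the
#'   agent-by-pulse interaction is dropped from `fit`. The reduced fixed
#'   effects must nest within the full model's.
#' @return List with `statistic`, `df` and `p`.
#' @export
lrt_interaction <- function(fit, reduced = NULL) {
  stopifnot(inherits(fit, "LmmFit"))
  full_ml <- stats::update(fit$model, REML = FALSE)
  red_ml <- if (is.null(reduced)) {
    stats::update(fit$model, formula = stats::update(stats::formula(fit$model),
                                                     . ~ . - agent:pulse),
                  REML = FALSE)
  } else {
    stats::update(reduced$model, REML = FALSE)
  }
  lab_full <- attr(stats::terms(lme4::nobars(stats::formula(full_ml))), "term.labels")
  lab_red <- attr(stats::terms(lme4::nobars(stats::formula(red_ml))), "term.labels")
  if (!all(lab_red %in% lab_full)) stopf("models are not nested")
  ll_full <- as.numeric(stats::logLik(full_ml))
  ll_red <- as.numeric(stats::logLik(red_ml))
  df <- length(lme4::fixef(full_ml)) - length(lme4::fixef(red_ml))
  if (df <= 0) stopf("reduced model does not drop any fixed-effect parameter")
  stat <- max(0, 2 * (ll_full - ll_red))
  list(statistic = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Refit the model on a subset of the data
#'
#' Identical model form on a filtered dataset, e.g. sex-stratified refits or
#' an agent subset.
#'
#' @param fit An [fit_lmm()] result fitted from a table that carried the
#'   filter columns (e.g. `sex`).
#' @param table The original table or data frame to filter.
#' @param sex Optional sex level to keep.
#' @param agents Optional character vector of agent levels to keep.
#' @return An `LmmFit` on the subset (error if fewer than 2 animals remain).
#' @export
subset_refit <- function(fit, table, sex = NULL, agents = NULL) {
  data <- if (inherits(table, "AnalyticTable")) table$records else table
  keep <- rep(TRUE, nrow(data))
  if (!is.null(sex)) keep <- keep & data$sex %in% sex
  if (!is.null(agents)) keep <- keep & data$agent %in% agents
  sub <- data[keep, , drop = FALSE]
  if (nrow(sub) == 0) stopf("empty subset")
  if (length(unique(sub$animal)) < 2) stopf("subset has fewer than 2 animals")
  fit_lmm(sub, response = fit$response, log = fit$log,
          ref_agent = fit$levels$agent[1])
}

#' Assemble a forest-plot table
#'
#' Binds contrast rows into the tidy layout used for forest plots: label,
#' pulse (or "combined"), ratio, CI bounds and p-value, against a no-effect
#' reference line at 1.
#'
#' @param results A `ContrastResult` data frame, or a list of them.
#' @return Data frame with columns `label`, `pulse`, `ratio`, `ci_lo`,
#'   `ci_hi`, `p`.
#' @export
export_forest <- function(results) {
  if (is.data.frame(results)) results <- list(results)
  if (length(results) == 0) stopf("no contrast results to export")
  tab <- do.call(rbind, results)
  out <- tab[, c("label", "pulse", "ratio", "ci_lo", "ci_hi", "p")]
  rownames(out) <- NULL
  out
}
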