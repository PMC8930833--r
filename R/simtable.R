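#' Configure a synthetic ln-AUC table
#'
#' Parameterizes the generating random-intercept model for per-line ln-AUC
#' values: fixed cell means on the ln scale indexed by agent and pulse, an
#' additive field effect, a Normal between-animal intercept and Normal
#' within-animal residual noise. Defaults use variance components typical of
#' this design (between-animal 1.24, within-animal 4.51, ln-units squared).
#'
#' @param cell_means Named list: one entry per agent, each a numeric vector
#'   of per-pulse ln-scale means (length `n_pulses`, or a scalar recycled).
#' @param field_effect Additive ln-scale effect of field 2 relative to
#'   field 1.
#' @param sigma2_between Between-animal variance of the random intercept,
#'   in (ln units)^2.
#' @param sigma2_within Within-animal residual variance, in (ln units)^2.
#' @param animals_per_agent Animals per agent (scalar, or named vector by
#'   agent). Must be >= 1 for every agent.
#' @param n_pulses Pulses per field (protocol default: 3).
#' @param lines_per_pulse Scan lines per pulse (protocol default: up to 8).
#' @param n_fields Fields per animal (1 or 2).
#' @param rng_seed Integer seed.
#' @return An `LnAucSimConfig` list.
#' @export
lnauc_sim_config <- function(cell_means = list(Saline = 0, `L-THA` = 1.741),
                             field_effect = 0,
                             sigma2_between = 1.24, sigma2_within = 4.51,
                             animals_per_agent = 6, n_pulses = 3,
                             lines_per_pulse = 8, n_fields = 1,
                             rng_seed = 1L) {
  if (sigma2_between < 0 || sigma2_within < 0) stopf("variances must be >= 0")
  if (is.null(names(cell_means)) || any(names(cell_means) == ""))
    stopf("cell_means must be a named list (one entry per agent)")
  if (!n_fields %in% 1:2) stopf("n_fields must be 1 or 2")
  agents <- names(cell_means)
  n_animals <- if (length(animals_per_agent) == 1) {
    stats::setNames(rep(animals_per_agent, length(agents)), agents)
  } else {
    animals_per_agent[agents]
  }
  if (any(is.na(n_animals)) || any(n_animals < 1))
    stopf("every agent needs >= 1 animal")
  cm <- lapply(cell_means, function(v) rep_len(as.numeric(v), n_pulses))
  structure(
    list(cell_means = cm, field_effect = field_effect,
         sigma2_between = sigma2_between, sigma2_within = sigma2_within,
         animals_per_agent = n_animals, n_pulses = n_pulses,
         lines_per_pulse = lines_per_pulse, n_fields = n_fields,
         rng_seed = as.integer(rng_seed)),
    class = "LnAucSimConfig"
  )
}

#' Simulate a per-line ln-AUC table from the random-intercept model
#'
#' Draws `y(animal, agent, field, pulse, line) = cell mean + field effect +
#' b_animal + e`, with `b ~ N(0, sigma2_between)` and
#' `e ~ N(0, sigma2_within)`, and returns the result on the ln scale with
#' full metadata columns (animal, sex, agent, field, pulse, line). Sexes
#' alternate within each agent so sex-stratified refits are exercised.
#'
#' @param config An [lnauc_sim_config()].
#' @return A data frame with columns `animal`, `sex`, `agent`, `field`,
#'   `pulse`, `line`, `ln_auc` and `auc` (`= exp(ln_auc)`).
#' @export
simulate_lnauc_table <- function(config) {
  stopifnot(inherits(config, "LnAucSimConfig"))
  agents <- names(config$cell_means)
  rows <- with_seed(config$rng_seed, {
    out <- vector("list", length(agents))
    for (ai in seq_along(agents)) {
      ag <- agents[ai]
      n_an <- config$animals_per_agent[[ag]]
      b <- stats::rnorm(n_an, 0, sqrt(config$sigma2_between))
      grid <- expand.grid(line = seq_len(config$lines_per_pulse),
                          pulse = seq_len(config$n_pulses),
                          field = seq_len(config$n_fields),
                          animal_i = seq_len(n_an))
      mu <- config$cell_means[[ag]][grid$pulse] +
        config$field_effect * (grid$field == 2) + b[grid$animal_i]
      y <- mu + stats::rnorm(nrow(grid), 0, sqrt(config$sigma2_within))
      out[[ai]] <- data.frame(
        animal = sprintf("%s_%02d", ag, grid$animal_i),
        sex = ifelse(grid$animal_i %% 2 == 1, "M", "F"),
        agent = ag, field = grid$field, pulse = grid$pulse,
        line = grid$line, ln_auc = y)
    }
    do.call(rbind, out)
  })
  rows$auc <- exp(rows$ln_auc)
  rownames(rows) <- NULL
  rows
}
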