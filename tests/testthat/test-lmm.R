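# ln-scale mixed model: variance-component recovery, contrasts,
# difference-of-differences, LRT, stratified refits and forest export.

sim_fit <- function(cell_means, n_animals = 10, s2b = 1.24, s2w = 4.51,
                    seed = 1, ...) {
  cfg <- lnauc_sim_config(cell_means = cell_means, sigma2_between = s2b,
                          sigma2_within = s2w,
                          animals_per_agent = n_animals, rng_seed = seed, ...)
  tab <- simulate_lnauc_table(cfg)
  suppressWarnings(suppressMessages(
    fit_lmm(tab, response = "ln_auc", log = FALSE)))
}

test_that("REML recovers the generating variance components", {
  vc <- rowMeans(vapply(1:4, function(s) {
    var_components(sim_fit(list(Saline = 0, `L-THA` = 1.741),
                           n_animals = 100, seed = 100 + s))
  }, numeric(2)))
  expect_lt(abs(vc[["between"]] - 1.24) / 1.24, 0.15)
  expect_lt(abs(vc[["within"]] - 4.51) / 4.51, 0.15)
})

test_that("zero-variance data reproduce cell means exactly", {
  fit <- sim_fit(list(Saline = c(0.3, 0.6, 0.9), `L-THA` = c(2, 2.5, 3)),
                 n_animals = 4, s2b = 0, s2w = 0)
  for (p in 1:3) {
    ct <- contrast(fit, "L-THA", "Saline", pulse = p)
    truth <- c(2, 2.5, 3)[p] - c(0.3, 0.6, 0.9)[p]
    expect_equal(ct$estimate_ln, truth, tolerance = 1e-8)
  }
})

test_that("duplicating every row leaves the fixed effects unchanged", {
  cfg <- lnauc_sim_config(cell_means = list(Saline = 0, `L-THA` = 1),
                          animals_per_agent = 5, rng_seed = 7)
  tab <- simulate_lnauc_table(cfg)
  f1 <- suppressMessages(fit_lmm(tab, response = "ln_auc", log = FALSE))
  f2 <- suppressMessages(fit_lmm(rbind(tab, tab), response = "ln_auc",
                                 log = FALSE))
  expect_equal(lme4::fixef(f1$model), lme4::fixef(f2$model),
               tolerance = 1e-6)
})

test_that("the degenerate one-row-per-animal contrast equals a pooled t-test", {
  set.seed(5)
  d <- data.frame(animal = sprintf("an%02d", 1:16),
                  agent = rep(c("Saline", "L-THA"), each = 8),
                  field = 1, pulse = 1,
                  auc = exp(rnorm(16, rep(c(0, 1), each = 8), 1)))
  fit <- suppressWarnings(suppressMessages(fit_lmm(d, response = "auc")))
  ct <- contrast(fit, "L-THA", "Saline", pulse = 1)
  tt <- t.test(log(auc) ~ agent, data = d, var.equal = TRUE)
  expect_equal(ct$estimate_ln, unname(-diff(tt$estimate)), tolerance = 1e-6)
  expect_equal(ct$se, tt$stderr, tolerance = 1e-6)
  expect_equal(ct$df, unname(tt$parameter), tolerance = 1e-3)
  expect_equal(ct$p, tt$p.value, tolerance = 1e-6)
})

test_that("a null contrast is exactly trivial and ratios exponentiate deltas", {
  fit <- sim_fit(list(Saline = 0, `L-THA` = 1.741), n_animals = 6, seed = 11)
  null <- contrast(fit, "Saline", "Saline")
  expect_equal(null$estimate_ln, 0)
  expect_equal(null$ratio, 1)
  expect_equal(null$p, 1)

  ct <- contrast_table(fit, "L-THA", "Saline")
  expect_equal(nrow(ct), 4)
  expect_equal(ct$pulse, c("combined", "1", "2", "3"))
  expect_equal(ct$ratio, exp(ct$estimate_ln), tolerance = 1e-12)
  expect_true(all(ct$ci_lo < ct$ratio & ct$ratio < ct$ci_hi))
  # pulse-averaged delta is the mean of the per-pulse deltas
  expect_equal(ct$estimate_ln[1], mean(ct$estimate_ln[2:4]),
               tolerance = 1e-10)
})

test_that("difference-of-differences equals its component contrasts exactly", {
  fit <- sim_fit(list(Saline = 0, `L-THA` = 1.7, DMSO = 0.6,
                      `Indo+L-THA` = 1.0),
                 n_animals = 6, seed = 13)
  dod <- dod_contrast(fit, "Indo+L-THA")
  c1 <- contrast(fit, "Indo+L-THA", "DMSO")
  c2 <- contrast(fit, "L-THA", "Saline")
  expect_equal(dod$estimate_ln, c1$estimate_ln - c2$estimate_ln,
               tolerance = 1e-10)
  expect_equal(dod$ratio, exp(dod$estimate_ln), tolerance = 1e-12)
  expect_error(dod_contrast(fit, "KB+L-THA"), "missing cell")
})

test_that("an additive agent effect yields a null difference-of-differences", {
  # agent effect constructed equal to substrate + vehicle effects
  fit <- sim_fit(list(Saline = 0, `L-THA` = 1.5, DMSO = 0.5,
                      `Indo+L-THA` = 2.0),
                 n_animals = 4, s2b = 0, s2w = 0)
  dod <- dod_contrast(fit, "Indo+L-THA")
  expect_equal(dod$estimate_ln, 0, tolerance = 1e-8)
  expect_equal(dod$ratio, 1, tolerance = 1e-8)
})

test_that("the interaction LRT is one for identical likelihoods and small for
           a strong interaction", {
  # noise orthogonal to the interaction columns and animal indicators:
  # full and reduced ML fits coincide, so the statistic is exactly zero
  set.seed(17)
  d <- expand.grid(animal = sprintf("a%02d", 1:8), pulse = factor(1:3),
                   line = 1:4)
  d$agent <- ifelse(as.integer(sub("a", "", d$animal)) <= 4,
                    "Saline", "L-THA")
  d$field <- 1
  X <- model.matrix(~ agent * pulse, d)
  Z <- model.matrix(~ 0 + animal, d)
  e <- residuals(lm(rnorm(nrow(d)) ~ 0 + cbind(X, Z)))
  d$ln_auc <- drop(X[, 1:4] %*% c(1, 0.8, 0.2, 0.4)) + e
  fit0 <- suppressWarnings(suppressMessages(
    fit_lmm(d, response = "ln_auc", log = FALSE)))
  out0 <- lrt_interaction(fit0)
  expect_equal(out0$p, 1, tolerance = 1e-6)
  expect_equal(out0$df, 2)

  # strong interaction: decisively rejected
  fit1 <- sim_fit(list(Saline = c(0, 0, 0), `L-THA` = c(0, 3, 6)),
                  n_animals = 8, seed = 19)
  out1 <- lrt_interaction(fit1)
  expect_lt(out1$p, 0.001)
})

test_that("null-interaction p-values are approximately uniform", {
  ps <- vapply(1:120, function(i) {
    fit <- sim_fit(list(Saline = 1, `L-THA` = 2), n_animals = 6,
                   seed = 400 + i, lines_per_pulse = 3)
    lrt_interaction(fit)$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("subset refits reproduce the full fit and demand two animals", {
  cfg <- lnauc_sim_config(cell_means = list(Saline = 0, `L-THA` = 1.741),
                          animals_per_agent = 6, rng_seed = 23)
  tab <- simulate_lnauc_table(cfg)
  fit <- suppressMessages(fit_lmm(tab, response = "ln_auc", log = FALSE))
  refit <- subset_refit(fit, tab, sex = c("M", "F"))
  expect_equal(lme4::fixef(refit$model), lme4::fixef(fit$model),
               tolerance = 1e-8)

  # males and females generated identically: ratios agree within MC error
  rm <- contrast(subset_refit(fit, tab, sex = "M"), "L-THA", "Saline")
  rf <- contrast(subset_refit(fit, tab, sex = "F"), "L-THA", "Saline")
  expect_lt(abs(rm$estimate_ln - rf$estimate_ln),
            3 * sqrt(rm$se^2 + rf$se^2))

  one <- tab[tab$animal == tab$animal[1], ]
  expect_error(subset_refit(fit, one), "2 animals")
  expect_error(subset_refit(fit, tab, agents = "nope"), "empty")
})

test_that("forest tables are tidy and survive a CSV round-trip", {
  fit <- sim_fit(list(Saline = 0, `L-THA` = 1.741), n_animals = 6, seed = 29)
  null <- contrast(fit, "Saline", "Saline")
  f1 <- export_forest(null)
  expect_equal(nrow(f1), 1)
  expect_equal(f1$ratio, 1)

  tab <- export_forest(contrast_table(fit, "L-THA", "Saline"))
  expect_equal(names(tab), c("label", "pulse", "ratio", "ci_lo", "ci_hi", "p"))
  expect_equal(nrow(tab), 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  back <- read.csv(path, colClasses = c(pulse = "character"))
  expect_equal(back, tab, tolerance = 1e-12)
})

test_that("model fitting validates its inputs", {
  d <- data.frame(animal = "a1", agent = "Saline", field = 1, pulse = 1,
                  auc = 1)
  expect_error(fit_lmm(d), "2 animals")
  d2 <- data.frame(animal = c("a1", "a2"), agent = "Saline", field = 1,
                   pulse = 1, auc = c(1, -1))
  expect_error(fit_lmm(d2), "positive")
  expect_error(fit_lmm(data.frame(x = 1)), "missing columns")
})
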