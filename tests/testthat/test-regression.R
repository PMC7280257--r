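# OLS fitting, cross-validation, selection, exclusion scan, outlier screen.

test_that("fit_mlr matches the normal-equation oracle on random datasets", {
  for (seed in 1:10) {
    n <- sample(8:20, 1)
    sim <- random_dataset(n, p = 3, seed = seed)
    preds <- setdiff(names(sim$coefficients), "intercept")
    fit <- fit_mlr(sim$dataset, model_spec(predictors = preds))
    ref <- normal_equation_fit(sim$dataset, preds)
    expect_equal(unname(fit$coefficients), unname(ref$coefficients),
                 tolerance = 1e-10)
    expect_equal(unname(fit$residuals), unname(ref$residuals),
                 tolerance = 1e-10)
  }
})

test_that("a 4-point single-predictor fit solves the normal equations by hand", {
  d <- affinity_dataset(data.frame(
    complex_id = paste0("P", 1:4), ligand = paste0("L", 1:4),
    log_ki = c(1, 3, 2, 5), binding_energy = c(10, 20, 30, 40),
    e_elstat = 0, e_exch = 0, e_ct = 0, e_disp = 0))
  fit <- fit_mlr(d, model_spec(predictors = "binding_energy"))
  # hand-solved: slope = Sxy/Sxx, intercept = ybar - slope*xbar
  x <- c(10, 20, 30, 40); y <- c(1, 3, 2, 5)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(unname(fit$coefficients),
               c(mean(y) - slope * mean(x), slope))
})

test_that("an exactly linear response is interpolated with 100% recovery", {
  sim <- make_linear_dataset(12, noise_sd = 0, seed = 4)
  preds <- setdiff(names(sim$coefficients), "intercept")
  fit <- fit_mlr(sim$dataset, model_spec(predictors = preds))
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
  expect_equal(fit$pct_recovered, 100, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients),
               unname(sim$coefficients[c("intercept", preds)]),
               tolerance = 1e-10)
})

test_that("intercept models have zero-sum residuals orthogonal to predictors", {
  for (seed in 1:5) {
    sim <- random_dataset(15, p = 4, seed = seed + 100)
    preds <- setdiff(names(sim$coefficients), "intercept")
    fit <- fit_mlr(sim$dataset, model_spec(predictors = preds))
    scale <- max(abs(sim$dataset$log_ki))
    expect_lt(abs(sum(fit$residuals)), 1e-10 * 15 * scale)
    for (p in preds) {
      expect_lt(abs(sum(fit$residuals * sim$dataset[[p]])), 1e-7)
    }
    expect_gte(fit$pct_recovered, 0)
    expect_lte(fit$pct_recovered, 100)
    expect_lte(fit$ssq_residual, fit$ssq_data)
  }
})

test_that("single-predictor %SSQ recovered equals the squared correlation", {
  d <- affinity_dataset(reference_table())
  fit <- fit_mlr(d, "M1")
  expect_equal(fit$pct_recovered,
               100 * cor(d$log_ki, d$binding_energy)^2)
})

test_that("degenerate designs raise singular/insufficient-data errors", {
  d <- affinity_dataset(reference_table())
  d$e_ct <- 2 * d$e_exch # collinear
  expect_error(fit_mlr(d, "M3"), "singular design")
  expect_error(model_spec(predictors = c("e_ct", "e_ct")), "duplicated")
  small <- affinity_dataset(reference_table()[1:6, ])
  expect_error(fit_mlr(small, "M3"), "insufficient data")
})

test_that("LOO equals explicit per-fold refits and is exact for noiseless data", {
  d <- affinity_dataset(data.frame(
    complex_id = paste0("P", 1:5), ligand = paste0("L", 1:5),
    log_ki = c(2.0, 1.1, 3.7, 0.4, 2.9), binding_energy = c(5, 11, 19, 2, 14),
    e_elstat = 0, e_exch = 0, e_ct = 0, e_disp = 0))
  loo <- loo_cv(d, model_spec(predictors = "binding_energy"))
  manual <- vapply(1:5, function(i) {
    f <- lm(log_ki ~ binding_energy, data = d[-i, ])
    unname(d$log_ki[i] - predict(f, d[i, ]))
  }, numeric(1))
  expect_equal(loo$folds$sq_error, manual^2)
  expect_equal(loo$press, sum(manual^2))
  # PRESS shortcut from the full fit is an independent check
  full <- lm(log_ki ~ binding_energy, data = d)
  expect_equal(loo$press,
               sum((resid(full) / (1 - hatvalues(full)))^2))

  sim <- make_linear_dataset(15, noise_sd = 0, seed = 8)
  preds <- setdiff(names(sim$coefficients), "intercept")
  loo0 <- loo_cv(sim$dataset, model_spec(predictors = preds))
  expect_equal(loo0$q2, 1, tolerance = 1e-8)
})

test_that("singular training folds are reported with the fold name", {
  # removing P4 leaves e_exch collinear with binding_energy
  d <- data.frame(
    complex_id = paste0("P", 1:4), ligand = paste0("L", 1:4),
    log_ki = c(1, 2, 3, 4), binding_energy = c(1, 2, 3, 4),
    e_elstat = 0, e_exch = c(2, 4, 6, 9), e_ct = 0, e_disp = 0)
  expect_error(
    loo_cv(affinity_dataset(d),
           model_spec(predictors = c("binding_energy", "e_exch"))),
    "leaving out P4")
})

test_that("q2_with_exclusion handles identity, subset and error cases", {
  d <- affinity_dataset(reference_table())
  loo <- loo_cv(d, "M3")
  expect_identical(q2_with_exclusion(loo, d, character(0)), loo$q2)
  expect_error(q2_with_exclusion(loo, d, d$complex_id), "every point")
  expect_error(q2_with_exclusion(loo, d, "NOPE"), "unknown complex")
  # excluding the worst fold must help when its error dominates its SSQ share
  worst <- loo$folds$complex_id[which.max(loo$folds$sq_error)]
  expect_gt(q2_with_exclusion(loo, d, worst), loo$q2)
})

test_that("backward elimination keeps all five descriptors on the reference data", {
  d <- affinity_dataset(reference_table())
  bwd <- variable_selection(d, direction = "backward", alpha = 0.05)
  expect_setequal(bwd$selected, c("binding_energy", "e_elstat", "e_exch",
                                  "e_ct", "e_disp"))
  fit <- fit_mlr(d, "M3")
  expect_true(all(fit$p_values[bwd$selected] < 0.05))
  # vacuous threshold: nothing can be dropped
  expect_setequal(variable_selection(d, direction = "backward",
                                     alpha = 1)$selected,
                  bwd$selected)
})

test_that("forward selection requires marginal significance to enter", {
  # on the reference data no single descriptor is significant alone, so the
  # forward pass stops at the empty model (a legal outcome)
  d <- affinity_dataset(reference_table())
  fwd <- variable_selection(d, direction = "forward", alpha = 0.05)
  expect_length(fwd$selected, 0)
  expect_equal(fwd$steps$action[1], "stop")
})

test_that("selection recovers a planted irrelevant column on synthetic data", {
  sim <- make_linear_dataset(
    120, coefficients = c(intercept = 2, binding_energy = 0.05, noise = 0),
    predictor_ranges = list(binding_energy = c(20, 240), noise = c(0, 10)),
    noise_sd = 0.5, seed = 77)
  fwd <- variable_selection(sim$dataset,
                            candidates = c("binding_energy", "noise"),
                            direction = "forward", alpha = 0.05)
  expect_equal(fwd$selected, "binding_energy")
  bwd <- variable_selection(sim$dataset,
                            candidates = c("binding_energy", "noise"),
                            direction = "backward", alpha = 0.05)
  expect_equal(bwd$selected, "binding_energy")
})

test_that("the exclusion scan quantifies each predictor's contribution", {
  d <- affinity_dataset(reference_table())
  scan <- exclusion_scan(d, "M3")
  expect_equal(nrow(scan), 5)
  expect_gte(min(scan$drop_pct), 27)
  # construction: y depends only on predictor A
  sim <- make_linear_dataset(
    30, coefficients = c(intercept = 1, binding_energy = 0.05, e_disp = 0),
    noise_sd = 0, seed = 12)
  sc <- exclusion_scan(sim$dataset,
                       model_spec(predictors = c("binding_energy", "e_disp")))
  # full model is exact (100%); without A only the incidental correlation
  # with B remains
  r2_b <- 100 * cor(sim$dataset$log_ki, sim$dataset$e_disp)^2
  expect_equal(sc$drop_pct[sc$excluded == "e_disp"], 0, tolerance = 1e-6)
  expect_equal(sc$drop_pct[sc$excluded == "binding_energy"], 100 - r2_b,
               tolerance = 1e-6)
  expect_error(exclusion_scan(d, model_spec(predictors = "e_ct")),
               "at least two")
})

test_that("the commensurability screen flags a planted off-model point", {
  # two predictors so each 7-point sub-fit keeps residual degrees of freedom
  # that an off-model point cannot hide in
  coefs <- c(intercept = 2, binding_energy = -0.02, e_disp = 0.05)
  preds <- c("binding_energy", "e_disp")
  sim <- make_linear_dataset(8, coefficients = coefs, noise_sd = 0, seed = 3,
                             outlier_index = 5, outlier_shift = 5)
  rep <- commensurability_screen(sim$dataset, model_spec(predictors = preds))
  expect_equal(rep$flagged, sim$dataset$complex_id[5])
  expect_equal(nrow(rep$table), 8)

  clean <- make_linear_dataset(8, coefficients = coefs, noise_sd = 0, seed = 3)
  rep0 <- commensurability_screen(clean$dataset,
                                  model_spec(predictors = preds))
  expect_length(rep0$flagged, 0)

  too_small <- make_linear_dataset(4, coefficients = coefs, noise_sd = 0,
                                   seed = 3)
  expect_error(commensurability_screen(too_small$dataset,
                                       model_spec(predictors = preds)),
               "insufficient data")
})
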