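test_that("ps_method1 evaluates the empirical formula", {
  # f0 = foN, SPL = 88.5 -> 1.2 kPa
  expect_equal(ps_method1(88.5, 120, foN = 120), kpa_to_cmh2o(1.2),
               tolerance = 1e-12)
  # exponent = 1: 0.14 + 0.06 + 10 = 10.2 kPa
  expect_equal(ps_method1(88.5 + 27.3, 190, sex = "female"),
               kpa_to_cmh2o(10.2), tolerance = 1e-12)
  # vanishing exponential term at very low SPL
  expect_equal(ps_method1(-400, 150, foN = 120),
               kpa_to_cmh2o(0.14 + 0.06 * (150 / 120)^2), tolerance = 1e-9)
  # strictly increasing in SPL and f0 over a grid
  spl_grid <- seq(40, 120, by = 2)
  f0_grid <- seq(80, 400, by = 10)
  for (f0 in c(100, 200, 350)) {
    expect_true(all(diff(ps_method1(spl_grid, f0, foN = 120)) > 0))
  }
  for (spl in c(55, 75, 95)) {
    expect_true(all(diff(ps_method1(spl, f0_grid, foN = 190)) > 0))
  }
})

test_that("kpa_to_cmh2o conversion constants", {
  expect_equal(kpa_to_cmh2o(0), 0)
  expect_equal(kpa_to_cmh2o(1), 10.1972)
  expect_equal(kpa_to_cmh2o(0.0980665), 1.0, tolerance = 1e-4)
})

test_that("method 2 recovery: exact when noiseless, unbiased under noise", {
  d0 <- simulate_method2_data(n = 20, slope = 2, intercept = 3, sigma = 0,
                              seed = 1)
  m0 <- fit_method2(d0$acc_rms, d0$ps_ref)
  expect_equal(m0$slope, 2, tolerance = 1e-12)
  expect_equal(m0$intercept, 3, tolerance = 1e-12)
  expect_equal(rmse_ps(predict_method2(m0, d0$acc_rms), d0$ps_ref), 0,
               tolerance = 1e-10)
  slopes <- vapply(1:100, function(s) {
    d <- simulate_method2_data(n = 60, slope = 2, intercept = 3, sigma = 0.5,
                               seed = s)
    fit_method2(d$acc_rms, d$ps_ref)$slope
  }, numeric(1))
  expect_lt(abs(median(slopes) / 2 - 1), 0.05)
  expect_error(fit_method2(rep(1, 12), rnorm(12)), "zero variance")
})

test_that("stepwise selection finds planted features and rejects decoys", {
  hits <- vapply(1:40, function(s) {
    sim <- simulate_feature_table(n = 60, coefs = c(rms = 2), sigma = 0.5,
                                  seed = s)
    m <- fit_method3_stepwise(sim$features, sim$ps_ref)
    "rms" %in% m$selected_features
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # two informative features: both found; decoys at ~per-decoy alpha rate
  res <- lapply(1:40, function(s) {
    sim <- simulate_feature_table(n = 60, coefs = c(rms = 0.8, oq = 0.25),
                                  sigma = 0.5, seed = 1000 + s)
    m <- fit_method3_stepwise(sim$features, sim$ps_ref)
    list(both = all(c("rms", "oq") %in% m$selected_features),
         decoys = length(setdiff(m$selected_features, c("rms", "oq"))))
  })
  expect_gte(mean(vapply(res, `[[`, logical(1), "both")), 0.9)
  expect_lte(mean(vapply(res, `[[`, numeric(1), "decoys")), 1.5)
  # all-noise features -> intercept-only with warning (most seeds)
  n_sel <- vapply(1:40, function(s) {
    sim <- simulate_feature_table(n = 60, coefs = c(), sigma = 1,
                                  seed = 2000 + s)
    m <- suppressWarnings(fit_method3_stepwise(sim$features, sim$ps_ref))
    length(m$selected_features)
  }, numeric(1))
  # per-decoy false inclusion <= ~alpha (10 decoys)
  expect_lte(mean(n_sel) / 10, 0.05 * 2)
})

test_that("stepwise selection is invariant to feature column order", {
  sim <- simulate_feature_table(n = 60, coefs = c(rms = 0.8, oq = 0.25),
                                sigma = 0.5, seed = 17)
  m1 <- fit_method3_stepwise(sim$features, sim$ps_ref)
  m2 <- fit_method3_stepwise(sim$features[, rev(colnames(sim$features))],
                             sim$ps_ref)
  expect_identical(m1$selected_features, m2$selected_features)
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-12)
})

test_that("cross-validation partitions correctly and picks the best fold", {
  sim <- simulate_feature_table(n = 63, coefs = c(rms = 2), sigma = 0.4,
                                seed = 5)
  cv <- crossvalidate_method3(sim$features, sim$ps_ref, k = 5, seed = 2)
  tab <- table(cv$folds)
  expect_equal(sum(tab), 63)
  expect_lte(diff(range(tab)), 1)
  expect_equal(cv$chosen_fold, which.min(cv$fold_rmses))
  # noiseless linear ground truth: every fold RMSE ~ 0
  sim0 <- simulate_feature_table(n = 40, coefs = c(rms = 2), sigma = 0,
                                 seed = 6)
  cv0 <- crossvalidate_method3(sim0$features, sim0$ps_ref, seed = 3)
  expect_lt(max(cv0$fold_rmses), 1e-8)
  expect_equal(unname(cv0$coefficients["rms"]), 2, tolerance = 1e-8)
  # fewer-folds fallback warns
  sim_small <- simulate_feature_table(n = 18, coefs = c(rms = 2), seed = 7)
  expect_warning(crossvalidate_method3(sim_small$features, sim_small$ps_ref),
                 "folds")
})

test_that("predict_ps contracts", {
  m <- structure(list(selected_features = "rms",
                      coefficients = c(rms = 2), intercept = 3,
                      alpha = 0.05, n = 30),
                 class = "ps_stepwise_model")
  expect_equal(predict_ps(m, data.frame(rms = 5)), 13)
  m0 <- structure(list(selected_features = character(0),
                       coefficients = numeric(0), intercept = 7.5,
                       alpha = 0.05, n = 30),
                  class = "ps_stepwise_model")
  expect_equal(predict_ps(m0, data.frame(rms = 1:3)), rep(7.5, 3))
  expect_error(predict_ps(m, data.frame(oq = 1)), "missing feature")
})

test_that("model JSON round trip", {
  sim <- simulate_feature_table(n = 40, coefs = c(rms = 1.5, cpp = 0.3),
                                sigma = 0.2, seed = 8)
  cv <- crossvalidate_method3(sim$features, sim$ps_ref, seed = 4)
  p <- file.path(tempdir(), "model.json")
  write_ps_model(cv, p)
  back <- read_ps_model(p)
  expect_equal(predict_ps(back, sim$features), predict_ps(cv, sim$features),
               tolerance = 1e-9)
  m2 <- fit_method2(1:12, 2 * (1:12) + 3)
  write_ps_model(m2, p)
  expect_equal(predict_method2(read_ps_model(p), 4), 11, tolerance = 1e-9)
  unlink(p)
})
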