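test_that("noise-free responses are perfectly reproducible", {
  cfg <- adaptation_config(n_cells = 10, sigma = 1e-12, d = 1, seed = 2)
  out <- generate_peak_table(cfg, compute_truth = FALSE)
  cc <- consecutive_correlation(out$peaks)
  expect_equal(cc$r, 1, tolerance = 1e-6)
  expect_equal(cc$slope, 1, tolerance = 1e-6)
})

test_that("the regression slope tracks the desensitization factor", {
  # small near-Gaussian noise: OLS attenuation (errors-in-x) stays well
  # below the 0.005 margin around the true factor d = 0.99
  cfg <- adaptation_config(n_cells = 25, n_pulses = 20, sigma = 0.01,
                           nu = 30, d = 0.99, seed = 4)
  out <- generate_peak_table(cfg, compute_truth = FALSE)
  cc <- consecutive_correlation(out$peaks)
  expect_gt(cc$slope, 0.985)
  expect_lt(cc$slope, 0.995)
  expect_gt(cc$r, 0.99)
  expect_lt(cc$p_slope_eq_1, 0.05)
})

test_that("permuting responses within cells destroys the correlation", {
  cfg <- adaptation_config(n_cells = 40, n_pulses = 20, sigma = 0.3,
                           nu = 30, d = 1, seed = 6)
  out <- generate_peak_table(cfg, compute_truth = FALSE)
  pk <- out$peaks[order(out$peaks$cell_id, out$peaks$pulse_index), ]
  # remove between-cell differences, then shuffle within cells
  res <- compute_residuals(pk)
  pk$peak_log_response <- res$residual
  set.seed(8)
  pk$peak_log_response <- unlist(lapply(split(pk$peak_log_response,
                                              pk$cell_id), sample))
  cc <- consecutive_correlation(pk)
  expect_gte(cc$n_pairs, 500)
  expect_lt(abs(cc$r), 0.1)
})

test_that("noiseless decay yields exactly 1 percent per pulse and 18.2 over 20", {
  cfg <- adaptation_config(n_cells = 5, n_pulses = 20, sigma = 1e-12,
                           d = 0.99, seed = 3)
  out <- generate_peak_table(cfg, compute_truth = FALSE)
  fit <- fit_decay(out$peaks)
  expect_equal(fit$decay_percent, 1.0, tolerance = 1e-6)
  expect_equal(fit$drop_20_pulses_percent, 100 * (1 - 0.99^20),
               tolerance = 1e-6)
  expect_equal(100 * (1 - 0.99^20), 18.2, tolerance = 0.05)
})

test_that("without adaptation the decay CI covers zero", {
  cfg <- adaptation_config(n_cells = 25, n_pulses = 20, sigma = 0.1,
                           d = 1, seed = 10)
  out <- generate_peak_table(cfg, compute_truth = FALSE)
  fit <- fit_decay(out$peaks)
  expect_lte(fit$decay_ci_percent[1], 0)
  expect_gte(fit$decay_ci_percent[2], 0)
})

test_that("decay estimation recovers the generator truth under heavy noise", {
  cfg <- adaptation_config(n_cells = 433, n_pulses = 20, sigma = 0.1,
                           nu = 5, d = 0.99, seed = 12)
  out <- generate_peak_table(cfg, compute_truth = FALSE)
  fit <- fit_decay(out$peaks)
  expect_gt(fit$decay_percent, 0.85)
  expect_lt(fit$decay_percent, 1.15)
  expect_lt(fit$p_value, 1e-6)
  # pooled-intercept variant is also available
  pooled <- fit_decay(out$peaks, per_cell_intercepts = FALSE)
  expect_true(is.finite(pooled$decay_percent))
})

test_that("correlation is invariant under common rescaling of responses", {
  cfg <- adaptation_config(n_cells = 20, sigma = 0.1, d = 0.99, seed = 14)
  out <- generate_peak_table(cfg, compute_truth = FALSE)
  cc1 <- consecutive_correlation(out$peaks)
  pk2 <- out$peaks
  pk2$peak_log_response <- pk2$peak_log_response + log(3.5)  # x3.5 linear
  cc2 <- consecutive_correlation(pk2)
  expect_equal(cc1$r, cc2$r, tolerance = 1e-12)
})

test_that("median-residual correction removes pure multiplicative decay", {
  cfg <- adaptation_config(n_cells = 5, n_pulses = 20, sigma = 1e-12,
                           d = 0.99, seed = 5)
  out <- generate_peak_table(cfg, compute_truth = FALSE)
  corr <- adaptation_correct(out$peaks)
  spread <- tapply(corr$peak_log_response, corr$cell_id,
                   function(x) diff(range(x)))
  expect_lt(max(spread), 1e-6)
  # idempotence
  corr2 <- adaptation_correct(corr)
  expect_lt(max(abs(corr2$peak_log_response - corr$peak_log_response)),
            1e-8)
  # decay disappears after correction
  fit <- fit_decay(corr)
  expect_lte(fit$decay_ci_percent[1], 1e-6)
  expect_gte(fit$decay_ci_percent[2], -1e-6)
})

test_that("correction is a near no-op when there is no adaptation", {
  cfg <- adaptation_config(n_cells = 60, n_pulses = 20, sigma = 0.1,
                           nu = 5, d = 1, seed = 16)
  out <- generate_peak_table(cfg, compute_truth = FALSE)
  corr <- adaptation_correct(out$peaks)
  shifts <- attr(corr, "corrections")$residual
  sem <- 0.1 * sqrt(5 / 3) / sqrt(60)   # rough scaled-t(0.1, nu=5) sem
  expect_lt(max(abs(shifts)), 4 * sem)
  expect_lt(max(abs(corr$peak_log_response - out$peaks$peak_log_response)),
            4 * sem)
})

test_that("correction raises the population capacity of an adapted dataset", {
  cfg <- small_population(n_cells = 15, seed = 19, d = 0.98)
  out <- generate_peak_table(cfg, compute_truth = FALSE)
  raw <- out$peaks
  corr <- adaptation_correct(raw)
  est_raw <- estimate_population_capacity(
    raw, fit_noise_model(raw), cfg$design, mode = "lower_bound")
  est_corr <- estimate_population_capacity(
    corr, fit_noise_model(corr), cfg$design, mode = "lower_bound")
  expect_gt(mean(est_corr$lower_bound_bits), mean(est_raw$lower_bound_bits))
})

test_that("degenerate inputs are rejected", {
  one_pulse <- data.frame(cell_id = 1:5, concentration_nM = 250,
                          replicate = 1, pulse_index = 1,
                          peak_log_response = rnorm(5), qc_flag = "ok")
  expect_error(fit_decay(one_pulse), "pulse index")
  expect_error(consecutive_correlation(one_pulse), "pairs")
})
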