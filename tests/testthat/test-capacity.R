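test_that("mutual information is zero when the output ignores the input", {
  m <- channel_model(c(1.3, 1.3, 1.3), 0.2, 5)
  expect_lt(mutual_information(m, rep(1 / 3, 3)), 1e-6)
  expect_lt(optimize_input_distribution(m)$bits, 1e-6)
})

test_that("a perfectly separable binary channel carries one bit", {
  m <- channel_model(c(0, 100), 1, 30)
  expect_equal(mutual_information(m, c(0.5, 0.5)), 1, tolerance = 1e-3)
})

test_that("quadrature MI matches a Monte-Carlo estimate", {
  # Gaussian-limit noise, means two scales apart
  sigma <- 0.5
  m <- channel_model(c(0, 2 * sigma), sigma, 200)
  I_quad <- mutual_information(m, c(0.5, 0.5))
  set.seed(123)
  n <- 2e6
  cidx <- sample(1:2, n, replace = TRUE)
  mu <- c(0, 2 * sigma)[cidx]
  r <- mu + rscaled_t(n, sigma, 200)
  f1 <- dscaled_t(r - 0, sigma, 200)
  f2 <- dscaled_t(r - 2 * sigma, sigma, 200)
  fc <- ifelse(cidx == 1, f1, f2)
  I_mc <- mean(log2(fc / (0.5 * f1 + 0.5 * f2)))
  expect_lt(abs(I_quad - I_mc), 0.005)
})

test_that("a mirror-symmetric channel has the uniform optimal input", {
  m <- channel_model(c(-1, 1), 0.8, 4)
  o <- optimize_input_distribution(m)
  expect_lt(max(abs(o$p - 0.5)), 1e-3)
  expect_gte(o$bits, mutual_information(m, c(0.5, 0.5)) - 1e-9)
})

test_that("Blahut-Arimoto matches exhaustive simplex search on a 3-input channel", {
  m <- channel_model(c(0, 0.6, 2.5), c(0.4, 0.3, 0.5), c(3, 8, 30))
  o <- optimize_input_distribution(m)
  expect_true(o$converged)
  expect_lt(abs(o$bits - grid_search_capacity(m, by = 0.01)), 1e-3)
})

test_that("the Blahut-Arimoto objective is non-decreasing", {
  for (m in list(channel_model(c(0, 1), 0.5, 5),
                 channel_model(c(0, 0.3, 1.7), c(0.2, 0.6, 0.3),
                               c(2, 10, 50)))) {
    o <- optimize_input_distribution(m, trace = TRUE)
    expect_true(all(diff(o$objective_trace) >= -1e-12))
  }
})

test_that("capacity never exceeds the log2 ceiling of the support size", {
  set.seed(17)
  for (rep in 1:5) {
    mu <- sort(rnorm(7, sd = 2))
    m <- channel_model(mu, runif(7, 0.05, 0.5), runif(7, 1, 50))
    o <- optimize_input_distribution(m)
    expect_gte(o$bits, 0)
    expect_lte(o$bits, log2(7) + 1e-9)
  }
})

test_that("capacity is invariant under a common shift of the means", {
  m1 <- channel_model(c(0, 0.5, 1.8), c(0.3, 0.2, 0.25), c(4, 6, 12))
  m2 <- channel_model(c(0, 0.5, 1.8) + 3.7, c(0.3, 0.2, 0.25), c(4, 6, 12))
  expect_equal(optimize_input_distribution(m1)$bits,
               optimize_input_distribution(m2)$bits, tolerance = 1e-4)
})

test_that("capacity is non-increasing in the noise scale", {
  mu <- c(0, 0.5, 1.8)
  sg <- c(0.3, 0.2, 0.25)
  caps <- vapply(c(1, 2, 4), function(lam) {
    optimize_input_distribution(channel_model(mu, lam * sg, c(4, 6, 12)))$bits
  }, numeric(1))
  expect_true(all(diff(caps) <= 1e-4))
})

test_that("interpolation reproduces knots and stays between them", {
  des <- stimulus_design()
  noise <- data.frame(concentration_nM = des$concentrations_nM,
                      sigma = c(0.30, 0.28, 0.24, 0.20, 0.16, 0.12, 0.10),
                      nu = c(3, 3, 4, 5, 6, 8, 10))
  prof <- data.frame(concentration_nM = des$concentrations_nM,
                     mu = c(-3, -2.8, -2, -1, -0.2, 0.1, 0.2))
  m <- interpolate_params(des, noise, prof, M = 101)
  # knot identity: the tested concentrations are support points with the
  # exact knot parameter values
  at <- vapply(des$concentrations_nM,
               function(cc) which.min(abs(m$support - cc)), integer(1))
  expect_lt(max(abs(m$support[at] - des$concentrations_nM) /
                des$concentrations_nM), 1e-9)
  expect_equal(m$mu[at], prof$mu)
  expect_equal(m$sigma[at], noise$sigma)
  expect_equal(m$nu[at], noise$nu)
  # log-midpoint between c2 and c3 carries the arithmetic mean of the knots
  mid <- sqrt(250 * 500)
  q <- stats::approx(log10(des$concentrations_nM), prof$mu,
                     xout = log10(mid))$y
  expect_equal(q, mean(prof$mu[2:3]))
  # piecewise-linear boundedness for the monotone sigma sequence
  expect_true(all(m$sigma <= max(noise$sigma) & m$sigma >= min(noise$sigma)))
  for (k in seq_len(6)) {
    seg <- m$support >= des$concentrations_nM[k] &
      m$support <= des$concentrations_nM[k + 1]
    expect_true(all(m$sigma[seg] <= max(noise$sigma[k:(k + 1)]) + 1e-12))
    expect_true(all(m$sigma[seg] >= min(noise$sigma[k:(k + 1)]) - 1e-12))
  }
  expect_error(interpolate_params(des, noise, prof, M = 2), "M must be")
})

test_that("flat cells have zero capacity and missing noise is an error", {
  des <- stimulus_design()
  noise <- data.frame(concentration_nM = des$concentrations_nM,
                      sigma = 0.2, nu = 5)
  pk <- data.frame(cell_id = 1,
                   concentration_nM = rep(des$concentrations_nM, each = 5),
                   replicate = rep(1:5, 7),
                   pulse_index = 1:35,
                   peak_log_response = 1.0,
                   qc_flag = "ok")
  est <- estimate_cell_capacity(pk, noise, des, mode = "both")
  expect_lt(est$lower_bound_bits, 1e-3)
  expect_lt(est$interpolated_bits, 1e-3)
  expect_error(
    estimate_cell_capacity(pk, noise[1:3, ], des),
    "no noise parameters")
})

test_that("both modes recover the true capacity of a known cell", {
  cfg <- small_population(n_cells = 2, seed = 42, d = 1)
  out <- generate_peak_table(cfg, compute_truth = TRUE)
  des <- cfg$design
  for (i in 1:2) {
    # exact profile and noise: estimation should match the independent truth
    pk <- data.frame(cell_id = i,
                     concentration_nM = rep(des$concentrations_nM, each = 2),
                     replicate = rep(1:2, 7),
                     pulse_index = seq_len(14),
                     peak_log_response = rep(out$truth$mu[i, ], each = 2),
                     qc_flag = "ok")
    est <- estimate_cell_capacity(pk, cfg$noise, des, mode = "both")
    expect_lt(abs(est$lower_bound_bits -
                  out$truth$true_capacity_discrete_bits[i]), 0.02)
    expect_lt(abs(est$interpolated_bits -
                  out$truth$true_capacity_interpolated_bits[i]), 0.02)
    expect_gte(est$interpolated_bits, est$lower_bound_bits - 1e-3)
  }
})

test_that("interpolated estimates exceed lower bounds across a population", {
  cfg <- small_population(n_cells = 10, seed = 3)
  out <- generate_peak_table(cfg, compute_truth = FALSE)
  noise <- fit_noise_model(out$peaks)
  est <- estimate_population_capacity(out$peaks, noise, cfg$design)
  expect_true(all(est$interpolated_bits >= est$lower_bound_bits - 1e-3))
  expect_gt(mean(est$interpolated_bits), mean(est$lower_bound_bits))
  expect_true(all(est$lower_bound_bits >= 0 &
                  est$lower_bound_bits <= log2(7) + 1e-9))
})

test_that("capacity is insensitive to the interpolation grid size", {
  cfg <- small_population(n_cells = 1, seed = 42, d = 1)
  out <- generate_peak_table(cfg, compute_truth = FALSE)
  des <- cfg$design
  prof <- data.frame(concentration_nM = des$concentrations_nM,
                     mu = out$truth$mu[1, ])
  caps <- vapply(c(51, 101, 201), function(M) {
    m <- interpolate_params(des, cfg$noise, prof, M = M)
    optimize_input_distribution(m)$bits
  }, numeric(1))
  expect_lt(max(caps) - min(caps), 0.02)
})

test_that("EC50 follows the half-maximum crossing in log space", {
  des <- stimulus_design()
  prof <- data.frame(concentration_nM = des$concentrations_nM,
                     mu = c(0, 0, 0.5, 1, 1, 1, 1))
  expect_equal(estimate_ec50(prof), 500, tolerance = 1e-9)
  # crossing midway (in log space) between 250 and 500
  prof2 <- data.frame(concentration_nM = des$concentrations_nM,
                      mu = c(0, 0.25, 0.75, 1, 1, 1, 1))
  expect_equal(estimate_ec50(prof2), sqrt(250 * 500), tolerance = 1e-6)
  flat <- data.frame(concentration_nM = des$concentrations_nM, mu = 1)
  expect_error(estimate_ec50(flat), "flat")
})

test_that("population summary reports mean, sd and histogram", {
  one <- data.frame(cell_id = 1, lower_bound_bits = 2.0,
                    interpolated_bits = 2.0, ec50_nM = NA,
                    n_concentrations = 7, converged = TRUE)
  s1 <- summarize_population(one)
  expect_equal(s1$interpolated$mean, 2.0)
  expect_equal(s1$interpolated$sd, 0)
  expect_true(s1$interpolated$single_cell)
  two <- rbind(one, transform(one, cell_id = 2, lower_bound_bits = 1.5,
                              interpolated_bits = 1.5))
  two$interpolated_bits <- c(1.5, 2.5)
  s2 <- summarize_population(two)
  expect_equal(s2$interpolated$mean, 2.0)
  expect_equal(s2$interpolated$sd, sd(c(1.5, 2.5)))
  expect_equal(sum(s2$interpolated$hist_counts), 2)
})
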