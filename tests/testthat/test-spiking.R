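test_that("temporal resolution formula scales as documented", {
  # in-vivo CA1-like values: same order as the 5-10 ms in-vitro window
  invivo <- lif_params(tau_m_ms = 20, sigma_v_mV = 2, psp_amp_mV = 15,
                       v_thresh_mV = -54)
  dt <- temporal_resolution(invivo)
  expect_gt(dt, 1)
  expect_lt(dt, 10)

  # scaling: linear in sigma_v and tau_m, inverse in psp amplitude
  base <- lif_params()
  d0 <- temporal_resolution(base)
  expect_equal(temporal_resolution(lif_params(sigma_v_mV = 2)), 2 * d0)
  expect_equal(temporal_resolution(lif_params(tau_m_ms = 20)), 2 * d0)
  expect_equal(temporal_resolution(lif_params(psp_amp_mV = 16)), d0 / 2)
  expect_gt(d0, 0)
  expect_error(temporal_resolution(lif_params(sigma_v_mV = 0)), "positive")
})

test_that("poisson_train is seeded, rate-faithful and refractory-aware", {
  expect_length(poisson_train(function(t) 0 * t, 10, seed = 1), 0)

  n <- length(poisson_train(function(t) rep(20, length(t)), 100, seed = 2))
  expect_lt(abs(n - 2000), 4 * sqrt(2000))

  t1 <- poisson_train(function(t) rep(10, length(t)), 50, seed = 3)
  t2 <- poisson_train(function(t) rep(10, length(t)), 50, seed = 3)
  expect_identical(t1, t2)

  expect_error(poisson_train(function(t) rep(-1, length(t)), 1), "negative")

  tr <- poisson_train(function(t) rep(100, length(t)), 60, seed = 4,
                      refractory_ms = 15)
  expect_true(all(diff(tr) >= 0.015 - 1e-12))
})

test_that("coincidence rule implements AND / OR limits and toy windows", {
  a <- c(1, 5, 9) / 1000
  b <- c(1.2, 20) / 1000
  # theta = 1: both inputs must hit the same 1 ms window
  out <- coincidence_train(list(a, b), theta = 1, delta_t_ms = 1)
  expect_length(out, 1)
  expect_lt(abs(out - 0.0015), 1e-9) # window [1, 2) ms, centre 1.5 ms

  # theta -> 1/n: logical OR of windows
  out_or <- coincidence_train(list(a, b), theta = 0.5, delta_t_ms = 1)
  expect_length(out_or, 4) # windows 1, 5, 9, 20 ms
  expect_error(coincidence_train(list(), delta_t_ms = 1), "empty")

  # output windows never exceed the sparsest input when all must agree
  set.seed(6)
  ins <- lapply(1:3, function(i) sort(runif(30 + 10 * i, 0, 2)))
  out3 <- coincidence_train(ins, theta = 1, delta_t_ms = 5)
  expect_lte(length(out3), min(lengths(ins)))
})

test_that("the LIF place cell is quiet without input and fires on forcing", {
  lif <- lif_params()
  traj <- fig4_traj(duration_s = 5)
  silent <- simulate_place_cell(lif, list(gaussian_rate_field(50, 10, 0)),
                                traj, seed = 1)
  expect_length(silent$spikes_s, 0)
  expect_lt(max(abs(silent$v_trace$v_mV - lif$v_rest_mV)), 6 * lif$sigma_v_mV)

  # two synchronized strong inputs: spike within a synaptic time constant
  ev <- c(1, 1) # two coincident spikes at t = 1 s
  out <- coincidence_train(list(ev, ev + 1e-4), theta = 1, delta_t_ms = 2)
  expect_length(out, 1)

  expect_error(simulate_place_cell(lif_params(dt_ms = 4), fig4_inputs(),
                                   traj), "stability")
})

test_that("posterior readout trims outliers and matches sampling theory", {
  traj <- trajectory(seq(0, 100, by = 0.1), seq(0, 100, by = 0.1))
  # spike times whose positions are a known Gaussian
  set.seed(12)
  pos <- rnorm(500, 40, 6)
  pos <- pos[pos > 0 & pos < 100]
  est <- posterior_from_spikes(pos, traj) # identity trajectory: time = position
  expect_lt(abs(est$mu - 40), 3 * 6 / sqrt(length(pos)) + 0.2)
  expect_equal(est$sigma, 6, tolerance = 0.15)

  # a far outlier among clustered spikes is trimmed
  clustered <- c(rnorm(100, 50, 1), 95)
  est2 <- posterior_from_spikes(clustered, traj)
  expect_equal(est2$n_trimmed, 1L)
  expect_lt(est2$mu, 52)

  # all-identical spikes flag a degenerate result
  est3 <- posterior_from_spikes(rep(33, 10), traj)
  expect_true(est3$degenerate)
  expect_error(posterior_from_spikes(c(1, 2), traj), ">= 5")
})

test_that("the simulated field lies between the inputs, nearer the narrow one", {
  lif <- lif_params()
  ins <- fig4_inputs()
  traj <- fig4_traj(duration_s = 60)
  mus <- numeric(8)
  sds <- numeric(8)
  for (r in 1:8) {
    sim <- simulate_place_cell(lif, list(ins$prior, ins$obs), traj,
                               seed = 400 + r)
    est <- posterior_from_spikes(sim$spikes_s, traj)
    mus[r] <- est$mu
    sds[r] <- est$sigma
  }
  expect_true(all(mus > 40 & mus < 60))
  expect_true(all(abs(mus - 40) < abs(mus - 60)))
  # Gaussian-product shrinkage: posterior no wider than the narrow input
  expect_lte(mean(sds), 5 + 3 * sd(sds) / sqrt(length(sds)))
})

test_that("multiplication error is computed against the exact product mean", {
  expect_equal(gaussian_product_mean(20, 4, 30, 2), 28)
  expect_equal(gaussian_product_mean(50, 3, 50, 7), 50)

  lif <- lif_params()
  traj <- fig4_traj(duration_s = 40)
  # identical prior and observation: error is sampling noise only
  same <- gaussian_rate_field(50, 6, 40)
  err <- multiplication_error(lif, same, same, traj, seed = 3, reps = 5)
  expect_lt(as.numeric(err), 2)
  expect_length(attr(err, "errors"), 5)
})

test_that("the error surface exposes the addition regime near rest", {
  lif <- lif_params()
  ins <- fig4_inputs()
  traj <- fig4_traj(duration_s = 40)
  surf <- error_surface(lif, tau_m_grid_ms = 10,
                        v_thresh_grid_mV = c(-68, -56),
                        prior_field = ins$prior, obs_field = ins$obs,
                        traj = traj, seed = 9, reps = 5)
  expect_equal(dim(surf), c(1L, 2L))
  # near-rest threshold: almost every input fires the cell -> addition
  expect_gt(surf[1, "-68"], surf[1, "-56"])
})

test_that("path probabilities are spike-sample fractions over a partition", {
  traj <- fig4_traj(duration_s = 30)
  lif <- lif_params()
  ins <- fig4_inputs()
  sim <- simulate_place_cell(lif, list(ins$prior, ins$obs), traj, seed = 77)
  expect_gt(length(sim$spikes_s), 0)
  dt <- sim$delta_t_ms

  expect_equal(path_probability(sim$spikes_s, c(0, 100), traj, dt), 1)
  expect_equal(path_probability(sim$spikes_s, c(5, 5), traj, dt), 0)

  cuts <- seq(0, 100, by = 20)
  parts <- vapply(seq_len(5), function(i)
    path_probability(sim$spikes_s, cuts[i:(i + 1)], traj, dt), numeric(1))
  expect_equal(sum(parts), 1)

  # matches a histogram oracle of window positions
  win <- unique(floor(sim$spikes_s / (dt / 1000)))
  pos <- approx(traj$times_s, traj$positions_cm,
                (win + 0.5) * dt / 1000, rule = 2)$y
  expect_equal(path_probability(sim$spikes_s, c(30, 50), traj, dt),
               mean(pos >= 30 & pos < 50))
  expect_error(path_probability(numeric(), c(0, 1), traj, dt), "zero output")
})
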