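test_that("generators are deterministic per seed", {
  env <- rect_env(180, 10)
  s <- synthetic_spec(env, gamma_true = 0.1, n_cells = 30, noise_cv = 0.1,
                      seed = 5)
  expect_identical(gen_linear_track(s), gen_linear_track(s))

  tr <- std_track()
  sc <- synthetic_spec(tr, gamma_true = 0.1, n_cells = 20, noise_cv = 0.1,
                       seed = 5)
  expect_identical(gen_circular_track(sc), gen_circular_track(sc))

  traj1 <- gen_trajectory(env, 20, 30)
  traj2 <- gen_trajectory(env, 20, 30)
  expect_identical(traj1, traj2)
})

test_that("linear-track sizes follow the model surface", {
  env <- rect_env(180, 10)
  s0 <- synthetic_spec(env, gamma_true = 0.08, n_cells = 50, noise_cv = 0,
                       seed = 9)
  d <- gen_linear_track(s0)
  p <- cue_params(gamma = 0.08)
  pred <- vapply(seq_len(nrow(d)), function(i)
    as.numeric(rect_track_size(point2d(d$x_cm[i], d$y_cm[i]), env, p)),
    numeric(1))
  expect_equal(d$size_value, pred, tolerance = 1e-12)

  # fields near the track centre are larger on average than near the ends
  s1 <- synthetic_spec(env, gamma_true = 0.08, n_cells = 200, noise_cv = 0.1,
                       seed = 10)
  d1 <- gen_linear_track(s1)
  mid <- abs(d1$x_cm - 90) < 30
  expect_gt(mean(d1$size_value[mid]), mean(d1$size_value[!mid]))
})

test_that("circular-track spikes match their generating sigmas", {
  tr <- std_track()
  s <- synthetic_spec(tr, gamma_true = 0.15, n_cells = 5, noise_cv = 0,
                      seed = 31)
  out <- gen_circular_track(s, n_spikes_per_field = 1000)
  for (i in seq_len(nrow(out$fields))) {
    sp <- out$spikes$arc_cm[out$spikes$cell_id == out$fields$cell_id[i] &
                              out$spikes$field_id == out$fields$field_id[i]]
    f <- field_from_spikes(sp)
    expect_equal(f$centroid, out$fields$arc_cm[i],
                 tolerance = 5 * out$fields$size_value[i] / sqrt(1000) /
                   max(out$fields$arc_cm[i], 1))
    expect_equal(f$size, out$fields$size_value[i], tolerance = 0.15)
  }
})

test_that("multi-field cells appear at the configured probability", {
  tr <- std_track()
  s <- synthetic_spec(tr, gamma_true = 0.1, n_cells = 400,
                      multi_field_prob = 0.3, noise_cv = 0, seed = 17)
  out <- gen_circular_track(s, n_spikes_per_field = 2)
  per_cell <- table(out$fields$cell_id)
  frac2 <- mean(per_cell == 2)
  expect_gt(frac2, 0.2)
  expect_lt(frac2, 0.4)
})

test_that("open-field maps carry Poisson noise scaled by occupancy", {
  envs <- open_boxes()
  base <- synthetic_spec(envs$A, gamma_true = 0.3, n_cells = 10,
                         noise_cv = 0.1, seed = 41)
  noisy_short <- gen_openfield(base, envs["A"], occupancy_s = 5)
  noisy_long <- gen_openfield(base, envs["A"], occupancy_s = 500)
  clean <- gen_openfield(synthetic_spec(envs$A, gamma_true = 0.3,
                                        n_cells = 10, noise_cv = 0,
                                        seed = 41), envs["A"])
  rmse <- function(cells, ref) {
    sq <- mapply(function(a, b) mean((a$maps$A$rates - b$maps$A$rates)^2),
                 cells, ref)
    sqrt(mean(sq))
  }
  # Poisson rate-noise sd scales as 1/sqrt(occupancy): factor 10 expected
  expect_equal(rmse(noisy_short, clean) / rmse(noisy_long, clean), 10,
               tolerance = 0.15)
})

test_that("trajectories respect the environment and the barrier", {
  env <- rect_env(180, 10)
  traj <- gen_trajectory(env, speed_cm_s = 25, duration_s = 120)
  expect_true(all(traj$positions_cm >= 0 & traj$positions_cm <= 180))
  # total path length equals speed x duration
  expect_equal(sum(abs(diff(traj$positions_cm))), 25 * 120, tolerance = 1e-6)

  tr <- std_track()
  circ <- track_circumference(tr)
  ct <- gen_trajectory(tr, speed_cm_s = 20, duration_s = 200)
  expect_true(all(ct$positions_cm >= 0 & ct$positions_cm <= circ))
  # never crosses the barrier: no jump between successive samples
  expect_lt(max(abs(diff(ct$positions_cm))), 20 * 0.05 + 1e-9)
})

test_that("statistical closure: gamma recovered within 10% under noise", {
  tr <- std_track()
  hits <- 0L
  for (r in 1:20) {
    s <- synthetic_spec(tr, gamma_true = 0.1, n_cells = 100, noise_cv = 0.1,
                        seed = 500 + r)
    d <- gen_circular_track(s)
    fit <- fit_gamma_track(d$fields$arc_cm, d$fields$size_value, tr)
    if (abs(fit$params$gamma - 0.1) / 0.1 < 0.1) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})
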