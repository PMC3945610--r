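test_that("field_from_spikes uses the mean and population std", {
  f <- field_from_spikes(c(10, 20, 30))
  expect_equal(f$centroid, 20)
  expect_equal(f$size, sqrt(mean((c(10, 20, 30) - 20)^2))) # ~8.165

  expect_equal(field_from_spikes(c(5, 5, 5))$size, 0)

  # translation moves the centroid, not the size
  f2 <- field_from_spikes(c(10, 20, 30) + 17)
  expect_equal(f2$centroid, 37)
  expect_equal(f2$size, f$size)

  # 2D spikes give per-axis sizes
  m <- cbind(x = c(0, 2, 4), y = c(1, 1, 1))
  f3 <- field_from_spikes(m)
  expect_equal(unname(f3$centroid), c(2, 1))
  expect_equal(unname(f3$size), c(sqrt(8 / 3), 0))

  expect_error(field_from_spikes(5), ">= 2")
})

test_that("moving_average follows the documented window convention", {
  expect_equal(moving_average(c(3, 3, 3, 3), 3), rep(3, 4))
  expect_equal(moving_average(1:7, 1), 1:7)
  expect_equal(moving_average(c(1, 2, 3, 4), 2), c(1.5, 2.5, 3.5, 4))
  # circular wrap
  expect_equal(moving_average(c(1, 2, 3, 4), 2, circular = TRUE),
               c(1.5, 2.5, 3.5, 2.5))
  expect_error(moving_average(1:3, 5), "window larger")
})

test_that("zscore normalizes to mean 0, variance 1 and is idempotent", {
  expect_equal(zscore(c(0, 2)), c(-1, 1))
  x <- rnorm(50, 10, 3)
  z <- zscore(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(mean(z^2), 1)
  expect_equal(zscore(z), z)
  expect_equal(zscore(5 * x + 2), z) # affine invariance
  expect_error(zscore(rep(1, 5)), "variance")
})

test_that("r_squared and its adjustment match hand computations", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  obs <- c(4, 8, 6)
  expect_equal(r_squared(rep(mean(obs), 3), obs), 0)
  expect_equal(r_squared(c(1, 2, 4), c(1, 2, 3)), 0.5)
  expect_error(r_squared(c(1, 2), c(1, 1)), "zero total")

  expect_equal(adjusted_r_squared(1, 20, 3), 1)
  expect_equal(adjusted_r_squared(0.7, 15, 0), 0.7)
  expect_equal(adjusted_r_squared(0.5, 11, 1), 1 - 0.5 * 10 / 9)
  expect_error(adjusted_r_squared(0.5, 4, 3), "n > p")
})

test_that("residual statistics behave on structured vs noise data", {
  set.seed(5)
  model <- sin(seq(0, 3 * pi, length.out = 60)) * 3
  data <- model + rnorm(60, 0, 0.05)
  rt <- residual_tests(data, model)
  expect_gt(rt$pearson_r, 0.99)
  expect_lt(rt$pearson_p, 1e-10)
  # residuals are pure normal noise: GOF should not reject
  expect_gt(rt$chi2_residuals$p_value, 0.01)
})

test_that("residual GOF p-values are roughly calibrated under the null", {
  set.seed(99)
  pvals <- replicate(200, chisq_gof_normal(rnorm(60))$p_value)
  # uniform p-values: around 10% below 0.1, not concentrated at 0
  expect_gt(mean(pvals > 0.05), 0.80)
  expect_lt(mean(pvals < 0.1), 0.25)
})

test_that("fit_gamma recovers the Weber factor", {
  # fields at single observations: closed form gamma = size / distance
  f <- fit_gamma(sizes = c(3.5, 7), predictor = function(g) g * c(50, 100))
  expect_equal(f$params$gamma, 0.07, tolerance = 1e-6)

  # noiseless circular-track recovery to machine-level precision
  tr <- std_track()
  spec <- synthetic_spec(tr, gamma_true = 0.12, n_cells = 60, noise_cv = 0,
                         seed = 7)
  d <- gen_circular_track(spec)
  fit <- fit_gamma_track(d$fields$arc_cm, d$fields$size_value, tr)
  expect_equal(fit$params$gamma, 0.12, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)

  # homogeneity: scaling sizes scales gamma (track dialect)
  fit2 <- fit_gamma_track(d$fields$arc_cm, 2 * d$fields$size_value, tr)
  expect_equal(fit2$params$gamma, 0.24, tolerance = 1e-6)

  expect_error(fit_gamma(c(0, 0), function(g) c(1, 1)), "positive sizes")
})

test_that("rect-track fit returns bound curves and a sane coverage", {
  env <- rect_env(180, 10)
  spec <- synthetic_spec(env, gamma_true = 0.1, n_cells = 80, noise_cv = 0.1,
                         seed = 13)
  d <- gen_linear_track(spec)
  fit <- fit_gamma_rect(d[, c("x_cm", "y_cm")], d$size_value, env)
  expect_equal(fit$params$gamma, 0.1, tolerance = 0.05)
  expect_true(all(fit$bounds$lower <= fit$bounds$upper))
  expect_gte(fit$coverage, 0)
  expect_lte(fit$coverage, 1)

  # coverage grows as the bound trajectories move apart
  cv_narrow <- bounds_coverage(d$x_cm, d$size_value, env, fit$params,
                               y_near = 4)$coverage
  cv_wide <- bounds_coverage(d$x_cm, d$size_value, env, fit$params,
                             y_near = 0.5)$coverage
  expect_gte(cv_wide, cv_narrow)
})

test_that("subset enumeration scores all masks and is oracle-consistent", {
  tr <- circular_track(106.7, 15, object_arcs_cm = c(40, 120, 230))
  mask_true <- subset_mask(c(1, 0, 1, 1))
  spec <- synthetic_spec(tr, gamma_true = 0.1, mask_true = mask_true,
                         n_cells = 80, noise_cv = 0, seed = 5)
  d <- gen_circular_track(spec)
  fit <- fit_subset(d$fields$arc_cm, d$fields$size_value, tr)
  expect_equal(fit$n_masks_evaluated, 15L)
  expect_equal(as.integer(fit$mask), as.integer(mask_true))
  expect_equal(fit$r2, 1, tolerance = 1e-9)

  # independent re-enumeration with a direct formula
  z_obs <- zscore(d$fields$size_value)
  dist_rows <- lapply(d$fields$arc_cm,
                      function(s) track_distances(s, tr)$distance_cm)
  best_score <- -Inf
  best_mask <- NULL
  for (m in 1:15) {
    delta <- as.integer(intToBits(m)[1:4])
    sig <- sapply(dist_rows, function(dd) {
      pr <- sum(1 / dd[delta == 1]^2)
      if (!is.finite(pr) || pr <= 0) 1e-6 else max(pr^-0.5, 1e-6)
    })
    if (sd(sig) == 0) next
    sc <- 1 - sum((zscore(sig) - z_obs)^2) / sum((z_obs - mean(z_obs))^2)
    if (sc > best_score) {
      best_score <- sc
      best_mask <- delta
    }
  }
  expect_equal(as.integer(fit$mask), best_mask)
  expect_equal(fit$r2, best_score, tolerance = 1e-9)

  # the enumeration guard
  big <- circular_track(1000, 15, object_arcs_cm = seq(10, 2000, length.out = 25))
  expect_error(fit_subset(c(1, 2, 3), c(1, 2, 3), big), "guard")
})
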