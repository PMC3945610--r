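test_that("gamma and beta stay consistent in cue_params", {
  p <- cue_params(gamma = 0.1)
  expect_equal(p$beta, 100)
  p2 <- cue_params(beta = 100)
  expect_equal(p2$gamma, 0.1)
  expect_error(cue_params(gamma = 0.1, beta = 50), "inconsistent")
  expect_error(cue_params(gamma = -1), "gamma")
  expect_error(cue_params(), "gamma or beta")
})

test_that("observation noise is linear in distance", {
  p <- cue_params(gamma = 0.1)
  expect_equal(observation_sigma(0, p), 0)
  expect_equal(observation_sigma(50, p), 5)
  expect_equal(observation_sigma(2 * 37, p), 2 * observation_sigma(37, p))
  expect_error(observation_sigma(-1, p), ">= 0")
})

test_that("fuse_1d matches the hand-evaluated Gaussian product", {
  # identical unit Gaussians
  g <- fuse_1d(gaussian1d(0, 1), gaussian1d(0, 1))
  expect_equal(g$sigma, 1 / sqrt(2))
  expect_equal(g$mu, 0)

  # prior N(0,3), observation N(10,4): closed form by hand
  g <- fuse_1d(gaussian1d(0, 3), gaussian1d(10, 4))
  expect_equal(g$mu, (0 / 9 + 10 / 16) / (1 / 9 + 1 / 16))
  expect_equal(g$sigma, 2.4)

  # order invariance
  ins <- list(gaussian1d(1, 2), gaussian1d(5, 0.5), gaussian1d(-3, 7))
  g1 <- fuse_1d(ins)
  g2 <- fuse_1d(rev(ins))
  expect_equal(g1$mu, g2$mu)
  expect_equal(g1$sigma, g2$sigma)

  expect_error(fuse_1d(list()), "undefined belief")
})

test_that("fusion adds precisions, shrinks uncertainty, keeps mean in hull", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(2:6, 1)
    mus <- runif(n, -50, 50)
    sigmas <- runif(n, 0.2, 20)
    ins <- Map(gaussian1d, mus, sigmas)
    g <- fuse_1d(ins)
    expect_equal(1 / g$sigma^2, sum(1 / sigmas^2), tolerance = 1e-12)
    expect_lte(g$sigma, min(sigmas))
    expect_gte(g$mu, min(mus) - 1e-12)
    expect_lte(g$mu, max(mus) + 1e-12)
  }
})

test_that("posterior_sigma implements the precision sum with masks", {
  p <- cue_params(gamma = 0.07)
  # single observation reduces to the Weber law
  expect_equal(as.numeric(posterior_sigma(40, p)), 0.07 * 40)
  # two equal distances halve the variance
  expect_equal(as.numeric(posterior_sigma(c(30, 30), p)), 0.07 * 30 / sqrt(2))
  # prior-only case
  pa <- cue_params(gamma = 1, alpha = 0.04)
  expect_equal(as.numeric(posterior_sigma(c(10, 20), pa,
                                          subset_mask(c(0, 0)))), 5)
  # masked-out observations have no effect
  m <- subset_mask(c(1, 0, 1))
  expect_equal(as.numeric(posterior_sigma(c(10, 999, 20), p, m)),
               as.numeric(posterior_sigma(c(10, 1, 20), p, m)))
  # degenerate zero distance
  s0 <- posterior_sigma(c(0, 10), p)
  expect_equal(as.numeric(s0), 0)
  expect_true(attr(s0, "degenerate"))
  # all masked out with no prior
  expect_error(posterior_sigma(c(10, 20), p, subset_mask(c(0, 0))),
               "infinite uncertainty")
})

test_that("posterior_sigma is monotone in masked-in distances", {
  p <- cue_params(gamma = 0.1)
  set.seed(8)
  for (i in 1:20) {
    d <- runif(4, 5, 100)
    m <- subset_mask(c(1, 1, 0, 1))
    s1 <- as.numeric(posterior_sigma(d, p, m))
    d2 <- d
    d2[1] <- d[1] * 1.3
    expect_gt(as.numeric(posterior_sigma(d2, p, m)), s1)
    d3 <- d
    d3[3] <- d[3] * 10 # masked out: no effect
    expect_equal(as.numeric(posterior_sigma(d3, p, m)), s1)
  }
})

test_that("2D covariance reduces to per-axis 1D fusion for wall normals", {
  p <- cue_params(gamma = 0.12)
  env <- rect_env(61, 122)
  pt <- point2d(20, 45)
  obs <- rect_boundary_distances(pt, env)
  cov <- posterior_covariance_2d(obs, p)
  sx <- as.numeric(posterior_sigma(c(20, 41), p))
  sy <- as.numeric(posterior_sigma(c(45, 77), p))
  expect_equal(cov[1, 1], sx^2, tolerance = 1e-12)
  expect_equal(cov[2, 2], sy^2, tolerance = 1e-12)
  expect_equal(cov[1, 2], 0)

  # two orthogonal walls only
  obs2 <- data.frame(distance_cm = c(10, 30), nx = c(1, 0), ny = c(0, 1))
  cov2 <- posterior_covariance_2d(obs2, p)
  expect_equal(sqrt(diag(cov2)), c(0.12 * 10, 0.12 * 30))

  # centre of a square box is isotropic
  cc <- posterior_covariance_2d(
    rect_boundary_distances(point2d(61, 61), rect_env(122, 122)), p)
  expect_equal(cc[1, 1], cc[2, 2])

  # rank-deficient precision rejected
  par_obs <- data.frame(distance_cm = c(10, 20), nx = c(1, 1), ny = c(0, 0))
  expect_error(posterior_covariance_2d(par_obs, p), "unconstrained")
})

test_that("rect track size peaks at the centre and is symmetric", {
  env <- rect_env(180, 10)
  p <- cue_params(gamma = 0.1)
  centre <- as.numeric(rect_track_size(point2d(90, 5), env, p))
  set.seed(3)
  for (i in 1:20) {
    pt <- c(runif(1, 1, 179), runif(1, 0.5, 9.5))
    expect_lte(as.numeric(rect_track_size(point2d(pt[1], pt[2]), env, p)),
               centre + 1e-12)
    # reflection symmetry about both midlines
    expect_equal(
      as.numeric(rect_track_size(point2d(pt[1], pt[2]), env, p)),
      as.numeric(rect_track_size(point2d(180 - pt[1], 10 - pt[2]), env, p)))
  }
  # midline value exceeds the near-wall value at the same x
  expect_gt(as.numeric(rect_track_size(point2d(60, 5), env, p)),
            as.numeric(rect_track_size(point2d(60, 1), env, p)))
})

test_that("size_profile has minima at masked-in objects and scales by gamma", {
  tr <- circular_track(106.7, 15, object_arcs_cm = c(60, 150, 250))
  p <- cue_params(gamma = 0.1)
  mask <- subset_mask(c(1, 0, 1, 1)) # drop the object at 150; barrier last
  prof <- size_profile(tr, p, mask, resolution_cm = 0.5)

  # local minima on a dense grid sit at the masked-in arcs (and the barrier)
  s <- prof$sigma_cm
  loc_min <- which(diff(sign(diff(s))) > 0) + 1L
  min_arcs <- prof$arc_cm[loc_min]
  for (a in c(60, 250)) expect_true(min(abs(min_arcs - a)) <= 0.5)
  expect_false(any(abs(min_arcs - 150) <= 2)) # masked-out object is no minimum

  # profile at an object arc is (floored) zero
  expect_equal(prof$sigma_cm[prof$arc_cm == 60], 1e-6)

  # all-ones mask lies pointwise below any sub-mask
  prof_all <- size_profile(tr, p, resolution_cm = 0.5)
  expect_true(all(prof_all$sigma_cm <= prof$sigma_cm + 1e-12))

  # z-scored shape is independent of gamma (alpha = 0)
  prof2 <- size_profile(tr, cue_params(gamma = 0.37), mask,
                        resolution_cm = 0.5)
  expect_equal(zscore(prof2$sigma_cm), zscore(prof$sigma_cm),
               tolerance = 1e-6)
})

test_that("spike density curves sum Gaussian fields linearly", {
  grid <- seq(-50, 150, by = 0.1)
  one <- spike_density_curve(50, 8, grid)
  expect_equal(one$density, dnorm(grid, 50, 8))
  two <- spike_density_curve(c(50, 50), c(8, 8), grid)
  expect_equal(two$density, 2 * one$density)
  # quadrature: integral ~ number of fields x weight
  curve <- spike_density_curve(c(30, 70), c(5, 9), grid, weights = 3)
  expect_equal(sum(curve$density) * 0.1, 6, tolerance = 1e-3)
  expect_error(spike_density_curve(numeric(), numeric(), grid), "empty")
})
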