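#' Default object layout for the synthetic circular track
#'
#' Eight fixed arc positions (cm) emulating the randomly distributed objects
#' of the in-vivo circular track (106.7 cm midline diameter, so circumference
#' ~335.2 cm). Fixed constants keep every synthetic dataset deterministic.
#'
#' @return Numeric vector of 8 arc coordinates (cm).
#' @export
default_object_arcs <- function() {
  c(21.5, 58.0, 97.5, 131.0, 166.5, 208.0, 252.5, 297.0)
}

#' Specification of a synthetic place-field dataset
#'
#' Ground-truth container for the generators: the environment, the true
#' Weber factor, the true observation subset, the number of cells, the
#' probability that a cell owns two fields, and the coefficient of variation
#' of the multiplicative lognormal size noise.
#'
#' @param environment A `rect_env` or `circular_track`.
#' @param gamma_true True Weber factor (> 0).
#' @param mask_true Optional [subset_mask()] (circular track only).
#' @param n_cells Number of cells.
#' @param multi_field_prob Probability a cell owns 2 fields.
#' @param noise_cv Coefficient of variation of the multiplicative size noise
#'   (>= 0; 0 means sizes lie exactly on the model surface).
#' @param seed Integer seed; every generator is reproducible per seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(environment, gamma_true = 0.1, mask_true = NULL,
                           n_cells = 100L, multi_field_prob = 0,
                           noise_cv = 0, seed = 1L) {
  validate_environment(environment)
  if (gamma_true <= 0) stop("gamma_true must be > 0", call. = FALSE)
  if (multi_field_prob < 0 || multi_field_prob > 1) {
    stop("multi_field_prob must be in [0, 1]", call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  structure(list(environment = environment, gamma_true = gamma_true,
                 mask_true = mask_true, n_cells = as.integer(n_cells),
                 multi_field_prob = multi_field_prob, noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# lognormal multiplicative noise with mean-log 0 and the sdlog matching a
# target coefficient of variation
size_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  stats::rlnorm(n, meanlog = 0, sdlog = sqrt(log(1 + cv^2)))
}

n_fields_per_cell <- function(spec) {
  1L + (stats::runif(spec$n_cells) < spec$multi_field_prob)
}

#' Generate a linear-track field table
#'
#' Field centroids are uniform over the track; sizes are the model surface
#' `sigma_x * sigma_y` at each centroid times multiplicative lognormal noise.
#' Emulates the rectangular-track dataset in which fields grow toward the
#' track centre.
#'
#' @param spec A [synthetic_spec()] whose environment is a `rect_env`.
#' @return Data frame with `cell_id`, `field_id`, `x_cm`, `y_cm`,
#'   `size_value`, `size_dialect` (`"area"`); attribute `gamma_true`.
#' @export
gen_linear_track <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"),
            inherits(spec$environment, "rect_env"))
  env <- spec$environment
  set.seed(spec$seed)
  nf <- n_fields_per_cell(spec)
  n <- sum(nf)
  params <- cue_params(gamma = spec$gamma_true)
  x <- stats::runif(n, 0, env$length_cm)
  y <- stats::runif(n, 0, env$width_cm)
  size <- vapply(seq_len(n), function(i)
    as.numeric(rect_track_size(point2d(x[i], y[i]), env, params)),
    numeric(1L)) * size_noise(n, spec$noise_cv)
  structure(data.frame(cell_id = rep(seq_along(nf), nf),
                       field_id = sequence(nf),
                       x_cm = x, y_cm = y, size_value = size,
                       size_dialect = "area",
                       stringsAsFactors = FALSE),
            gamma_true = spec$gamma_true)
}

#' Generate a circular-track field table with spike positions
#'
#' Field centroids are uniform on the arc; each field's sigma is the
#' posterior standard deviation under the true mask at its centroid, times
#' lognormal noise; spike positions are drawn Gaussian around the centroid
#' with that sigma. Cells own a second field with probability
#' `multi_field_prob`.
#'
#' @param spec A [synthetic_spec()] whose environment is a `circular_track`.
#' @param n_spikes_per_field Spikes drawn per field.
#' @param sigma_floor Lower clip applied to degenerate (object-adjacent)
#'   sigmas before drawing spikes.
#' @return List with `fields` (data frame `cell_id`, `field_id`, `arc_cm`,
#'   `size_value`, `size_dialect = "std"`) and `spikes` (data frame `cell_id`,
#'   `field_id`, `arc_cm`); attributes `gamma_true`, `mask_true`.
#' @export
gen_circular_track <- function(spec, n_spikes_per_field = 100L,
                               sigma_floor = 1e-6) {
  stopifnot(inherits(spec, "synthetic_spec"),
            inherits(spec$environment, "circular_track"))
  track <- spec$environment
  circ <- track_circumference(track)
  n_obs <- length(track$object_arcs_cm) + 1L
  mask <- spec$mask_true
  if (is.null(mask)) mask <- subset_mask(rep(1L, n_obs))
  set.seed(spec$seed)
  nf <- n_fields_per_cell(spec)
  n <- sum(nf)
  params <- cue_params(gamma = spec$gamma_true)
  arcs <- stats::runif(n, 0, circ)
  sigma <- vapply(arcs, function(s) {
    d <- track_distances(s, track)$distance_cm
    max(as.numeric(posterior_sigma(d, params, mask)), sigma_floor)
  }, numeric(1L)) * size_noise(n, spec$noise_cv)
  fields <- data.frame(cell_id = rep(seq_along(nf), nf),
                       field_id = sequence(nf),
                       arc_cm = arcs, size_value = sigma,
                       size_dialect = "std", stringsAsFactors = FALSE)
  spikes <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(cell_id = fields$cell_id[i], field_id = fields$field_id[i],
               arc_cm = stats::rnorm(n_spikes_per_field, arcs[i],
                                     max(sigma[i], sigma_floor)))
  }))
  structure(list(fields = fields, spikes = spikes),
            gamma_true = spec$gamma_true, mask_true = mask)
}

#' Generate open-field rate maps across environments
#'
#' Each cell gets a relative position (uniform within the central region of
#' the box) that is preserved across environments, and a per-cell Weber
#' factor drawn lognormally around `gamma_true`. Per-environment sigmas come
#' from the wall distances (alpha = 0); the rate map is the Gaussian surface
#' on 1.9 cm bins, with Poisson spike-count noise under uniform occupancy
#' when `noise_cv > 0`.
#'
#' @param spec A [synthetic_spec()] (its environment field is unused here).
#' @param environments Named list of `rect_env`s (e.g. A, B, C, D boxes).
#' @param peak_rate_hz Field peak firing rate (Hz).
#' @param occupancy_s Uniform occupancy per bin (s) governing the Poisson
#'   noise level (longer occupancy, lower noise).
#' @param gamma_sdlog Log-sd of the per-cell Weber factor.
#' @param bin_size_cm Map bin size.
#' @param margin Relative margin keeping centroids off the walls.
#' @return List over cells; each element has `gamma`, `rel_x`, `rel_y`,
#'   `maps` (named list of `rate_map`s) and `truth` (per-env mu/sigma).
#' @export
gen_openfield <- function(spec, environments, peak_rate_hz = 10,
                          occupancy_s = 30, gamma_sdlog = 0.2,
                          bin_size_cm = 1.9, margin = 0.15) {
  stopifnot(inherits(spec, "synthetic_spec"), length(names(environments)) > 0)
  set.seed(spec$seed)
  # cell-level parameters are drawn before any map noise, so the same seed
  # yields the same cells whatever the noise settings
  rel_xs <- stats::runif(spec$n_cells, margin, 1 - margin)
  rel_ys <- stats::runif(spec$n_cells, margin, 1 - margin)
  gammas <- stats::rlnorm(spec$n_cells, log(spec$gamma_true), gamma_sdlog)
  lapply(seq_len(spec$n_cells), function(k) {
    rel_x <- rel_xs[k]
    rel_y <- rel_ys[k]
    gamma_k <- gammas[k]
    maps <- list()
    truth <- list()
    for (e in names(environments)) {
      env <- environments[[e]]
      mu_x <- rel_x * env$length_cm
      mu_y <- rel_y * env$width_cm
      sx <- sigma_from_gamma(gamma_k, mu_x, env$length_cm - mu_x)
      sy <- sigma_from_gamma(gamma_k, mu_y, env$width_cm - mu_y)
      m <- gaussian_ratemap(env, mu_x, mu_y, sx, sy, peak_rate_hz,
                            bin_size_cm)
      if (spec$noise_cv > 0) {
        counts <- stats::rpois(length(m$rates), m$rates * occupancy_s)
        m$rates <- matrix(counts / occupancy_s, nrow = nrow(m$rates))
      }
      maps[[e]] <- m
      truth[[e]] <- list(mu_x = mu_x, mu_y = mu_y, sigma_x = sx,
                         sigma_y = sy)
    }
    list(gamma = gamma_k, rel_x = rel_x, rel_y = rel_y, maps = maps,
         truth = truth)
  })
}

#' Generate a constant-speed trajectory
#'
#' Back-and-forth sweeps along the long axis of a rectangular environment, or
#' lap alternation between the two barrier faces of a circular track (the
#' position bounces at the barrier and never crosses it). Positions are the
#' 1D coordinate (x, or arc length).
#'
#' @param env A `rect_env` or `circular_track`.
#' @param speed_cm_s Running speed (cm/s); positive.
#' @param duration_s Duration (s); positive.
#' @param dt_s Sampling interval (s).
#' @return A [trajectory()].
#' @export
gen_trajectory <- function(env, speed_cm_s, duration_s, dt_s = 0.05) {
  if (speed_cm_s <= 0 || duration_s <= 0) {
    stop("speed and duration must be positive", call. = FALSE)
  }
  span <- if (inherits(env, "circular_track")) {
    track_circumference(env)
  } else {
    validate_environment(env)
    env$length_cm
  }
  tt <- seq(0, duration_s, by = dt_s)
  path <- speed_cm_s * tt
  # triangle wave on [0, span]
  phase <- path %% (2 * span)
  pos <- ifelse(phase <= span, phase, 2 * span - phase)
  trajectory(tt, pos)
}
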