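#' One-dimensional Gaussian location belief
#'
#' @param mu Mean (cm).
#' @param sigma Standard deviation (cm); must be positive.
#' @return An object of class `gaussian1d`.
#' @export
gaussian1d <- function(mu, sigma) {
  if (!is.finite(mu)) stop("mu must be finite", call. = FALSE)
  if (!is.finite(sigma) || sigma <= 0) {
    stop("sigma must be > 0", call. = FALSE)
  }
  structure(list(mu = as.numeric(mu), sigma = as.numeric(sigma)),
            class = "gaussian1d")
}

#' Two-dimensional Gaussian location belief
#'
#' @param mu Length-2 mean vector (cm).
#' @param cov 2x2 symmetric positive-definite covariance matrix (cm^2).
#' @return An object of class `gaussian2d`.
#' @export
gaussian2d <- function(mu, cov) {
  mu <- as.numeric(mu)
  cov <- as.matrix(cov)
  if (length(mu) != 2L || !all(is.finite(mu))) {
    stop("mu must be a finite 2-vector", call. = FALSE)
  }
  if (!all(dim(cov) == c(2L, 2L)) || max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov)))) {
    stop("cov must be a symmetric 2x2 matrix", call. = FALSE)
  }
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("cov must be positive definite", call. = FALSE)
  structure(list(mu = mu, cov = cov), class = "gaussian2d")
}

#' Cue-integration model parameters
#'
#' The observation model is Weber-law noise: an observation at distance `d`
#' has standard deviation `gamma * d`, hence precision `beta / d^2` with
#' `beta = 1 / gamma^2`. `alpha` is the precision of the path-integration
#' prior; it defaults to 0 because the modelled recordings come from distal
#' CA1, which is dominated by sensory rather than path-integration input.
#'
#' Exactly one of `gamma` and `beta` needs to be supplied; the other is
#' derived and the two are kept consistent.
#'
#' @param gamma Weber factor (dimensionless): observation sd per cm of
#'   distance.
#' @param beta Observation precision factor, `1 / gamma^2`.
#' @param alpha Prior precision (cm^-2); `>= 0`.
#' @return An object of class `cue_params` with fields `gamma`, `beta`,
#'   `alpha`.
#' @examples
#' cue_params(gamma = 0.1)
#' cue_params(beta = 100)   # the same model
#' @export
cue_params <- function(gamma = NULL, beta = NULL, alpha = 0) {
  if (is.null(gamma) && is.null(beta)) {
    stop("supply gamma or beta", call. = FALSE)
  }
  if (is.null(gamma)) {
    if (!is.finite(beta) || beta <= 0) stop("beta must be > 0", call. = FALSE)
    gamma <- 1 / sqrt(beta)
  } else {
    if (!is.finite(gamma) || gamma <= 0) stop("gamma must be > 0", call. = FALSE)
    if (!is.null(beta) && abs(beta - 1 / gamma^2) > 1e-8 * beta) {
      stop("gamma and beta are inconsistent (beta must equal 1/gamma^2)",
           call. = FALSE)
    }
    beta <- 1 / gamma^2
  }
  if (!is.finite(alpha) || alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  structure(list(gamma = gamma, beta = beta, alpha = alpha),
            class = "cue_params")
}

#' Subset mask over observations
#'
#' Binary indicators, one per observation, marking which observations enter
#' the uncertainty estimate. Used by the subset-extended model.
#'
#' @param delta Vector of 0/1 (or logical) indicators.
#' @return Integer vector of class `subset_mask`.
#' @export
subset_mask <- function(delta) {
  delta <- as.integer(delta)
  if (length(delta) == 0L || any(is.na(delta)) || any(!delta %in% c(0L, 1L))) {
    stop("mask entries must be 0 or 1", call. = FALSE)
  }
  structure(delta, class = "subset_mask")
}

#' Weber-law observation noise
#'
#' Standard deviation of a distance observation: `sigma = gamma * d`.
#'
#' @param d Distance(s) in cm; non-negative.
#' @param params A [cue_params()] object.
#' @return Observation standard deviation(s) in cm.
#' @export
observation_sigma <- function(d, params) {
  stopifnot(inherits(params, "cue_params"))
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("distances must be finite and >= 0", call. = FALSE)
  }
  params$gamma * d
}

#' Fuse Gaussian beliefs by precision weighting
#'
#' The product of Gaussian densities is Gaussian with precision equal to the
#' sum of input precisions and mean equal to the precision-weighted mean of
#' the input means. The prior, when present, is just another input.
#'
#' @param ... `gaussian1d` objects, or a single list of them.
#' @return The fused `gaussian1d`.
#' @examples
#' fuse_1d(gaussian1d(0, 3), gaussian1d(10, 4))
#' @export
fuse_1d <- function(...) {
  inputs <- list(...)
  if (length(inputs) == 1L && !inherits(inputs[[1L]], "gaussian1d")) {
    inputs <- inputs[[1L]]
  }
  if (length(inputs) == 0L) {
    stop("undefined belief: no prior and no observations to fuse",
         call. = FALSE)
  }
  ok <- vapply(inputs, inherits, logical(1L), what = "gaussian1d")
  if (!all(ok)) stop("all inputs must be gaussian1d", call. = FALSE)
  prec <- vapply(inputs, function(g) 1 / g$sigma^2, numeric(1L))
  mus <- vapply(inputs, function(g) g$mu, numeric(1L))
  gaussian1d(sum(prec * mus) / sum(prec), 1 / sqrt(sum(prec)))
}

#' Posterior location uncertainty from observation distances
#'
#' The one-dimensional posterior standard deviation given a prior of
#' precision `alpha` and observations at distances `d_j` with Weber-law
#' noise, optionally restricted to a subset:
#' `sigma = (alpha + beta * sum_j delta_j / d_j^2)^(-1/2)`.
#'
#' A masked-in observation at distance 0 carries infinite precision; the
#' function then returns 0 with attribute `degenerate = TRUE` (such points
#' legitimately occur on sampled grids passing through an object).
#'
#' @param distances Observation distances (cm), non-negative.
#' @param params A [cue_params()] object.
#' @param mask Optional [subset_mask()]; defaults to all ones.
#' @return Posterior standard deviation (cm). Attribute `degenerate` is TRUE
#'   when a masked-in zero distance forced sigma to 0.
#' @export
posterior_sigma <- function(distances, params, mask = NULL) {
  stopifnot(inherits(params, "cue_params"))
  if (any(!is.finite(distances)) || any(distances < 0)) {
    stop("distances must be finite and >= 0", call. = FALSE)
  }
  n <- length(distances)
  if (is.null(mask)) mask <- subset_mask(rep(1L, max(n, 1L)))
  if (length(mask) != n) {
    stop("mask length must equal the number of observations", call. = FALSE)
  }
  d_in <- distances[mask == 1L]
  if (any(d_in == 0)) {
    return(structure(0, degenerate = TRUE))
  }
  prec <- params$alpha + params$beta * sum(1 / d_in^2)
  if (prec <= 0) {
    stop("infinite uncertainty: all observations masked out and alpha = 0",
         call. = FALSE)
  }
  structure(1 / sqrt(prec), degenerate = FALSE)
}

#' Posterior 2D covariance from directed distance observations
#'
#' Accumulates precision along each observation's unit normal:
#' `P = alpha * I + sum_j n_j n_j^T / (gamma * d_j)^2`; the covariance is
#' `P^{-1}`. For axis-aligned wall normals this reduces exactly to two
#' independent one-dimensional fusions.
#'
#' @param observations A data frame with columns `distance_cm`, `nx`, `ny`
#'   (as returned by [rect_boundary_distances()]).
#' @param params A [cue_params()] object.
#' @return A 2x2 covariance matrix (cm^2).
#' @export
posterior_covariance_2d <- function(observations, params) {
  stopifnot(inherits(params, "cue_params"),
            is.data.frame(observations),
            all(c("distance_cm", "nx", "ny") %in% names(observations)))
  d <- observations$distance_cm
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("distances must be finite and >= 0", call. = FALSE)
  }
  nrm <- sqrt(observations$nx^2 + observations$ny^2)
  if (any(abs(nrm - 1) > 1e-8)) {
    stop("observation normals must be unit vectors", call. = FALSE)
  }
  P <- diag(params$alpha, 2)
  for (j in seq_along(d)) {
    if (d[j] == 0) {
      stop("degenerate observation at distance 0: 2D covariance undefined",
           call. = FALSE)
    }
    nj <- c(observations$nx[j], observations$ny[j])
    P <- P + tcrossprod(nj) / (params$gamma * d[j])^2
  }
  ev <- eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(abs(ev), 1)) {
    stop("unconstrained direction: precision matrix is rank deficient (all normals parallel with alpha = 0?)",
         call. = FALSE)
  }
  solve(P)
}

#' Predicted field size on a rectangular track
#'
#' Fuses the two opposing-wall observations per axis independently and
#' returns the product `sigma_x * sigma_y` — an area-like quantity matching
#' field sizes measured in bins. Per-axis sigmas are attached as attributes.
#'
#' @param p A `point2d` inside `env` (or a numeric vector `c(x, y)`).
#' @param env A `rect_env`.
#' @param params A [cue_params()] object.
#' @return `sigma_x * sigma_y` (cm^2-like), with attributes `sigma_x`,
#'   `sigma_y`.
#' @export
rect_track_size <- function(p, env, params) {
  if (is.numeric(p) && length(p) == 2L) p <- point2d(p[1L], p[2L])
  obs <- rect_boundary_distances(p, env)
  sx <- posterior_sigma(obs$distance_cm[obs$wall %in% c("W", "E")], params)
  sy <- posterior_sigma(obs$distance_cm[obs$wall %in% c("S", "N")], params)
  structure(as.numeric(sx) * as.numeric(sy),
            sigma_x = as.numeric(sx), sigma_y = as.numeric(sy))
}

#' Uncertainty profile along a circular track
#'
#' Samples the posterior standard deviation on a regular arc grid. With
#' `alpha = 0` the profile has its local minima exactly at the masked-in
#' object/barrier positions (uncertainty is lowest next to an object).
#' Degenerate sigma values at object arcs are clipped from below at
#' `sigma_floor` so the profile can be z-scored and plotted.
#'
#' @param track A `circular_track`.
#' @param params A [cue_params()] object.
#' @param mask Optional [subset_mask()] over the observations in
#'   [track_distances()] order (objects, then barrier).
#' @param resolution_cm Arc grid spacing (cm); must be positive.
#' @param sigma_floor Lower clip for degenerate sigmas (cm).
#' @return A data frame with columns `arc_cm`, `sigma_cm`.
#' @export
size_profile <- function(track, params, mask = NULL, resolution_cm = 1,
                         sigma_floor = 1e-6) {
  stopifnot(inherits(track, "circular_track"))
  if (!is.finite(resolution_cm) || resolution_cm <= 0) {
    stop("resolution_cm must be > 0", call. = FALSE)
  }
  circ <- track_circumference(track)
  arcs <- seq(0, circ - resolution_cm / 2, by = resolution_cm)
  sig <- vapply(arcs, function(s) {
    d <- track_distances(s, track)$distance_cm
    max(as.numeric(posterior_sigma(d, params, mask)), sigma_floor)
  }, numeric(1L))
  data.frame(arc_cm = arcs, sigma_cm = sig)
}

#' Summed spike-density curve over a set of place fields
#'
#' Pointwise sum of Gaussian densities, one per field, centred at the field
#' centroids with the field sigmas; each density integrates to its weight.
#' This is the model counterpart of the pooled spike-density histogram.
#'
#' @param centroids Field centres (cm).
#' @param sigmas Field standard deviations (cm); positive, same length.
#' @param grid Coordinates at which to evaluate the curve (cm).
#' @param weights Per-field weights (total spikes per field); recycled.
#' @return A data frame with columns `coord_cm`, `density`.
#' @export
spike_density_curve <- function(centroids, sigmas, grid, weights = 1) {
  if (length(centroids) == 0L) stop("empty field list", call. = FALSE)
  if (length(sigmas) != length(centroids)) {
    stop("centroids and sigmas must have equal length", call. = FALSE)
  }
  if (any(!is.finite(sigmas)) || any(sigmas <= 0)) {
    stop("sigmas must be > 0", call. = FALSE)
  }
  weights <- rep_len(weights, length(centroids))
  dens <- Reduce(`+`, Map(function(m, s, w) w * stats::dnorm(grid, m, s),
                          centroids, sigmas, weights))
  data.frame(coord_cm = grid, density = dens)
}
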