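#' Place-field centroid and size from spike positions
#'
#' The field centroid is the mean of the spike positions and the field size
#' their population (divide-by-n) standard deviation — per axis for 2D
#' spikes, scalar for arc coordinates. This is the size dialect used on the
#' circular track, directly comparable to posterior standard deviations.
#'
#' @param spike_positions Numeric vector (1D/arc coordinates) or a two-column
#'   matrix / data frame of x, y positions; at least 2 spikes.
#' @return A list of class `place_field` with `centroid` and `size`
#'   (per-axis for 2D input).
#' @export
field_from_spikes <- function(spike_positions) {
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  if (is.data.frame(spike_positions)) spike_positions <- as.matrix(spike_positions)
  if (is.matrix(spike_positions)) {
    if (nrow(spike_positions) < 2L) stop("need >= 2 spikes", call. = FALSE)
    centroid <- colMeans(spike_positions)
    size <- apply(spike_positions, 2L, pop_sd)
  } else {
    if (length(spike_positions) < 2L) stop("need >= 2 spikes", call. = FALSE)
    centroid <- mean(spike_positions)
    size <- pop_sd(spike_positions)
  }
  structure(list(centroid = centroid, size = size), class = "place_field")
}

#' Moving average of a series
#'
#' The window is centred at each index, extending `floor((w-1)/2)` points to
#' the left and `ceiling((w-1)/2)` to the right (even windows lean right).
#' Circular series wrap around; linear series shrink the window at the edges.
#'
#' @param x Numeric series.
#' @param window Window length (points), default the 10-point smoother used
#'   for field-size series.
#' @param circular Wrap around the series ends?
#' @return Smoothed series, same length as `x`.
#' @export
moving_average <- function(x, window = 10, circular = FALSE) {
  n <- length(x)
  if (n == 0L) stop("series is empty", call. = FALSE)
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  if (!circular && window > n) {
    stop("window larger than series on non-circular input", call. = FALSE)
  }
  lo <- (window - 1L) %/% 2L
  hi <- window - 1L - lo
  vapply(seq_len(n), function(i) {
    idx <- (i - lo):(i + hi)
    if (circular) {
      idx <- ((idx - 1L) %% n) + 1L
    } else {
      idx <- idx[idx >= 1L & idx <= n]
    }
    mean(x[idx])
  }, numeric(1L))
}

#' Z-score a series
#'
#' Normalizes to mean 0 and variance 1 (population variance), the
#' normalization applied to field-size and spike-density series before
#' comparison with model profiles.
#'
#' @param x Numeric series with positive variance.
#' @return The normalized series.
#' @export
zscore <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (!is.finite(s) || s == 0) stop("zero variance series", call. = FALSE)
  (x - m) / s
}

#' Proportion of variance explained
#'
#' `R^2 = 1 - SS_err / SS_tot`, where `SS_err` is the sum of squared
#' differences between the model prediction and the data and `SS_tot` the
#' total sum of squares about the data mean. Can be negative for models
#' worse than the mean.
#'
#' @param pred Model predictions.
#' @param obs Observed data, same length (>= 2).
#' @return R-squared.
#' @export
r_squared <- function(pred, obs) {
  if (length(pred) != length(obs) || length(obs) < 2L) {
    stop("pred and obs must have equal length >= 2", call. = FALSE)
  }
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) stop("zero total sum of squares", call. = FALSE)
  1 - sum((obs - pred)^2) / ss_tot
}

#' Adjusted proportion of variance explained
#'
#' `1 - (1 - R^2) (n - 1) / (n - p - 1)`, penalizing the number of fitted
#' parameters `p`.
#'
#' @param r2 Unadjusted R-squared.
#' @param n Number of data points.
#' @param p Number of model parameters; requires `n > p + 1`.
#' @return Adjusted R-squared.
#' @export
adjusted_r_squared <- function(r2, n, p) {
  if (n <= p + 1) stop("need n > p + 1", call. = FALSE)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Chi-square goodness of fit against a fitted normal distribution
#'
#' Bins the data into `k` equal-probability bins of a normal with mean and sd
#' estimated from the data, `k = max(8, floor(n/5))`, and compares observed
#' with expected counts on `k - 3` degrees of freedom (two estimated
#' parameters).
#'
#' @param x Numeric data, at least 8 points.
#' @return List with `statistic`, `df`, `p_value`, `k`.
#' @export
chisq_gof_normal <- function(x) {
  n <- length(x)
  if (n < 8L) stop("need >= 8 data points for the binned chi-square",
                   call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("degenerate data: zero variance",
                                    call. = FALSE)
  k <- max(8L, n %/% 5L)
  breaks <- stats::qnorm(seq(0, 1, length.out = k + 1L), mean(x), s)
  breaks[1L] <- -Inf
  breaks[k + 1L] <- Inf
  obs_counts <- as.vector(table(cut(x, breaks)))
  expected <- n / k
  statistic <- sum((obs_counts - expected)^2 / expected)
  df <- k - 3L
  list(statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df, lower.tail = FALSE), k = k)
}

#' Model-vs-data residual statistics
#'
#' Computes the statistic set reported for the track fits: Pearson
#' correlation between model and data (with p-value), a chi-square
#' goodness-of-fit test of the data against a fitted normal (the data having
#' non-random structure shows as a small p-value), and the same test on the
#' residuals `data - model` (a large p-value means the residuals are
#' compatible with random normal noise, i.e. the model captured the
#' structure).
#'
#' @param data Observed series (>= 8 points).
#' @param model Model predictions, same length.
#' @return A list with `pearson_r`, `pearson_p`, `chi2_data`,
#'   `chi2_residuals` (each a [chisq_gof_normal()] result).
#' @export
residual_tests <- function(data, model) {
  if (length(data) != length(model) || length(data) < 8L) {
    stop("data and model must have equal length >= 8", call. = FALSE)
  }
  ct <- stats::cor.test(model, data, method = "pearson")
  list(pearson_r = unname(ct$estimate),
       pearson_p = ct$p.value,
       chi2_data = chisq_gof_normal(data),
       chi2_residuals = chisq_gof_normal(data - model))
}

fit_result <- function(params, mask, r2, r2_adj, pearson_r, residuals,
                       n_params_used, extra = list()) {
  structure(c(list(params = params, mask = mask, r2 = r2, r2_adj = r2_adj,
                   pearson_r = pearson_r, residuals = residuals,
                   n_params_used = n_params_used), extra),
            class = "pf_fit")
}

#' @export
print.pf_fit <- function(x, ...) {
  cat("<placefuse fit>\n")
  cat(sprintf("  gamma = %.6g (beta = %.6g, alpha = %.3g)\n",
              x$params$gamma, x$params$beta, x$params$alpha))
  if (!is.null(x$mask)) cat("  mask  =", paste(unclass(x$mask), collapse = ""), "\n")
  cat(sprintf("  R^2 = %.4f  adj R^2 = %.4f  r = %.4f\n",
              x$r2, if (is.null(x$r2_adj)) NA_real_ else x$r2_adj,
              if (is.null(x$pearson_r)) NA_real_ else x$pearson_r))
  invisible(x)
}

#' Fit the Weber factor to observed field sizes
#'
#' Finds the `gamma` minimizing the sum of squared differences between
#' predicted and observed sizes. The single-scalar coordinate descent
#' degenerates to a golden-section line search on `interval` (via
#' [stats::optimize()]) with tolerance `tol`.
#'
#' `predictor(gamma)` must return the predicted size for every observed
#' field. Convenience wrappers [fit_gamma_track()] and [fit_gamma_rect()]
#' build the predictor from an environment.
#'
#' @param sizes Observed field sizes (>= 2, at least one positive).
#' @param predictor Function mapping a scalar `gamma` to predicted sizes.
#' @param interval Search interval for `gamma`.
#' @param tol Line-search tolerance.
#' @param alpha Prior precision passed through to the returned parameters.
#' @return A `pf_fit` with the fitted [cue_params()], R-squared, Pearson r
#'   and residuals.
#' @export
fit_gamma <- function(sizes, predictor, interval = c(1e-4, 10), tol = 1e-8,
                      alpha = 0) {
  if (length(sizes) < 2L || all(sizes <= 0)) {
    stop("need >= 2 fields with positive sizes", call. = FALSE)
  }
  sse <- function(g) {
    pred <- predictor(g)
    v <- sum((pred - sizes)^2)
    if (!is.finite(v)) stop("non-finite objective at gamma = ", g,
                            call. = FALSE)
    v
  }
  opt <- stats::optimize(sse, interval = interval, tol = tol)
  g <- opt$minimum
  pred <- predictor(g)
  r2 <- r_squared(pred, sizes)
  pr <- if (stats::sd(pred) > 0) stats::cor(pred, sizes) else NA_real_
  n <- length(sizes)
  fit_result(params = cue_params(gamma = g, alpha = alpha), mask = NULL,
             r2 = r2,
             r2_adj = if (n > 2L) adjusted_r_squared(r2, n, 1L) else NA_real_,
             pearson_r = pr, residuals = sizes - pred, n_params_used = 1L,
             extra = list(predicted = pred, sse = opt$objective))
}

#' Fit the Weber factor on a circular track
#'
#' Predicted size at each field centroid is the posterior standard deviation
#' from the track's object/barrier distances (std-of-spike-positions size
#' dialect).
#'
#' @param arcs Field centroid arc coordinates (cm).
#' @param sizes Observed field sizes (cm, std dialect).
#' @param track A `circular_track`.
#' @param mask Optional [subset_mask()] restricting the observations used.
#' @param alpha Prior precision.
#' @param ... Passed to [fit_gamma()].
#' @return A `pf_fit`.
#' @export
fit_gamma_track <- function(arcs, sizes, track, mask = NULL, alpha = 0, ...) {
  dist_list <- lapply(arcs, function(s) track_distances(s, track)$distance_cm)
  predictor <- function(g) {
    p <- cue_params(gamma = g, alpha = alpha)
    vapply(dist_list, function(d) as.numeric(posterior_sigma(d, p, mask)),
           numeric(1L))
  }
  fit_gamma(sizes, predictor, alpha = alpha, ...)
}

#' Fit the Weber factor on a rectangular track
#'
#' Predicted size at each centroid is the product `sigma_x * sigma_y` of the
#' per-axis posteriors from the four walls (area-like size dialect). Also
#' reports the two bound curves along the track — the near-wall trajectory
#' and the midline trajectory — and the fraction of observed sizes lying
#' between them, the coverage statistic quoted for the linear track.
#'
#' @param centroids Two-column matrix / data frame of field centroids (cm).
#' @param sizes Observed field sizes (area-like dialect).
#' @param env A `rect_env`.
#' @param alpha Prior precision.
#' @param y_near Distance from the wall of the near-wall bound trajectory
#'   (cm); default one 1.9 cm rate-map bin.
#' @param ... Passed to [fit_gamma()].
#' @return A `pf_fit` with extra fields `bounds` (per-field lower/upper
#'   curves) and `coverage` (fraction between the curves).
#' @export
fit_gamma_rect <- function(centroids, sizes, env, alpha = 0, y_near = 1.9,
                           ...) {
  centroids <- as.matrix(centroids)
  predictor <- function(g) {
    p <- cue_params(gamma = g, alpha = alpha)
    vapply(seq_len(nrow(centroids)), function(i) {
      as.numeric(rect_track_size(point2d(centroids[i, 1L], centroids[i, 2L]),
                                 env, p))
    }, numeric(1L))
  }
  fit <- fit_gamma(sizes, predictor, alpha = alpha, ...)
  bc <- bounds_coverage(centroids[, 1L], sizes, env, fit$params,
                        y_near = y_near)
  fit$bounds <- bc$bounds
  fit$coverage <- bc$coverage
  fit
}

#' Bound curves and coverage on a rectangular track
#'
#' At each field's x position, evaluates the model size for a trajectory
#' hugging the wall (`y = y_near`) and for one on the track midline
#' (`y = width/2`); the coverage is the fraction of observed sizes falling
#' between these two curves (inclusive). Most recorded sizes falling between
#' the curves is the linear-track summary statistic.
#'
#' @param xs Field x positions (cm).
#' @param sizes Observed sizes.
#' @param env A `rect_env`.
#' @param params A [cue_params()].
#' @param y_near Wall offset of the near-wall trajectory (cm).
#' @return List with `bounds` (data frame `x_cm`, `lower`, `upper`) and
#'   `coverage`.
#' @export
bounds_coverage <- function(xs, sizes, env, params, y_near = 1.9) {
  y_mid <- env$width_cm / 2
  lower <- vapply(xs, function(x)
    as.numeric(rect_track_size(point2d(x, y_near), env, params)), numeric(1L))
  upper <- vapply(xs, function(x)
    as.numeric(rect_track_size(point2d(x, y_mid), env, params)), numeric(1L))
  list(bounds = data.frame(x_cm = xs, lower = lower, upper = upper),
       coverage = mean(sizes >= lower & sizes <= upper))
}

#' Select the observation subset by exhaustive enumeration
#'
#' Evaluates every non-empty mask over the track's `N` observations (objects
#' plus barrier; `2^N - 1` masks, guarded at `N <= 20`), scoring each by the
#' R-squared between the z-scored predicted uncertainty at the field arcs and
#' the z-scored observed sizes. With `alpha = 0`, z-scoring removes `gamma`
#' from the profile shape, so no inner `gamma` fit is needed. The adjusted
#' R-squared uses `p = N + 1` parameters (the N binary indicators plus the
#' Weber factor).
#'
#' @param arcs Arc coordinates of the size observations (cm).
#' @param sizes Observed sizes (same length, variance > 0).
#' @param track A `circular_track`.
#' @param params A [cue_params()]; `alpha` must be 0 for the shape-invariance
#'   shortcut (enforced).
#' @param sigma_floor Lower clip for degenerate sigmas.
#' @param max_n Enumeration guard on the number of observations.
#' @return A `pf_fit` whose `mask` is the best subset; extra field
#'   `n_masks_evaluated`.
#' @export
fit_subset <- function(arcs, sizes, track, params = cue_params(gamma = 1),
                       sigma_floor = 1e-6, max_n = 20L) {
  stopifnot(inherits(track, "circular_track"))
  if (params$alpha != 0) {
    stop("subset enumeration assumes alpha = 0 (sensory-driven fields)",
         call. = FALSE)
  }
  n_obs <- length(track$object_arcs_cm) + 1L
  if (n_obs > max_n) {
    stop(sprintf("N = %d observations exceeds the enumeration guard (%d); use the base single-parameter model",
                 n_obs, max_n), call. = FALSE)
  }
  if (length(arcs) != length(sizes) || length(sizes) < 2L) {
    stop("arcs and sizes must have equal length >= 2", call. = FALSE)
  }
  dist_mat <- t(vapply(arcs, function(s) track_distances(s, track)$distance_cm,
                       numeric(n_obs)))
  z_obs <- zscore(sizes)
  n <- length(sizes)
  best <- list(score = -Inf, mask = NULL, pred = NULL)
  n_masks <- 0L
  for (code in seq_len(2L^n_obs - 1L)) {
    delta <- as.integer(bitwAnd(code, 2L^(seq_len(n_obs) - 1L)) > 0L)
    n_masks <- n_masks + 1L
    # sigma shape for gamma = 1; clip degenerate zero distances
    prec <- (dist_mat[, delta == 1L, drop = FALSE])^(-2)
    sig <- rowSums(prec)^(-1 / 2)
    sig[!is.finite(sig)] <- sigma_floor
    sig <- pmax(sig, sigma_floor)
    if (stats::sd(sig) == 0) next
    score <- r_squared(zscore(sig), z_obs)
    if (score > best$score) best <- list(score = score, mask = delta, pred = sig)
  }
  if (is.null(best$mask)) stop("no mask produced a non-constant profile",
                               call. = FALSE)
  r2 <- best$score
  r2_adj <- if (n > n_obs + 2L) {
    adjusted_r_squared(r2, n, n_obs + 1L)
  } else {
    NA_real_
  }
  fit_result(params = params, mask = subset_mask(best$mask), r2 = r2,
             r2_adj = r2_adj, pearson_r = stats::cor(best$pred, sizes),
             residuals = z_obs - zscore(best$pred),
             n_params_used = n_obs + 1L,
             extra = list(n_masks_evaluated = n_masks,
                          predicted_shape = best$pred))
}
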