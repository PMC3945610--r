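#' Construct a binned firing-rate map
#'
#' `rates[ix, iy]` is the mean firing rate (Hz) in the bin whose centre is
#' `origin + (c(ix, iy) - 0.5) * bin_size_cm`; rows index x (eastward),
#' columns y (northward). The default bin size is the 1.9 cm used for the
#' recorded maps.
#'
#' @param rates Matrix of non-negative firing rates (Hz).
#' @param bin_size_cm Bin side length (cm).
#' @param origin `point2d` of the map's south-west corner (default the
#'   environment origin).
#' @return An object of class `rate_map`.
#' @export
rate_map <- function(rates, bin_size_cm = 1.9, origin = point2d(0, 0)) {
  rates <- as.matrix(rates)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("rates must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(bin_size_cm) || bin_size_cm <= 0) {
    stop("bin_size_cm must be > 0", call. = FALSE)
  }
  structure(list(rates = rates, bin_size_cm = bin_size_cm, origin = origin),
            class = "rate_map")
}

#' Bin-centre coordinates of a rate map
#'
#' @param map A `rate_map`.
#' @return List with vectors `x_cm`, `y_cm` of bin centres.
#' @export
ratemap_coords <- function(map) {
  stopifnot(inherits(map, "rate_map"))
  list(x_cm = map$origin$x_cm + (seq_len(nrow(map$rates)) - 0.5) * map$bin_size_cm,
       y_cm = map$origin$y_cm + (seq_len(ncol(map$rates)) - 0.5) * map$bin_size_cm)
}

#' Render a separable Gaussian firing field as a rate map
#'
#' @param env A `rect_env` defining the map extent.
#' @param mu_x,mu_y Field centre (cm).
#' @param sigma_x,sigma_y Field standard deviations (cm).
#' @param amplitude Peak rate (Hz).
#' @param bin_size_cm Bin size (cm).
#' @return A `rate_map`.
#' @export
gaussian_ratemap <- function(env, mu_x, mu_y, sigma_x, sigma_y,
                             amplitude = 10, bin_size_cm = 1.9) {
  stopifnot(inherits(env, "rect_env"))
  nx <- max(1L, round(env$length_cm / bin_size_cm))
  ny <- max(1L, round(env$width_cm / bin_size_cm))
  xc <- (seq_len(nx) - 0.5) * bin_size_cm
  yc <- (seq_len(ny) - 0.5) * bin_size_cm
  rates <- amplitude * exp(-(outer((xc - mu_x)^2 / (2 * sigma_x^2),
                                   (yc - mu_y)^2 / (2 * sigma_y^2), `+`)))
  rate_map(rates, bin_size_cm)
}

#' Least-squares Gaussian fit to a rate map
#'
#' Fits a separable two-dimensional Gaussian
#' `A * exp(-(x - mu_x)^2 / (2 sigma_x^2) - (y - mu_y)^2 / (2 sigma_y^2))`
#' (optionally plus a uniform baseline) to the rate surface by
#' Levenberg-Marquardt nonlinear least squares, starting from the rate-
#' weighted moments.
#'
#' @param map A `rate_map` with a positive peak.
#' @param baseline Include a uniform offset term?
#' @return List with `mu_x`, `mu_y`, `sigma_x`, `sigma_y`, `amplitude`,
#'   `baseline`, `r2`, `fitted` (a `rate_map` of the fitted surface), and
#'   `converged`.
#' @export
fit_gaussian_ratemap <- function(map, baseline = FALSE) {
  stopifnot(inherits(map, "rate_map"))
  r <- map$rates
  if (max(r) <= 0) stop("map has no positive peak", call. = FALSE)
  cc <- ratemap_coords(map)
  df <- data.frame(x = rep(cc$x_cm, times = ncol(r)),
                   y = rep(cc$y_cm, each = nrow(r)),
                   r = as.vector(r))
  r0 <- df$r - min(df$r) # moments on the baseline-subtracted surface
  w <- r0 / sum(r0)
  start <- list(A = max(r0),
                mx = sum(w * df$x), my = sum(w * df$y),
                sx = max(sqrt(sum(w * df$x^2) - sum(w * df$x)^2), map$bin_size_cm),
                sy = max(sqrt(sum(w * df$y^2) - sum(w * df$y)^2), map$bin_size_cm))
  eps <- map$bin_size_cm / 10
  fit <- if (baseline) {
    minpack.lm::nlsLM(
      r ~ b + A * exp(-(x - mx)^2 / (2 * sx^2) - (y - my)^2 / (2 * sy^2)),
      data = df, start = c(start, list(b = min(df$r))),
      lower = c(0, -Inf, -Inf, eps, eps, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(
      r ~ A * exp(-(x - mx)^2 / (2 * sx^2) - (y - my)^2 / (2 * sy^2)),
      data = df, start = start,
      lower = c(0, -Inf, -Inf, eps, eps),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- stats::coef(fit)
  fitted_mat <- matrix(stats::predict(fit), nrow = nrow(r))
  list(mu_x = unname(cf["mx"]), mu_y = unname(cf["my"]),
       sigma_x = unname(abs(cf["sx"])), sigma_y = unname(abs(cf["sy"])),
       amplitude = unname(cf["A"]),
       baseline = if (baseline) unname(cf["b"]) else 0,
       r2 = r_squared(as.vector(fitted_mat), as.vector(r)),
       fitted = rate_map(pmax(fitted_mat, 0), map$bin_size_cm, map$origin),
       converged = fit$convInfo$isConv %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment contiguous firing fields in a rate map
#'
#' A field is a 4-connected component of bins with rate at or above
#' `threshold_frac` of the map peak. A cell owning several fields yields
#' several rows, each handled independently downstream. Field size here is
#' the area dialect: the number of suprathreshold bins.
#'
#' @param map A `rate_map`.
#' @param threshold_frac Fraction of the peak rate defining field membership.
#' @return Data frame with one row per field: `field_id`, `area_bins`,
#'   `peak_hz`, `centroid_x_cm`, `centroid_y_cm`.
#' @export
segment_fields <- function(map, threshold_frac = 0.2) {
  stopifnot(inherits(map, "rate_map"))
  r <- map$rates
  thr <- threshold_frac * max(r)
  above <- r >= thr & r > 0
  lab <- matrix(0L, nrow(r), ncol(r))
  cur <- 0L
  for (i in seq_len(nrow(r))) {
    for (j in seq_len(ncol(r))) {
      if (above[i, j] && lab[i, j] == 0L) {
        cur <- cur + 1L
        queue <- list(c(i, j))
        lab[i, j] <- cur
        while (length(queue)) {
          p <- queue[[1L]]; queue <- queue[-1L]
          for (dij in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
            ni <- p[1L] + dij[1L]; nj <- p[2L] + dij[2L]
            if (ni >= 1L && ni <= nrow(r) && nj >= 1L && nj <= ncol(r) &&
                above[ni, nj] && lab[ni, nj] == 0L) {
              lab[ni, nj] <- cur
              queue[[length(queue) + 1L]] <- c(ni, nj)
            }
          }
        }
      }
    }
  }
  if (cur == 0L) {
    return(data.frame(field_id = integer(), area_bins = integer(),
                      peak_hz = numeric(), centroid_x_cm = numeric(),
                      centroid_y_cm = numeric()))
  }
  cc <- ratemap_coords(map)
  out <- lapply(seq_len(cur), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    wts <- r[lab == k]
    data.frame(field_id = k, area_bins = nrow(idx), peak_hz = max(wts),
               centroid_x_cm = sum(cc$x_cm[idx[, 1L]] * wts) / sum(wts),
               centroid_y_cm = sum(cc$y_cm[idx[, 2L]] * wts) / sum(wts))
  })
  do.call(rbind, out)
}

#' Per-axis skewness of a rate map and asymmetry flag
#'
#' Rate-weighted sample skewness of each marginal. Fields with
#' `|skewness| > threshold` on either axis are flagged as asymmetric and are
#' excluded from Gaussian-model fitting (mirroring the exclusion of fields
#' that did not fit a Gaussian).
#'
#' @param map A `rate_map`.
#' @param threshold Absolute skewness above which a field is flagged.
#' @return List with `skew_x`, `skew_y`, `asymmetric`.
#' @export
field_skewness <- function(map, threshold = 1.0) {
  stopifnot(inherits(map, "rate_map"))
  cc <- ratemap_coords(map)
  w_skew <- function(v, w) {
    w <- w / sum(w)
    m <- sum(w * v)
    s2 <- sum(w * (v - m)^2)
    if (s2 == 0) return(0)
    sum(w * (v - m)^3) / s2^1.5
  }
  sx <- w_skew(rep(cc$x_cm, times = ncol(map$rates)), as.vector(map$rates))
  sy <- w_skew(rep(cc$y_cm, each = nrow(map$rates)), as.vector(map$rates))
  list(skew_x = sx, skew_y = sy,
       asymmetric = abs(sx) > threshold || abs(sy) > threshold)
}

# Weber factor per axis from a fitted sigma and the two opposing wall
# distances (alpha = 0): 1/sigma^2 = (1/gamma^2)(1/d1^2 + 1/d2^2).
gamma_from_sigma <- function(sigma, d1, d2) {
  sigma * sqrt(1 / d1^2 + 1 / d2^2)
}

# Predicted sigma on an axis from gamma and the two wall distances.
sigma_from_gamma <- function(gamma, d1, d2) {
  gamma / sqrt(1 / d1^2 + 1 / d2^2)
}

#' Cross-environment place-field prediction
#'
#' For each field, fits Gaussians to its rate maps in two source
#' environments, derives a per-field Weber factor from the fitted sigmas and
#' the wall distances (alpha = 0), relocates the centroid to the target
#' environment by preserving its relative position, predicts the target
#' sigmas from the target wall distances, and renders the predicted map as a
#' Gaussian (amplitude chosen by least squares against the observed target
#' map, since amplitude reflects non-spatial factors). The prediction's
#' per-field R-squared is compared against the optimal Gaussian fit to the
#' observed target map with a paired t-test.
#'
#' @param fields A list; each element has `maps`, a named list of
#'   `rate_map`s containing the two source environments and the target.
#' @param envs Named list of `rect_env`s for every environment in `maps`.
#' @param source_envs Names of the two source environments (default
#'   `c("C", "D")`).
#' @param target_env Name of the target environment (default `"B"`).
#' @param exclude_asymmetric Drop fields flagged by [field_skewness()] in a
#'   source environment?
#' @param skew_threshold Passed to [field_skewness()].
#' @return List with `per_field` (data frame of gammas, predicted sigmas,
#'   `r2_model`, `r2_optimal`), `mean_r2_model`, `mean_r2_optimal`,
#'   `t_test` (paired), `n_used`, `n_excluded`, and `predicted_maps`.
#' @export
cross_env_predict <- function(fields, envs, source_envs = c("C", "D"),
                              target_env = "B", exclude_asymmetric = TRUE,
                              skew_threshold = 1.0) {
  stopifnot(length(source_envs) == 2L,
            all(c(source_envs, target_env) %in% names(envs)))
  rows <- list()
  pred_maps <- list()
  n_excl <- 0L
  for (k in seq_along(fields)) {
    fld <- fields[[k]]
    maps <- fld$maps
    if (exclude_asymmetric) {
      skews <- vapply(source_envs, function(e)
        field_skewness(maps[[e]], skew_threshold)$asymmetric, logical(1L))
      if (any(skews)) {
        n_excl <- n_excl + 1L
        next
      }
    }
    src_fits <- lapply(source_envs, function(e) fit_gaussian_ratemap(maps[[e]]))
    names(src_fits) <- source_envs
    gammas <- unlist(lapply(source_envs, function(e) {
      f <- src_fits[[e]]; env <- envs[[e]]
      c(gamma_from_sigma(f$sigma_x, f$mu_x, env$length_cm - f$mu_x),
        gamma_from_sigma(f$sigma_y, f$mu_y, env$width_cm - f$mu_y))
    }))
    gamma_k <- mean(gammas)
    # relocated centroid: mean relative position over the source envs
    rel <- rowMeans(vapply(source_envs, function(e) {
      f <- src_fits[[e]]; env <- envs[[e]]
      c(f$mu_x / env$length_cm, f$mu_y / env$width_cm)
    }, numeric(2L)))
    tgt <- envs[[target_env]]
    mu_x <- rel[1L] * tgt$length_cm
    mu_y <- rel[2L] * tgt$width_cm
    if (mu_x <= 0 || mu_x >= tgt$length_cm || mu_y <= 0 || mu_y >= tgt$width_cm) {
      warning(sprintf("field %d: relocated centroid outside target; skipped", k))
      next
    }
    sig_x <- sigma_from_gamma(gamma_k, mu_x, tgt$length_cm - mu_x)
    sig_y <- sigma_from_gamma(gamma_k, mu_y, tgt$width_cm - mu_y)
    obs_map <- maps[[target_env]]
    shape <- gaussian_ratemap(tgt, mu_x, mu_y, sig_x, sig_y, amplitude = 1,
                              bin_size_cm = obs_map$bin_size_cm)
    sh <- as.vector(shape$rates)
    ob <- as.vector(obs_map$rates)
    amp <- sum(sh * ob) / sum(sh^2)
    pred <- amp * sh
    r2_model <- r_squared(pred, ob)
    r2_opt <- fit_gaussian_ratemap(obs_map)$r2
    pred_maps[[length(pred_maps) + 1L]] <-
      rate_map(matrix(pmax(pred, 0), nrow = nrow(obs_map$rates)),
               obs_map$bin_size_cm, obs_map$origin)
    rows[[length(rows) + 1L]] <- data.frame(
      field = k, gamma = gamma_k, mu_x_cm = mu_x, mu_y_cm = mu_y,
      sigma_x_cm = sig_x, sigma_y_cm = sig_y, amplitude = amp,
      r2_model = r2_model, r2_optimal = r2_opt)
  }
  if (!length(rows)) stop("no usable fields for cross-environment prediction",
                          call. = FALSE)
  per_field <- do.call(rbind, rows)
  tt <- if (nrow(per_field) >= 2L &&
            stats::sd(per_field$r2_model - per_field$r2_optimal) > 0) {
    stats::t.test(per_field$r2_model, per_field$r2_optimal, paired = TRUE)
  } else {
    list(statistic = c(t = 0), p.value = 1)
  }
  list(per_field = per_field,
       mean_r2_model = mean(per_field$r2_model),
       mean_r2_optimal = mean(per_field$r2_optimal),
       t_statistic = unname(tt$statistic), t_p_value = tt$p.value,
       n_used = nrow(per_field), n_excluded = n_excl,
       predicted_maps = pred_maps)
}
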