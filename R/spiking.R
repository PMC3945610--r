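#' Leaky integrate-and-fire parameters
#'
#' Defaults are configuration values chosen so the cell is a genuine
#' coincidence detector: membrane time constant 10 ms (the effective in-vivo
#' constant under synaptic bombardment, shorter than in vitro), synaptic time
#' constant 5 ms, rest and reset at -70 mV, threshold -56 mV, PSP amplitude
#' 8 mV, membrane noise sd 1 mV, Euler step 0.1 ms. With these values a lone
#' PSP peaks 6 noise-sd below threshold (no output), while two PSPs arriving
#' within the coincidence window cross it. The absolute refractory period
#' after an output spike defaults to the coincidence-detection window
#' [temporal_resolution()], so one window yields at most one output spike.
#'
#' @param tau_m_ms Membrane time constant (ms).
#' @param tau_s_ms Synaptic time constant (ms).
#' @param v_rest_mV Resting potential (mV).
#' @param v_thresh_mV Spike threshold (mV); must exceed `v_rest_mV`.
#' @param v_reset_mV Post-spike reset potential (mV).
#' @param psp_amp_mV Peak amplitude of a single postsynaptic potential (mV).
#' @param sigma_v_mV Standard deviation of membrane-potential fluctuation
#'   (mV).
#' @param dt_ms Integration step (ms).
#' @param refractory_ms Absolute refractory period (ms); `NULL` means the
#'   coincidence window.
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(tau_m_ms = 10, tau_s_ms = 5, v_rest_mV = -70,
                       v_thresh_mV = -56, v_reset_mV = -70, psp_amp_mV = 8,
                       sigma_v_mV = 1, dt_ms = 0.1, refractory_ms = NULL) {
  if (tau_m_ms <= 0 || tau_s_ms <= 0 || dt_ms <= 0) {
    stop("tau_m_ms, tau_s_ms and dt_ms must be > 0", call. = FALSE)
  }
  if (v_thresh_mV <= v_rest_mV) {
    stop("v_thresh_mV must exceed v_rest_mV", call. = FALSE)
  }
  if (psp_amp_mV <= 0) stop("psp_amp_mV must be > 0", call. = FALSE)
  if (sigma_v_mV < 0) stop("sigma_v_mV must be >= 0", call. = FALSE)
  p <- structure(list(tau_m_ms = tau_m_ms, tau_s_ms = tau_s_ms,
                      v_rest_mV = v_rest_mV, v_thresh_mV = v_thresh_mV,
                      v_reset_mV = v_reset_mV, psp_amp_mV = psp_amp_mV,
                      sigma_v_mV = sigma_v_mV, dt_ms = dt_ms,
                      refractory_ms = refractory_ms),
                 class = "lif_params")
  if (is.null(p$refractory_ms)) p$refractory_ms <- temporal_resolution(p)
  p
}

#' Temporal resolution of coincidence detection
#'
#' The window within which inputs must arrive to be treated as coincident,
#' approximated from the membrane-potential fluctuation `sigma_V`, the
#' membrane time constant `tau_m` and the PSP amplitude `A` as
#' `delta_t = sigma_V * tau_m / A`. With membrane fluctuation and time
#' constant values observed in vivo in CA1 (sigma_V ~2 mV, tau_m ~20-30 ms)
#' and a PSP amplitude just under the rest-to-threshold gap (~15 mV), this
#' gives a few milliseconds -- the same order as the 5-10 ms coincidence
#' window measured in vitro in CA1.
#'
#' @param params A [lif_params()] object.
#' @return Window length `delta_t` in ms (positive).
#' @export
temporal_resolution <- function(params) {
  stopifnot(inherits(params, "lif_params"))
  with(params, {
    if (sigma_v_mV <= 0 || tau_m_ms <= 0 || psp_amp_mV <= 0) {
      stop("temporal resolution needs positive sigma_v, tau_m and psp_amp",
           call. = FALSE)
    }
    sigma_v_mV * tau_m_ms / psp_amp_mV
  })
}

#' Gaussian spatial tuning of an input neuron
#'
#' @param center_cm Field centre (cm).
#' @param sigma_cm Tuning width (cm); positive.
#' @param peak_rate_hz Peak firing rate (Hz); non-negative.
#' @return An object of class `gaussian_rate_field`.
#' @export
gaussian_rate_field <- function(center_cm, sigma_cm, peak_rate_hz) {
  if (sigma_cm <= 0) stop("sigma_cm must be > 0", call. = FALSE)
  if (peak_rate_hz < 0) stop("peak_rate_hz must be >= 0", call. = FALSE)
  structure(list(center_cm = center_cm, sigma_cm = sigma_cm,
                 peak_rate_hz = peak_rate_hz), class = "gaussian_rate_field")
}

#' Evaluate a Gaussian rate field at positions
#'
#' @param field A [gaussian_rate_field()].
#' @param positions_cm Positions (cm).
#' @return Firing rates (Hz).
#' @export
field_rate <- function(field, positions_cm) {
  field$peak_rate_hz *
    exp(-(positions_cm - field$center_cm)^2 / (2 * field$sigma_cm^2))
}

#' Construct a trajectory
#'
#' @param times_s Strictly increasing sample times (s).
#' @param positions_cm Positions at those times (cm); same length.
#' @return An object of class `pf_trajectory`.
#' @export
trajectory <- function(times_s, positions_cm) {
  if (length(times_s) != length(positions_cm)) {
    stop("times and positions must have equal length", call. = FALSE)
  }
  if (any(diff(times_s) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  structure(list(times_s = as.numeric(times_s),
                 positions_cm = as.numeric(positions_cm)),
            class = "pf_trajectory")
}

traj_position <- function(traj, t_s) {
  stats::approx(traj$times_s, traj$positions_cm, xout = t_s, rule = 2)$y
}

#' Sample a non-homogeneous Poisson spike train
#'
#' Per-bin Bernoulli sampling at resolution `dt_ms`: a bin at time `t` emits
#' a spike with probability `rate(t) * dt`. Seeded and reproducible.
#'
#' An optional absolute refractory period removes spikes following a
#' previous one within `refractory_ms`; with the refractory set to the
#' coincidence window, the train matches the binary per-window spike-train
#' function of the coincidence rule (an input cannot register twice within
#' one window).
#'
#' @param rate_fn Function mapping times (s) to rates (Hz); must be
#'   non-negative.
#' @param duration_s Train duration (s).
#' @param dt_ms Sampling resolution (ms).
#' @param seed Optional integer seed (set before sampling).
#' @param refractory_ms Absolute refractory period (ms); 0 for a pure
#'   Poisson process.
#' @return Sorted spike times (s).
#' @export
poisson_train <- function(rate_fn, duration_s, dt_ms = 0.1, seed = NULL,
                          refractory_ms = 0) {
  if (!is.null(seed)) set.seed(seed)
  t_s <- seq(0, duration_s, by = dt_ms / 1000)
  t_s <- t_s[t_s < duration_s]
  rates <- rate_fn(t_s)
  if (any(rates < 0)) stop("negative rate encountered", call. = FALSE)
  p <- rates * dt_ms / 1000
  spikes <- t_s[stats::runif(length(t_s)) < p]
  if (refractory_ms > 0 && length(spikes) > 1L) {
    ref_s <- refractory_ms / 1000
    keep <- logical(length(spikes))
    last <- -Inf
    for (i in seq_along(spikes)) {
      if (spikes[i] - last >= ref_s) {
        keep[i] <- TRUE
        last <- spikes[i]
      }
    }
    spikes <- spikes[keep]
  }
  spikes
}

#' Coincidence detection over input spike trains
#'
#' Implements the binary coincidence rule on windows of width `delta_t_ms`:
#' an output spike occurs in a window exactly when at least
#' `ceiling(theta * n)` distinct inputs each fired at least one spike inside
#' that window (a Heaviside threshold on the proportion of active inputs).
#' Output spikes are discretized at the window centres.
#'
#' @param inputs List of spike-time vectors (s); non-empty.
#' @param theta Proportion of inputs required, in `(0, 1]`. The default 1
#'   requires all inputs to coincide.
#' @param delta_t_ms Window width (ms); positive.
#' @param duration_s Duration covered (s); defaults to the latest spike.
#' @return Output spike times (s) at window centres.
#' @export
coincidence_train <- function(inputs, theta = 1, delta_t_ms,
                              duration_s = NULL) {
  if (!length(inputs)) stop("empty input list", call. = FALSE)
  if (theta <= 0 || theta > 1) stop("theta must be in (0, 1]", call. = FALSE)
  if (delta_t_ms <= 0) stop("delta_t_ms must be > 0", call. = FALSE)
  dt_s <- delta_t_ms / 1000
  if (is.null(duration_s)) {
    duration_s <- max(c(0, unlist(inputs))) + dt_s
  }
  n <- length(inputs)
  need <- ceiling(theta * n)
  counts <- integer(ceiling(duration_s / dt_s))
  for (tr in inputs) {
    w <- unique(pmin(floor(tr / dt_s) + 1L, length(counts)))
    counts[w] <- counts[w] + 1L
  }
  which(counts >= need) * dt_s - dt_s / 2
}

# peak membrane response to a unit jump of the synaptic variable; used to
# scale weights so one input spike produces a PSP of peak psp_amp_mV.
psp_unit_peak <- function(tau_m, tau_s) {
  if (abs(tau_m - tau_s) < 1e-9) return(exp(-1))
  t_star <- log(tau_m / tau_s) * tau_m * tau_s / (tau_m - tau_s)
  (tau_s / (tau_m - tau_s)) * (exp(-t_star / tau_m) - exp(-t_star / tau_s))
}

#' Simulate a place cell receiving Gaussian-tuned Poisson inputs
#'
#' Each input neuron fires a non-homogeneous Poisson train whose rate is its
#' Gaussian tuning evaluated along the trajectory. The place cell is a
#' current-based LIF neuron (Euler integration, exponential synapse, noise on
#' the membrane potential, spike-and-reset at threshold). With the default
#' near-coincidence threshold the cell fires only when inputs arrive within
#' the coincidence window, so its output field approximates the product of
#' the input rate profiles — the Bayesian posterior.
#'
#' Input trains carry an absolute refractory period (default 15 ms),
#' matching the binary per-window semantics of the coincidence rule (an
#' input cannot register twice within a window) and keeping the steady-state
#' summation ceiling of a single train, `A / (1 - exp(-R / tau_m))`, several
#' noise-sd below threshold -- without this, temporal summation of one input
#' alone fires the cell and coincidence detection degrades into addition.
#'
#' @param lif A [lif_params()] object; `dt_ms` must be at most `tau_s_ms / 2`
#'   for stability.
#' @param input_fields List of [gaussian_rate_field()]s.
#' @param traj A [trajectory()].
#' @param seed Optional integer seed.
#' @param trace_every Store every n-th membrane-potential sample (0 = none).
#' @param input_refractory_ms Absolute refractory of the input trains (ms).
#' @return List with `spikes_s`, `v_trace` (data frame `t_s`, `v_mV`),
#'   `input_trains` (list of spike-time vectors) and `delta_t_ms`.
#' @export
simulate_place_cell <- function(lif, input_fields, traj, seed = NULL,
                                trace_every = 10L,
                                input_refractory_ms = 15) {
  stopifnot(inherits(lif, "lif_params"), inherits(traj, "pf_trajectory"))
  if (lif$dt_ms > lif$tau_s_ms / 2) {
    stop("dt_ms too large for stability (must be <= tau_s_ms / 2)",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  duration_s <- max(traj$times_s)
  input_trains <- lapply(input_fields, function(f) {
    poisson_train(function(t) field_rate(f, traj_position(traj, t)),
                  duration_s, dt_ms = lif$dt_ms,
                  refractory_ms = input_refractory_ms)
  })
  w <- lif$psp_amp_mV / psp_unit_peak(lif$tau_m_ms, lif$tau_s_ms)
  ev_t <- unlist(input_trains) * 1000
  ord <- order(ev_t)
  ev_t <- ev_t[ord]
  ev_w <- rep(w, length(ev_t))
  res <- lif_integrate_cpp(ev_t, ev_w, duration_s * 1000, lif$dt_ms,
                           lif$tau_m_ms, lif$tau_s_ms, lif$v_rest_mV,
                           lif$v_thresh_mV, lif$v_reset_mV, lif$sigma_v_mV,
                           lif$refractory_ms, as.integer(trace_every))
  list(spikes_s = res$spike_t_ms / 1000,
       v_trace = data.frame(t_s = res$trace_t_ms / 1000,
                            v_mV = res$trace_v_mv),
       input_trains = input_trains,
       delta_t_ms = temporal_resolution(lif))
}

#' Posterior location estimate from output spikes
#'
#' Maps the output spike times to positions along the trajectory and
#' estimates the represented Gaussian by the mean and standard deviation of
#' the noise-filtered spike positions: points beyond 3 standard deviations of
#' the running mean are trimmed iteratively (at most `max_pass` passes).
#'
#' @param spikes_s Output spike times (s); at least 5.
#' @param traj A [trajectory()].
#' @param max_pass Maximum trimming passes.
#' @return List of class `posterior_estimate` with `mu`, `sigma`, `n_used`,
#'   `n_trimmed`, `degenerate` (TRUE when all surviving positions coincide).
#' @export
posterior_from_spikes <- function(spikes_s, traj, max_pass = 5L) {
  if (length(spikes_s) < 5L) stop("need >= 5 output spikes", call. = FALSE)
  pos <- traj_position(traj, spikes_s)
  keep <- pos
  for (i in seq_len(max_pass)) {
    m <- mean(keep)
    s <- stats::sd(keep)
    if (!is.finite(s) || s == 0) break
    inside <- abs(keep - m) <= 3 * s
    if (all(inside)) break
    keep <- keep[inside]
  }
  s <- stats::sd(keep)
  structure(list(mu = mean(keep),
                 sigma = if (is.finite(s)) s else 0,
                 n_used = length(keep),
                 n_trimmed = length(pos) - length(keep),
                 degenerate = !is.finite(s) || s == 0),
            class = "posterior_estimate")
}

#' Error of coincidence-based multiplication
#'
#' Runs the two-input place-cell simulation `reps` times (deterministic
#' per-rep seeds derived from `seed`) and returns the mean absolute
#' difference between the simulated posterior mean (via
#' [posterior_from_spikes()]) and the exact Gaussian-product posterior mean.
#' Repetitions with too few output spikes are discarded with a warning.
#'
#' @param lif A [lif_params()] object.
#' @param prior_field,obs_field [gaussian_rate_field()]s for the
#'   path-integration prior and the observation.
#' @param traj A [trajectory()].
#' @param seed Master integer seed.
#' @param reps Number of repetitions.
#' @return Mean absolute posterior-mean error (cm), with attributes
#'   `errors` (per-rep) and `n_discarded`.
#' @export
multiplication_error <- function(lif, prior_field, obs_field, traj,
                                 seed = 1L, reps = 10L) {
  exact_mu <- gaussian_product_mean(prior_field$center_cm,
                                    prior_field$sigma_cm,
                                    obs_field$center_cm, obs_field$sigma_cm)
  errs <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    sim <- simulate_place_cell(lif, list(prior_field, obs_field), traj,
                               seed = rep_seed(seed, r), trace_every = 0L)
    if (length(sim$spikes_s) >= 5L) {
      est <- posterior_from_spikes(sim$spikes_s, traj)
      errs[r] <- abs(est$mu - exact_mu)
    }
  }
  n_disc <- sum(is.na(errs))
  if (n_disc > 0L) {
    warning(sprintf("%d of %d repetitions produced too few output spikes and were discarded",
                    n_disc, reps))
  }
  if (n_disc == reps) stop("no repetition produced output spikes",
                           call. = FALSE)
  structure(mean(errs, na.rm = TRUE), errors = errs, n_discarded = n_disc)
}

#' Exact mean of a product of two Gaussians
#'
#' Precision-weighted mean `(mu1/s1^2 + mu2/s2^2) / (1/s1^2 + 1/s2^2)`.
#'
#' @param mu1,sigma1,mu2,sigma2 Means and sds of the two factors.
#' @return The product-Gaussian mean.
#' @export
gaussian_product_mean <- function(mu1, sigma1, mu2, sigma2) {
  (mu1 / sigma1^2 + mu2 / sigma2^2) / (1 / sigma1^2 + 1 / sigma2^2)
}

#' Multiplication-error surface over LIF parameters
#'
#' Evaluates [multiplication_error()] on a grid of membrane time constants
#' and spike thresholds (other parameters fixed), mapping where coincidence
#' detection approximates multiplication well. Cells where no repetition
#' yields output spikes are `NaN`.
#'
#' @param lif Baseline [lif_params()].
#' @param tau_m_grid_ms Membrane time constants (ms).
#' @param v_thresh_grid_mV Spike thresholds (mV).
#' @param prior_field,obs_field Input [gaussian_rate_field()]s.
#' @param traj A [trajectory()].
#' @param seed Master seed.
#' @param reps Repetitions per grid point.
#' @return Matrix of errors, rows indexing `tau_m_grid_ms`, columns
#'   `v_thresh_grid_mV` (dimnames carry the grids).
#' @export
error_surface <- function(lif, tau_m_grid_ms, v_thresh_grid_mV, prior_field,
                          obs_field, traj, seed = 1L, reps = 5L) {
  if (!length(tau_m_grid_ms) || !length(v_thresh_grid_mV)) {
    stop("grids must be non-empty", call. = FALSE)
  }
  out <- matrix(NA_real_, length(tau_m_grid_ms), length(v_thresh_grid_mV),
                dimnames = list(tau_m_grid_ms, v_thresh_grid_mV))
  for (i in seq_along(tau_m_grid_ms)) {
    for (j in seq_along(v_thresh_grid_mV)) {
      p <- lif
      p$tau_m_ms <- tau_m_grid_ms[i]
      p$v_thresh_mV <- v_thresh_grid_mV[j]
      p$refractory_ms <- temporal_resolution(p)
      out[i, j] <- tryCatch(
        suppressWarnings(as.numeric(
          multiplication_error(p, prior_field, obs_field, traj,
                               seed = seed + 1000L * i + j, reps = reps))),
        error = function(e) NaN)
    }
  }
  out
}

#' Probability that the animal is on a path interval
#'
#' Treats output spikes as samples of the posterior: discretizes time into
#' windows of width `delta_t_ms`, and returns the fraction of spike-bearing
#' windows whose trajectory position falls in `[x_a, x_b)` (closed at the
#' trajectory's maximum position so a partition of the domain sums to one).
#'
#' @param spikes_s Output spike times (s); non-empty.
#' @param interval Numeric `c(x_a, x_b)` (cm), within the trajectory range.
#' @param traj A [trajectory()].
#' @param delta_t_ms Window width (ms).
#' @return Probability in `[0, 1]`.
#' @export
path_probability <- function(spikes_s, interval, traj, delta_t_ms) {
  if (!length(spikes_s)) stop("zero output spikes", call. = FALSE)
  stopifnot(length(interval) == 2L, interval[1L] <= interval[2L])
  dt_s <- delta_t_ms / 1000
  win <- unique(floor(spikes_s / dt_s))
  pos <- traj_position(traj, (win + 0.5) * dt_s)
  hi <- max(traj$positions_cm)
  in_int <- pos >= interval[1L] &
    (pos < interval[2L] | (interval[2L] >= hi & pos <= interval[2L]))
  mean(in_int)
}

#' Position-binned firing-rate profile of a spike train
#'
#' Bins spikes by trajectory position, divides by occupancy time, and
#' smooths with a centred moving average; used to read out the peak firing
#' rate of a simulated place field.
#'
#' @param spikes_s Spike times (s).
#' @param traj A [trajectory()].
#' @param bin_cm Position bin width (cm).
#' @param smooth_window Moving-average window in bins (1 = none).
#' @return Data frame with `position_cm` (bin centres), `rate_hz`,
#'   `occupancy_s`.
#' @export
spike_rate_profile <- function(spikes_s, traj, bin_cm = 2,
                               smooth_window = 3L) {
  rng <- range(traj$positions_cm)
  breaks <- seq(rng[1L], rng[2L] + bin_cm, by = bin_cm)
  # occupancy from a dense resampling of the trajectory
  dt <- min(diff(traj$times_s)) / 2
  tt <- seq(min(traj$times_s), max(traj$times_s), by = dt)
  occ_pos <- traj_position(traj, tt)
  occ <- as.vector(table(cut(occ_pos, breaks, include.lowest = TRUE))) * dt
  cnt <- as.vector(table(cut(traj_position(traj, spikes_s), breaks,
                             include.lowest = TRUE)))
  rate <- ifelse(occ > 0, cnt / occ, NA_real_)
  rate[is.na(rate)] <- 0
  if (smooth_window > 1L) rate <- moving_average(rate, smooth_window)
  data.frame(position_cm = breaks[-length(breaks)] + bin_cm / 2,
             rate_hz = rate, occupancy_s = occ)
}

# deterministic per-repetition seed derived from a master seed (kept < 2^31)
rep_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 1009 + r * 9973) %% 2147483647)
}
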