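#' Run one pipeline command from a config
#'
#' Orchestration layer tying the modules into reproducible runs. The config
#' is a JSON (or YAML) file, or an equivalent named list, with a `command`
#' field naming one of: `generate`, `fit-gamma`, `fit-subset`,
#' `predict-crossenv`, `simulate-spiking`, `sweep-error`, `report`. A single
#' `seed` field governs all randomness; every run writes its artifacts plus a
#' `log.json` echoing the config, seed and package version, so a run is
#' reproducible from its log alone. A thin command-line wrapper around this
#' function ships in `inst/scripts/placefuse-cli.R`.
#'
#' @param config Path to a JSON/YAML config, or a named list.
#' @param out_dir Output directory (created if missing).
#' @param seed Optional integer overriding the config's seed.
#' @param verbose Print progress messages?
#' @return Invisibly, a list with `command`, `artifacts` (paths) and
#'   `results` (command-specific).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, verbose = FALSE) {
  cfg <- load_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$command)) stop("config lacks a 'command'", call. = FALSE)
  cmds <- c("generate", "fit-gamma", "fit-subset", "predict-crossenv",
            "simulate-spiking", "sweep-error", "report")
  if (!cfg$command %in% cmds) {
    stop(sprintf("unknown command '%s' (expected one of: %s)", cfg$command,
                 paste(cmds, collapse = ", ")), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  say("running '%s' (seed %d) -> %s", cfg$command, cfg$seed, out_dir)
  res <- switch(cfg$command,
    "generate" = pipe_generate(cfg, out_dir),
    "fit-gamma" = pipe_fit_gamma(cfg, out_dir),
    "fit-subset" = pipe_fit_subset(cfg, out_dir),
    "predict-crossenv" = pipe_crossenv(cfg, out_dir),
    "simulate-spiking" = pipe_simulate(cfg, out_dir),
    "sweep-error" = pipe_sweep(cfg, out_dir),
    "report" = pipe_report(cfg, out_dir))
  log_path <- file.path(out_dir, "log.json")
  jsonlite::write_json(
    list(command = cfg$command, seed = cfg$seed, config = cfg,
         package_version = as.character(utils::packageVersion("placefuse")),
         artifacts = res$artifacts),
    log_path, auto_unbox = TRUE, digits = NA, force = TRUE, null = "null")
  invisible(list(command = cfg$command,
                 artifacts = c(res$artifacts, log.json = log_path),
                 results = res$results))
}

load_config <- function(config) {
  if (is.list(config)) return(config)
  if (!file.exists(config)) {
    stop(sprintf("config file not found: %s", config), call. = FALSE)
  }
  if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package needed to read YAML configs", call. = FALSE)
    }
    yaml::read_yaml(config)
  } else {
    jsonlite::read_json(config, simplifyVector = TRUE)
  }
}

require_input <- function(path, what) {
  if (is.null(path) || !file.exists(path)) {
    stop(sprintf("missing input: %s (%s)", what,
                 if (is.null(path)) "not configured" else path),
         call. = FALSE)
  }
  path
}

config_environment <- function(cfg) {
  if (!is.null(cfg$environment_file)) {
    read_environment(require_input(cfg$environment_file, "environment config"))
  } else if (!is.null(cfg$environment)) {
    environment_from_config(cfg$environment)
  } else {
    stop("config needs 'environment' or 'environment_file'", call. = FALSE)
  }
}

pipe_generate <- function(cfg, out_dir) {
  env <- config_environment(cfg)
  spec <- synthetic_spec(env,
                         gamma_true = cfg$gamma_true %||% 0.1,
                         mask_true = if (!is.null(cfg$mask_true))
                           subset_mask(cfg$mask_true) else NULL,
                         n_cells = cfg$n_cells %||% 100L,
                         multi_field_prob = cfg$multi_field_prob %||% 0,
                         noise_cv = cfg$noise_cv %||% 0,
                         seed = cfg$seed)
  arts <- character()
  if (inherits(env, "rect_env")) {
    fields <- gen_linear_track(spec)
    fp <- file.path(out_dir, "fields.csv")
    write_fields_csv(fields, fp)
    arts <- c(fields = fp)
  } else {
    out <- gen_circular_track(spec)
    fp <- file.path(out_dir, "fields.csv")
    sp <- file.path(out_dir, "spikes.csv")
    write_fields_csv(out$fields, fp)
    utils::write.csv(out$spikes, sp, row.names = FALSE)
    arts <- c(fields = fp, spikes = sp)
  }
  ep <- file.path(out_dir, "environment.json")
  write_environment(env, ep)
  pv <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(list(gamma_true = spec$gamma_true,
                            mask_true = if (!is.null(spec$mask_true))
                              as.integer(spec$mask_true) else NULL,
                            n_cells = spec$n_cells,
                            multi_field_prob = spec$multi_field_prob,
                            noise_cv = spec$noise_cv, seed = spec$seed),
                       pv, auto_unbox = TRUE, digits = NA, null = "null")
  list(artifacts = c(arts, environment.json = ep, provenance.json = pv),
       results = list(spec = spec))
}

fit_report_list <- function(fit) {
  list(gamma = fit$params$gamma, beta = fit$params$beta,
       alpha = fit$params$alpha,
       mask = if (!is.null(fit$mask)) as.integer(fit$mask) else NULL,
       r2 = fit$r2, r2_adj = fit$r2_adj, pearson_r = fit$pearson_r,
       n_params_used = fit$n_params_used)
}

pipe_fit_gamma <- function(cfg, out_dir) {
  env <- config_environment(cfg)
  fields <- read_fields_csv(require_input(cfg$fields, "field table"))
  fit <- if (inherits(env, "circular_track")) {
    fit_gamma_track(fields$arc_cm, fields$size_value, env,
                    alpha = cfg$alpha %||% 0)
  } else {
    fit_gamma_rect(fields[, c("x_cm", "y_cm")], fields$size_value, env,
                   alpha = cfg$alpha %||% 0)
  }
  rep_list <- fit_report_list(fit)
  if (!is.null(fit$coverage)) rep_list$coverage <- fit$coverage
  if (length(fields$size_value) >= 8L) {
    rt <- residual_tests(fields$size_value, fit$predicted)
    rep_list$pearson_p <- rt$pearson_p
    rep_list$gof_p_data <- rt$chi2_data$p_value
    rep_list$gof_p_residuals <- rt$chi2_residuals$p_value
  }
  rp <- file.path(out_dir, "fit_gamma.json")
  jsonlite::write_json(rep_list, rp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  list(artifacts = c(fit_gamma.json = rp), results = list(fit = fit))
}

pipe_fit_subset <- function(cfg, out_dir) {
  env <- config_environment(cfg)
  if (!inherits(env, "circular_track")) {
    stop("fit-subset requires a circular_track environment", call. = FALSE)
  }
  fields <- read_fields_csv(require_input(cfg$fields, "field table"))
  fit <- fit_subset(fields$arc_cm, fields$size_value, env)
  rep_list <- fit_report_list(fit)
  rep_list$n_masks_evaluated <- fit$n_masks_evaluated
  rp <- file.path(out_dir, "fit_subset.json")
  jsonlite::write_json(rep_list, rp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  prof <- size_profile(env, cue_params(gamma = 1), fit$mask)
  pp <- file.path(out_dir, "profile.tsv")
  write_profile(prof, pp, params = fit$params, mask = fit$mask, env = env)
  list(artifacts = c(fit_subset.json = rp, profile.tsv = pp),
       results = list(fit = fit))
}

pipe_crossenv <- function(cfg, out_dir) {
  env_cfgs <- cfg$environments
  if (is.null(env_cfgs)) stop("config needs 'environments'", call. = FALSE)
  envs <- lapply(env_cfgs, environment_from_config)
  spec <- synthetic_spec(envs[[1L]], gamma_true = cfg$gamma_true %||% 0.3,
                         n_cells = cfg$n_cells %||% 8L,
                         noise_cv = cfg$noise_cv %||% 0, seed = cfg$seed)
  cells <- gen_openfield(spec, envs,
                         occupancy_s = cfg$occupancy_s %||% 30)
  res <- cross_env_predict(cells, envs,
                           source_envs = cfg$source_envs %||% c("C", "D"),
                           target_env = cfg$target_env %||% "B",
                           exclude_asymmetric = cfg$exclude_asymmetric %||% TRUE)
  rp <- file.path(out_dir, "crossenv.json")
  jsonlite::write_json(list(mean_r2_model = res$mean_r2_model,
                            mean_r2_optimal = res$mean_r2_optimal,
                            t_statistic = res$t_statistic,
                            t_p_value = res$t_p_value,
                            n_used = res$n_used,
                            n_excluded = res$n_excluded),
                       rp, auto_unbox = TRUE, digits = NA)
  pf <- file.path(out_dir, "crossenv_per_field.csv")
  utils::write.csv(res$per_field, pf, row.names = FALSE)
  list(artifacts = c(crossenv.json = rp, crossenv_per_field.csv = pf),
       results = res)
}

config_lif <- function(cfg) {
  lp <- cfg$lif %||% list()
  do.call(lif_params, lp)
}

config_inputs <- function(cfg) {
  lapply(cfg$inputs, function(f)
    gaussian_rate_field(f$center_cm, f$sigma_cm, f$peak_rate_hz))
}

config_traj <- function(cfg) {
  tr <- cfg$trajectory %||% list()
  gen_trajectory(rect_env(tr$length_cm %||% 100, tr$width_cm %||% 10),
                 speed_cm_s = tr$speed_cm_s %||% 20,
                 duration_s = tr$duration_s %||% 60)
}

pipe_simulate <- function(cfg, out_dir) {
  lif <- config_lif(cfg)
  inputs <- config_inputs(cfg)
  if (!length(inputs)) stop("config needs 'inputs' rate fields", call. = FALSE)
  traj <- config_traj(cfg)
  sim <- simulate_place_cell(lif, inputs, traj, seed = cfg$seed)
  sp <- file.path(out_dir, "spikes.tsv")
  trains <- rbind(
    data.frame(neuron_id = 0L, t_s = sim$spikes_s),
    do.call(rbind, lapply(seq_along(sim$input_trains), function(i)
      data.frame(neuron_id = i, t_s = sim$input_trains[[i]]))))
  utils::write.table(trains, sp, sep = "\t", row.names = FALSE, quote = FALSE)
  est <- if (length(sim$spikes_s) >= 5L) {
    posterior_from_spikes(sim$spikes_s, traj)
  } else {
    NULL
  }
  rp <- file.path(out_dir, "simulation.json")
  jsonlite::write_json(
    list(n_output_spikes = length(sim$spikes_s),
         delta_t_ms = sim$delta_t_ms,
         posterior_mu_cm = est$mu %||% NULL,
         posterior_sigma_cm = est$sigma %||% NULL),
    rp, auto_unbox = TRUE, digits = NA, null = "null")
  list(artifacts = c(spikes.tsv = sp, simulation.json = rp),
       results = list(sim = sim, estimate = est))
}

pipe_sweep <- function(cfg, out_dir) {
  lif <- config_lif(cfg)
  inputs <- config_inputs(cfg)
  if (length(inputs) != 2L) {
    stop("sweep-error needs exactly two 'inputs' (prior and observation)",
         call. = FALSE)
  }
  traj <- config_traj(cfg)
  surf <- error_surface(lif,
                        tau_m_grid_ms = cfg$tau_m_grid_ms %||% c(10, 20, 40),
                        v_thresh_grid_mV = cfg$v_thresh_grid_mV %||%
                          c(-66, -60, -54),
                        prior_field = inputs[[1L]], obs_field = inputs[[2L]],
                        traj = traj, seed = cfg$seed,
                        reps = cfg$reps %||% 5L)
  sp <- file.path(out_dir, "error_surface.csv")
  utils::write.table(surf, sp, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(tau_m_grid_ms = as.numeric(rownames(surf)),
                            v_thresh_grid_mV = as.numeric(colnames(surf)),
                            seed = cfg$seed),
                       paste0(sp, ".json"), auto_unbox = TRUE, digits = NA)
  list(artifacts = c(error_surface.csv = sp), results = list(surface = surf))
}

pipe_report <- function(cfg, out_dir) {
  paths <- cfg$inputs
  if (is.null(paths)) stop("report needs 'inputs' (JSON artifact paths)",
                           call. = FALSE)
  parts <- lapply(paths, function(p)
    jsonlite::read_json(require_input(p, "report input"),
                        simplifyVector = TRUE))
  names(parts) <- basename(unlist(paths))
  rp <- file.path(out_dir, "report.json")
  jsonlite::write_json(parts, rp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  list(artifacts = c(report.json = rp), results = parts)
}
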