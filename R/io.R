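#' Read an environment description from JSON
#'
#' The config dialect is `{"type": "rect", "length_cm": .., "width_cm": ..}`
#' or `{"type": "circular_track", "diameter_cm": .., "track_width_cm": ..,
#' "objects": [arc positions], "barrier": 0}`. Units are always cm.
#'
#' @param path Path to a JSON file.
#' @return A validated environment object.
#' @export
read_environment <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  environment_from_config(cfg)
}

#' Build an environment from a parsed config list
#'
#' @param cfg Named list (parsed JSON/YAML).
#' @return A validated environment object.
#' @export
environment_from_config <- function(cfg) {
  if (is.null(cfg$type)) stop("environment config lacks a 'type'", call. = FALSE)
  switch(cfg$type,
    rect = rect_env(cfg$length_cm, cfg$width_cm),
    circular_track = circular_track(
      diameter_cm = cfg$diameter_cm,
      track_width_cm = cfg$track_width_cm %||% 15,
      object_arcs_cm = as.numeric(cfg$objects %||% numeric()),
      barrier_arc_cm = cfg$barrier %||% 0),
    stop(sprintf("unknown environment type '%s'", cfg$type), call. = FALSE))
}

#' Write an environment description to JSON
#'
#' @param env A `rect_env` or `circular_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_environment <- function(env, path) {
  validate_environment(env)
  cfg <- if (inherits(env, "rect_env")) {
    list(type = "rect", length_cm = env$length_cm, width_cm = env$width_cm)
  } else {
    list(type = "circular_track", diameter_cm = env$diameter_cm,
         track_width_cm = env$track_width_cm,
         objects = env$object_arcs_cm, barrier = env$barrier_arc_cm)
  }
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a place-field table
#'
#' The CSV dialect has columns `cell_id`, `field_id`, coordinate columns
#' (`x_cm`,`y_cm` or `arc_cm`), `size_value` and `size_dialect`
#' (`"std"` or `"area"`; the two dialects are never mixed in one table).
#'
#' @param path CSV path.
#' @return Data frame of fields.
#' @export
read_fields_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "field_id", "size_value", "size_dialect")
  if (!all(need %in% names(df))) {
    stop("field table lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  if (length(unique(df$size_dialect)) > 1L) {
    stop("field table mixes size dialects", call. = FALSE)
  }
  df
}

#' @rdname read_fields_csv
#' @param fields Data frame of fields.
#' @export
write_fields_csv <- function(fields, path) {
  utils::write.csv(fields, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a rate map (CSV matrix plus JSON sidecar)
#'
#' The matrix CSV holds rates in Hz, rows indexing x bins; the sidecar
#' (`<path>.json`) records `bin_size_cm` and the origin.
#'
#' @param path CSV path (sidecar at `paste0(path, ".json")`).
#' @return A `rate_map`.
#' @export
read_ratemap <- function(path) {
  rates <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(rates) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rate_map(rates, bin_size_cm = meta$bin_size_cm,
           origin = point2d(meta$origin_x_cm %||% 0, meta$origin_y_cm %||% 0))
}

#' @rdname read_ratemap
#' @param map A `rate_map`.
#' @export
write_ratemap <- function(map, path) {
  stopifnot(inherits(map, "rate_map"))
  utils::write.table(map$rates, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(bin_size_cm = map$bin_size_cm,
                            origin_x_cm = map$origin$x_cm,
                            origin_y_cm = map$origin$y_cm),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a profile or curve as two-column delimited text
#'
#' Writes `(coordinate_cm, value)` rows plus a JSON sidecar recording the
#' model parameters, mask and environment description.
#'
#' @param profile Data frame whose first two columns are coordinate and
#'   value.
#' @param path Output path (sidecar at `paste0(path, ".json")`).
#' @param params Optional [cue_params()] recorded in the sidecar.
#' @param mask Optional [subset_mask()] recorded in the sidecar.
#' @param env Optional environment recorded (as its config) in the sidecar.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, params = NULL, mask = NULL,
                          env = NULL) {
  utils::write.table(profile[, 1:2], path, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  side <- list()
  if (!is.null(params)) {
    side$params <- list(gamma = params$gamma, beta = params$beta,
                        alpha = params$alpha)
  }
  if (!is.null(mask)) side$mask <- as.integer(mask)
  if (!is.null(env)) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp), add = TRUE)
    write_environment(env, tmp)
    side$environment <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
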