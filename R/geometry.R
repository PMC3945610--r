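#' Construct a 2D point
#'
#' Positions are continuous Cartesian coordinates in centimetres, origin at the
#' south-west corner of the environment, x increasing eastward and y northward.
#'
#' @param x_cm Position along the east-west axis (cm).
#' @param y_cm Position along the north-south axis (cm).
#' @return An object of class `point2d`.
#' @examples
#' point2d(30, 10)
#' @export
point2d <- function(x_cm, y_cm) {
  if (!is.finite(x_cm) || !is.finite(y_cm)) {
    stop("point2d coordinates must be finite", call. = FALSE)
  }
  structure(list(x_cm = as.numeric(x_cm), y_cm = as.numeric(y_cm)),
            class = "point2d")
}

#' @export
print.point2d <- function(x, ...) {
  cat(sprintf("<point2d (%.3f, %.3f) cm>\n", x$x_cm, x$y_cm))
  invisible(x)
}

#' Construct a rectangular environment
#'
#' Covers both narrow tracks and open boxes (e.g. the 61x61, 122x122, 61x122
#' and 122x61 cm boxes). The four walls are the observation sources.
#'
#' @param length_cm Extent along x (cm); must be positive.
#' @param width_cm Extent along y (cm); must be positive.
#' @return An object of class `rect_env` (also `pf_environment`).
#' @examples
#' rect_env(122, 122)
#' @export
rect_env <- function(length_cm, width_cm) {
  env <- structure(list(type = "rect",
                        length_cm = as.numeric(length_cm),
                        width_cm = as.numeric(width_cm)),
                   class = c("rect_env", "pf_environment"))
  validate_environment(env)
}

#' Construct a circular track with objects and a barrier
#'
#' The one-dimensional coordinate is arc length along the track midline,
#' measured counter-clockwise from the barrier, in `[0, circumference)`. The
#' printed diameter is interpreted as the midline diameter of the annulus.
#' The barrier blocks passage, so path distances never wrap across it.
#'
#' @param diameter_cm Midline diameter (cm); the in-vivo track was 106.7 cm.
#' @param track_width_cm Width of the annulus (cm); 15 cm in vivo.
#' @param object_arcs_cm Arc-length coordinates of the objects (cm), each in
#'   `[0, circumference)`. May be empty.
#' @param barrier_arc_cm Arc coordinate of the barrier; fixed at 0 by the
#'   coordinate convention (arcs are measured from the barrier).
#' @return An object of class `circular_track` (also `pf_environment`).
#' @examples
#' circular_track(106.7, 15, object_arcs_cm = c(40, 120, 250))
#' @export
circular_track <- function(diameter_cm, track_width_cm = 15,
                           object_arcs_cm = numeric(), barrier_arc_cm = 0) {
  env <- structure(list(type = "circular_track",
                        diameter_cm = as.numeric(diameter_cm),
                        track_width_cm = as.numeric(track_width_cm),
                        barrier_arc_cm = as.numeric(barrier_arc_cm),
                        object_arcs_cm = as.numeric(object_arcs_cm)),
                   class = c("circular_track", "pf_environment"))
  validate_environment(env)
}

#' Track circumference
#'
#' @param track A `circular_track`.
#' @return Midline circumference pi * diameter (cm).
#' @export
track_circumference <- function(track) {
  stopifnot(inherits(track, "circular_track"))
  pi * track$diameter_cm
}

#' Validate an environment object
#'
#' Checks the type invariants (positive extents, arc coordinates within
#' `[0, circumference)`) and returns the environment unchanged.
#'
#' @param env A `rect_env` or `circular_track`.
#' @return `env`, invisibly unchanged, if valid; otherwise an error naming the
#'   violated invariant.
#' @export
validate_environment <- function(env) {
  if (inherits(env, "rect_env")) {
    if (!is.finite(env$length_cm) || env$length_cm <= 0) {
      stop("invariant violated: length_cm must be > 0", call. = FALSE)
    }
    if (!is.finite(env$width_cm) || env$width_cm <= 0) {
      stop("invariant violated: width_cm must be > 0", call. = FALSE)
    }
  } else if (inherits(env, "circular_track")) {
    if (!is.finite(env$diameter_cm) || env$diameter_cm <= 0) {
      stop("invariant violated: diameter_cm must be > 0", call. = FALSE)
    }
    if (!is.finite(env$track_width_cm) || env$track_width_cm <= 0) {
      stop("invariant violated: track_width_cm must be > 0", call. = FALSE)
    }
    circ <- pi * env$diameter_cm
    arcs <- c(env$barrier_arc_cm, env$object_arcs_cm)
    if (length(arcs) && (any(!is.finite(arcs)) || any(arcs < 0) ||
                         any(arcs >= circ))) {
      stop("invariant violated: arc coordinates must lie in [0, circumference)",
           call. = FALSE)
    }
    if (env$barrier_arc_cm != 0) {
      stop("invariant violated: barrier_arc_cm must be 0 (arcs are measured from the barrier)",
           call. = FALSE)
    }
  } else {
    stop("unknown environment type", call. = FALSE)
  }
  invisible(env)
}

#' Distances from a point to the four walls of a rectangular environment
#'
#' Each wall contributes one observation: its perpendicular distance and the
#' unit normal along which it constrains position. Walls are ordered west,
#' east, south, north; opposing distances sum to the corresponding extent.
#'
#' @param p A `point2d` inside the environment.
#' @param env A `rect_env`.
#' @return A data frame with columns `wall`, `distance_cm`, `nx`, `ny`.
#' @examples
#' rect_boundary_distances(point2d(61, 61), rect_env(122, 122))
#' @export
rect_boundary_distances <- function(p, env) {
  stopifnot(inherits(p, "point2d"), inherits(env, "rect_env"))
  L <- env$length_cm
  W <- env$width_cm
  if (p$x_cm < 0 || p$x_cm > L) {
    stop(sprintf("point outside environment: x_cm = %g violates 0 <= x <= %g",
                 p$x_cm, L), call. = FALSE)
  }
  if (p$y_cm < 0 || p$y_cm > W) {
    stop(sprintf("point outside environment: y_cm = %g violates 0 <= y <= %g",
                 p$y_cm, W), call. = FALSE)
  }
  data.frame(
    wall = c("W", "E", "S", "N"),
    distance_cm = c(p$x_cm, L - p$x_cm, p$y_cm, W - p$y_cm),
    nx = c(1, 1, 0, 0),
    ny = c(0, 0, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Path distances along a circular track to its objects and barrier
#'
#' Distances are path lengths along the track midline that never cross the
#' barrier (the barrier blocks passage, with food trays on each side), so the
#' distance between arc coordinates `s` and `a` is simply `|s - a|`. The
#' barrier itself is reachable from either side; its distance is the minimum
#' over the two faces, `min(s, circumference - s)`.
#'
#' @param s Arc coordinate of the location (cm), in `[0, circumference)`.
#' @param track A `circular_track`.
#' @return A data frame with columns `source` ("object"/"barrier"), `arc_cm`
#'   and `distance_cm`, objects first (input order), barrier last. This order
#'   is the observation order used by subset masks throughout the package.
#' @examples
#' tr <- circular_track(106.7, 15, object_arcs_cm = c(50, 150))
#' track_distances(10, tr)
#' @export
track_distances <- function(s, track) {
  stopifnot(inherits(track, "circular_track"))
  circ <- track_circumference(track)
  if (!is.finite(s) || s < 0 || s >= circ) {
    stop(sprintf("arc coordinate %g outside [0, %g)", s, circ), call. = FALSE)
  }
  obj <- track$object_arcs_cm
  data.frame(
    source = c(rep("object", length(obj)), "barrier"),
    arc_cm = c(obj, track$barrier_arc_cm),
    distance_cm = c(abs(s - obj), min(s, circ - s)),
    stringsAsFactors = FALSE
  )
}
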