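# Path geometry: four-leg, three-turn walked paths and their landmark points.
#
# Canonical frame (left-turn chirality): start S at the origin, leg 1 along
# +y, all three 90-degree turns to the left, so
#   S = (0, 0), T1 = (0, L1), T2 = (-L2, L1), T3 = (-L2, L1 - L3),
#   E = (-L2 + L4, L1 - L3),
# and the final heading at E is +x. A right-turn spec is the mirror image
# (x negated), with final heading -x. Bearings are signed degrees relative to
# the final heading, positive clockwise, wrapped to (-180, 180].

GEOM_TOL <- 1e-9

#' Specify a four-leg walked path
#'
#' A path has four legs `L1..L4` (meters) joined by three 90-degree turns that
#' all go in the same direction. Whether the first and fourth legs cross
#' depends only on the leg lengths: the path crosses itself iff `L3 < L1` and
#' `L4 > L2`.
#'
#' @param leg_lengths numeric vector of four positive leg lengths in meters.
#' @param turn_direction `"left"` or `"right"`; applied at all three turns.
#' @param path_id label for the path.
#' @param experiment_tag optional label for the experiment/condition family.
#' @param arena_bound maximum leg length expected of real stimuli (meters).
#'   Legs exceeding it trigger a warning, not an error, so that hypothetical
#'   geometries can still be constructed.
#' @return an object of class `path_spec`.
#' @examples
#' path_spec(c(3, 2, 1.5, 3), "left", path_id = "P3")
#' @export
path_spec <- function(leg_lengths, turn_direction = c("left", "right"),
                      path_id = "path", experiment_tag = "",
                      arena_bound = 3.4) {
  turn_direction <- match.arg(turn_direction)
  if (length(leg_lengths) != 4 || !is.numeric(leg_lengths)) {
    stop("leg_lengths must be four numeric values", call. = FALSE)
  }
  if (any(!is.finite(leg_lengths)) || any(leg_lengths <= 0)) {
    stop("all four leg lengths must be positive and finite", call. = FALSE)
  }
  if (is.finite(arena_bound) && any(leg_lengths > arena_bound + GEOM_TOL)) {
    warning(sprintf("leg length exceeds the %.2f m arena bound", arena_bound),
            call. = FALSE)
  }
  structure(
    list(leg_lengths = as.numeric(leg_lengths),
         turn_direction = turn_direction,
         path_id = as.character(path_id),
         experiment_tag = as.character(experiment_tag)),
    class = "path_spec"
  )
}

#' @export
print.path_spec <- function(x, ...) {
  cat(sprintf("<path_spec %s> legs = [%s] m, %s turns%s\n",
              x$path_id, paste(format(x$leg_lengths), collapse = ", "),
              x$turn_direction,
              if (nzchar(x$experiment_tag)) paste0(" (", x$experiment_tag, ")")
              else ""))
  invisible(x)
}

#' Build the planar geometry of a path
#'
#' Computes the vertices, final heading, crossing topology, and every landmark
#' point used by the representational hypotheses:
#' \describe{
#'   \item{I}{walked intersection of legs 1 and 4 (crossed paths only).}
#'   \item{I_prime}{virtual intersection of the *extended* leg 4 with the line
#'     of leg 1 (uncrossed short-L4 paths).}
#'   \item{F1, F2}{false-intersection landmarks aligned with leg 1's line;
#'     F2 is where leg 4 crosses that line (uncrossed long-L3 paths). F1, the
#'     rendered gate on leg 1, has no analytic role and is placed at the
#'     midpoint of leg 1.}
#'   \item{E_prime}{endpoint of the hypothesized extension of leg 4 (short-L4
#'     paths; extension doubles the gap `|E - I'|`).}
#'   \item{E_prime_far}{point with E's x-coordinate and T1's y-coordinate
#'     (long-L3 paths; the represented end if the two false intersections are
#'     stacked).}
#' }
#' Boundary topologies (`L3 == L1` or `L4 == L2`), which would put the
#' intersection exactly at a path endpoint, are rejected, as is the
#' unsupported corner `L3 > L1 & L4 < L2` where no hypothesis landmark exists.
#'
#' @param spec a [path_spec()].
#' @return an object of class `path_geometry` with fields `S`, `T1`, `T2`,
#'   `T3`, `E`, `final_heading`, `crossing_class`, the applicable landmarks,
#'   and the originating `spec`.
#' @examples
#' g <- build_path(path_spec(c(3, 2, 1.5, 3), "left"))
#' g$crossing_class
#' g$I
#' @export
build_path <- function(spec) {
  stopifnot(inherits(spec, "path_spec"))
  L <- spec$leg_lengths
  L1 <- L[1]; L2 <- L[2]; L3 <- L[3]; L4 <- L[4]

  if (abs(L3 - L1) <= GEOM_TOL || abs(L4 - L2) <= GEOM_TOL) {
    stop("boundary topology: L3 = L1 or L4 = L2 puts the intersection at a ",
         "path endpoint", call. = FALSE)
  }

  crossing_class <-
    if (L3 < L1 && L4 > L2) "cross"
    else if (L4 < L2 && L3 < L1) "no_cross_short_L4"
    else if (L3 > L1 && L4 > L2) "no_cross_long_L3"
    else stop("unsupported topology: L3 > L1 with L4 < L2 has no hypothesis ",
              "landmarks", call. = FALSE)

  # canonical left-turn coordinates
  S  <- c(0, 0)
  T1 <- c(0, L1)
  T2 <- c(-L2, L1)
  T3 <- c(-L2, L1 - L3)
  E  <- c(-L2 + L4, L1 - L3)
  heading <- c(1, 0)

  landmarks <- list(I = NULL, I_prime = NULL, F1 = NULL, F2 = NULL,
                    E_prime = NULL, E_prime_far = NULL)
  if (crossing_class == "cross") {
    landmarks$I <- c(0, L1 - L3)
  } else if (crossing_class == "no_cross_short_L4") {
    landmarks$I_prime <- c(0, L1 - L3)
    # extension of leg 4 doubling the remaining gap |E - I'| = L2 - L4
    landmarks$E_prime <- c(L2 - L4, L1 - L3)
  } else { # no_cross_long_L3
    landmarks$F2 <- c(0, L1 - L3)
    landmarks$F1 <- c(0, L1 / 2)
    landmarks$E_prime_far <- c(-L2 + L4, L1)
  }

  mirror <- spec$turn_direction == "right"
  flip_x <- function(p) if (is.null(p)) NULL else c(-p[1], p[2])
  if (mirror) {
    S <- flip_x(S); T1 <- flip_x(T1); T2 <- flip_x(T2); T3 <- flip_x(T3)
    E <- flip_x(E); heading <- c(-1, 0)
    landmarks <- lapply(landmarks, flip_x)
  }

  structure(
    c(list(S = S, T1 = T1, T2 = T2, T3 = T3, E = E,
           final_heading = heading, crossing_class = crossing_class,
           spec = spec),
      landmarks),
    class = "path_geometry"
  )
}

#' @export
print.path_geometry <- function(x, ...) {
  cat(sprintf("<path_geometry %s> class = %s, E = (%.3f, %.3f)\n",
              x$spec$path_id, x$crossing_class, x$E[1], x$E[2]))
  invisible(x)
}

#' Signed bearing of one point from another in the end-heading frame
#'
#' The bearing of `target` seen from `origin` is the signed angle of the
#' vector `target - origin` relative to the path's final heading, positive
#' clockwise, wrapped to `(-180, 180]`. It is invariant to translating or
#' globally rotating the path, and flips sign exactly under mirroring.
#'
#' @param origin,target planar points (length-2 numeric), in the same frame as
#'   `geom`, or the name of a landmark in `geom` (e.g. `"E"`, `"I"`).
#' @param geom a [build_path()] result supplying the final heading.
#' @return signed bearing in degrees.
#' @examples
#' g <- build_path(path_spec(c(3, 2, 1.5, 3), "left"))
#' bearing("E", "I", g)  # 180
#' bearing("I", "S", g)  # 90
#' @export
bearing <- function(origin, target, geom) {
  stopifnot(inherits(geom, "path_geometry"))
  pt <- function(p) {
    if (is.character(p)) {
      stopifnot(length(p) == 1)
      q <- geom[[p]]
      if (is.null(q)) stop(sprintf("landmark '%s' is not defined for a %s path",
                                   p, geom$crossing_class), call. = FALSE)
      q
    } else {
      stopifnot(is.numeric(p), length(p) == 2)
      p
    }
  }
  o <- pt(origin); tg <- pt(target)
  v <- tg - o
  if (sqrt(sum(v^2)) <= GEOM_TOL) {
    stop("zero-length vector: origin and target coincide", call. = FALSE)
  }
  h <- geom$final_heading
  crossp <- h[1] * v[2] - h[2] * v[1]
  dotp <- h[1] * v[1] + h[2] * v[2]
  wrap_signed(-rad2deg(atan2(crossp, dotp)))
}

#' Geometrically correct pointing direction at the end of a path
#'
#' The bearing of the start S from the end E. For crossed paths this is
#' backward-oriented (absolute value above 90 degrees).
#'
#' @param geom a [build_path()] result.
#' @return signed bearing in degrees.
#' @examples
#' correct_pointing(build_path(path_spec(c(3, 2, 1.5, 3), "left")))
#' @export
correct_pointing <- function(geom) {
  stopifnot(inherits(geom, "path_geometry"))
  bearing(geom$E, geom$S, geom)
}

#' Length of the hypothesized extension of leg 4
#'
#' For an uncrossed short-L4 path, the no-cross-to-cross hypothesis extends
#' leg 4 past the line of leg 1 by the gap it originally fell short,
#' `L4 + 2 |E - I'| = 2 L2 - L4` in the canonical frame.
#'
#' @param geom a [build_path()] result with `crossing_class`
#'   `"no_cross_short_L4"`.
#' @return extended length in meters.
#' @examples
#' extended_leg4_length(build_path(path_spec(c(3, 2, 1.5, 1), "left")))
#' @export
extended_leg4_length <- function(geom) {
  stopifnot(inherits(geom, "path_geometry"))
  if (geom$crossing_class != "no_cross_short_L4") {
    stop("extended_leg4_length is defined only for no_cross_short_L4 paths",
         call. = FALSE)
  }
  L <- geom$spec$leg_lengths
  gap <- sqrt(sum((geom$E - geom$I_prime)^2))
  L[4] + 2 * gap
}

#' Euclidean end-to-start distance of a path
#'
#' @param geom a [build_path()] result.
#' @return distance `|E - S|` in meters.
#' @export
end_to_start_distance <- function(geom) {
  stopifnot(inherits(geom, "path_geometry"))
  sqrt(sum((geom$E - geom$S)^2))
}
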