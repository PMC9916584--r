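# Predicted pointing-direction intervals for the nine representational
# hypotheses about remembered path shape.
#
# Each hypothesis describes a family of distorted representations of the
# walked path (shortening/extending legs, deleting or creating the crossing)
# and predicts a clockwise arc of pointing directions in the end-heading
# frame. Within each admissible set the arcs have disjoint interiors, which
# is what makes the overlap-ratio comparison diagnostic.

HYPOTHESIS_IDS <- c("CtoC", "CtoN1", "CtoN2", "CtoN3",
                    "NtoN1", "NtoN2", "NtoC1", "NtoC2", "NtoC3")

#' Clockwise angular interval
#'
#' An arc on the circle of pointing directions, traversed clockwise (i.e. in
#' increasing canonical angle) from `from_bearing` to `to_bearing`, wrap-safe
#' across the +/-180 cut. Boundaries count as inside (closed arc).
#'
#' @param from_bearing,to_bearing arc boundaries, degrees in `(-180, 180]`.
#' @return an object of class `angular_interval`.
#' @examples
#' iv <- angular_interval(90, 180)
#' interval_width(iv)
#' interval_contains(iv, 135)
#' @export
angular_interval <- function(from_bearing, to_bearing) {
  stopifnot(is.numeric(from_bearing), is.numeric(to_bearing),
            length(from_bearing) == 1, length(to_bearing) == 1,
            is.finite(from_bearing), is.finite(to_bearing))
  from_bearing <- wrap_signed(from_bearing)
  to_bearing <- wrap_signed(to_bearing)
  w <- (to_bearing - from_bearing) %% 360
  if (w <= 0 || w >= 360) {
    stop("arc width must be strictly between 0 and 360 degrees",
         call. = FALSE)
  }
  structure(list(from_bearing = from_bearing, to_bearing = to_bearing,
                 width = w),
            class = "angular_interval")
}

#' @export
print.angular_interval <- function(x, ...) {
  cat(sprintf("<angular_interval> clockwise [%.2f, %.2f], width %.2f deg\n",
              x$from_bearing, x$to_bearing, x$width))
  invisible(x)
}

#' Arc width of an angular interval
#' @param interval an [angular_interval()].
#' @return width in degrees, in `(0, 360)`.
#' @export
interval_width <- function(interval) {
  stopifnot(inherits(interval, "angular_interval"))
  interval$width
}

#' Arc midpoint of an angular interval
#' @param interval an [angular_interval()].
#' @return canonical angle of the midpoint in degrees.
#' @export
interval_midpoint <- function(interval) {
  stopifnot(inherits(interval, "angular_interval"))
  wrap_signed(interval$from_bearing + interval$width / 2)
}

#' Test whether angles fall inside a (closed) angular interval
#' @param interval an [angular_interval()].
#' @param angle numeric vector of angles in degrees.
#' @param tol boundary tolerance in degrees.
#' @return logical vector.
#' @export
interval_contains <- function(interval, angle, tol = 1e-9) {
  stopifnot(inherits(interval, "angular_interval"), is.numeric(angle))
  d <- (angle - interval$from_bearing) %% 360
  d <= interval$width + tol | d >= 360 - tol
}

#' Arc length of the intersection of two angular intervals
#'
#' @param a,b [angular_interval()] objects.
#' @return total intersection arc length in degrees (0 if disjoint).
#' @export
interval_intersect_length <- function(a, b) {
  stopifnot(inherits(a, "angular_interval"), inherits(b, "angular_interval"))
  # place a at [0, wa); b starts at offset d, also appearing at d - 360
  d <- (b$from_bearing - a$from_bearing) %% 360
  seg <- function(lo, hi) max(0, min(hi, a$width) - max(lo, 0))
  seg(d, d + b$width) + seg(d - 360, d - 360 + b$width)
}

#' Admissible hypotheses for an experimental condition
#'
#' Crossed-path conditions (HI-C, PG-C, TI-C) admit the cross-origin
#' hypotheses CtoC and CtoN1-3. Uncrossed-path conditions admit
#' NtoN1/NtoN2/NtoC1 in the Experiment-1 path family (short fourth leg) and
#' NtoN1/NtoC2/NtoC3 in the Experiment-2/3 family (long third leg, where
#' false intersections can be rendered). NI-NC therefore maps to different
#' sets depending on the experiment.
#'
#' @param condition_label one of `"HI-C"`, `"NI-NC"`, `"PG-C"`, `"PG-NC"`,
#'   `"TI-C"`, `"FI-NC"`.
#' @param experiment experiment number (1, 2, 3 or 4); disambiguates NI-NC.
#' @return character vector of hypothesis ids.
#' @examples
#' admissible_set("FI-NC", experiment = 2)
#' @export
admissible_set <- function(condition_label, experiment = 1) {
  stopifnot(length(condition_label) == 1, is.character(condition_label))
  stopifnot(experiment %in% 1:4)
  cross_set <- c("CtoC", "CtoN1", "CtoN2", "CtoN3")
  switch(condition_label,
    "HI-C" = cross_set,
    "PG-C" = cross_set,
    "TI-C" = {
      if (experiment < 2) stop("TI-C only exists in Experiments 2-4",
                               call. = FALSE)
      cross_set
    },
    "PG-NC" = c("NtoN1", "NtoN2", "NtoC1"),
    "NI-NC" = if (experiment == 1) c("NtoN1", "NtoN2", "NtoC1")
              else c("NtoN1", "NtoC2", "NtoC3"),
    "FI-NC" = {
      if (experiment < 2) stop("FI-NC only exists in Experiments 2-4",
                               call. = FALSE)
      c("NtoN1", "NtoC2", "NtoC3")
    },
    stop(sprintf("unknown condition label '%s'", condition_label),
         call. = FALSE)
  )
}

# crossing classes for which each hypothesis is defined
hypothesis_classes <- function(hypothesis_id) {
  switch(hypothesis_id,
    CtoC = , CtoN1 = , CtoN2 = , CtoN3 = "cross",
    NtoN2 = , NtoC1 = "no_cross_short_L4",
    NtoC2 = , NtoC3 = "no_cross_long_L3",
    NtoN1 = c("no_cross_short_L4", "no_cross_long_L3"),
    stop(sprintf("unknown hypothesis id '%s'", hypothesis_id), call. = FALSE)
  )
}

#' Predicted pointing interval for a hypothesis on a path
#'
#' Boundaries are bearings of landmark points in the end-heading frame:
#' \describe{
#'   \item{CtoC}{`[bearing(I,S) = 90, bearing(E,I) = 180]` — crossing kept,
#'     legs 1 and 4 possibly shortened.}
#'   \item{CtoN1}{`[180, bearing(E,T1)]` — leg 1 shortened past the
#'     intersection (crossing deleted).}
#'   \item{CtoN2}{`[bearing(T3,S), 90]` — leg 4 shortened past the
#'     intersection.}
#'   \item{CtoN3}{`[-90, 0]`, i.e. `[bearing(I,T1), bearing(T3,I)]` — both
#'     legs shortened.}
#'   \item{NtoN1}{short-L4 family: `[bearing(E,T1), 0]` (leg 1 shortened,
#'     start remembered toward T1). Long-L3 family: the sweep of
#'     `bearing(E, S')` as the represented leg 1 runs from maximally
#'     shortened (S' at T1) to the largest extension that neither exceeds the
#'     arena bound nor creates a crossing (represented L1 capped at
#'     `min(arena_bound, L3)`).}
#'   \item{NtoN2}{`[bearing(T3,S), bearing(I',S) = 90]` — leg 4 under- or
#'     overestimated, crossing still absent.}
#'   \item{NtoC1}{`[90, bearing(E',S)]` — leg 4 extended to cross leg 1
#'     (E' from the doubled-gap extension).}
#'   \item{NtoC2}{`[bearing(E'_far, S), 180]` — the two false intersections
#'     remembered as one (leg 3 compressed).}
#'   \item{NtoC3}{`[bearing(F2,S) = -90, bearing(T3,S)]` — false
#'     intersections remembered as distinct nodes joined by an auxiliary
#'     segment.}
#' }
#'
#' @param hypothesis_id one of the nine hypothesis ids.
#' @param geom a [build_path()] result whose `crossing_class` admits the
#'   hypothesis.
#' @param arena_bound cap (meters) on represented leg lengths used by the
#'   long-L3 NtoN1 sweep.
#' @return an [angular_interval()].
#' @examples
#' g <- build_path(path_spec(c(3, 2, 1.5, 3), "left"))
#' predict_range("CtoC", g)
#' @export
predict_range <- function(hypothesis_id, geom, arena_bound = 3.4) {
  stopifnot(inherits(geom, "path_geometry"))
  hypothesis_id <- match.arg(hypothesis_id, HYPOTHESIS_IDS)
  ok <- hypothesis_classes(hypothesis_id)
  if (!(geom$crossing_class %in% ok)) {
    stop(sprintf(
      "hypothesis %s is not admissible for a %s path (admissible classes: %s)",
      hypothesis_id, geom$crossing_class, paste(ok, collapse = ", ")),
      call. = FALSE)
  }
  # Boundary bearings are computed in the geometry's own frame, so mirrored
  # (right-turn) geometries yield sign-flipped bounds; mirroring also reverses
  # clockwise traversal, so the boundary order is swapped for them.
  b <- function(o, t) bearing(o, t, geom)
  bounds <- switch(hypothesis_id,
    CtoC  = c(b("I", "S"), b("E", "I")),
    CtoN1 = c(b("E", "I"), b("E", "T1")),
    CtoN2 = c(b("T3", "S"), b("I", "S")),
    CtoN3 = c(b("I", "T1"), b("T3", "I")),
    NtoN2 = c(b("T3", "S"), b("I_prime", "S")),
    NtoC1 = c(b("I_prime", "S"), b("E_prime", "S")),
    NtoC2 = c(b("E_prime_far", "S"), 180),
    NtoC3 = c(b("F2", "S"), b("T3", "S")),
    NtoN1 = {
      if (geom$crossing_class == "no_cross_short_L4") {
        c(b("E", "T1"), 0)
      } else {
        L <- geom$spec$leg_lengths
        ell_max <- min(arena_bound, L[3])
        # S' for represented leg-1 length ell lies at distance ell from T1
        # back along the leg-1 line toward (and past) S.
        sprime <- function(ell) geom$T1 + ell * (geom$S - geom$T1) / L[1]
        c(bearing(geom$E, sprime(ell_max), geom),
          bearing(geom$E, geom$T1, geom))
      }
    }
  )
  if (identical(geom$spec$turn_direction, "right")) {
    # mirrored frame: the fixed straight-back (180) and ahead (0) bounds are
    # their own mirror images; computed landmark bearings flipped already.
    if (hypothesis_id == "NtoC2") bounds[2] <- 180
    if (hypothesis_id == "NtoN1" &&
        geom$crossing_class == "no_cross_short_L4") bounds[2] <- 0
    bounds <- rev(bounds)
  }
  angular_interval(bounds[1], bounds[2])
}

#' Circular mean of uniform draws within a predicted interval
#'
#' Reproduces the mean-prediction convention: the circular mean of `n_samples`
#' uniform random angles within the arc. As `n_samples` grows this converges
#' to the arc midpoint.
#'
#' @param interval an [angular_interval()].
#' @param n_samples number of uniform draws (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @return canonical angle in degrees.
#' @examples
#' range_mean(angular_interval(90, 180), seed = 1)
#' @export
range_mean <- function(interval, n_samples = 1000, seed = NULL) {
  stopifnot(inherits(interval, "angular_interval"))
  if (!is.numeric(n_samples) || n_samples < 1) {
    stop("n_samples must be at least 1", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    set.seed(seed)
    on.exit(restore_rng(old), add = TRUE)
  }
  draws <- interval$from_bearing +
    stats::runif(n_samples, 0, interval$width)
  circ_mean_rl(wrap_signed(draws))$mean
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Prediction table for a set of paths
#'
#' Tabulates, for every path and every admissible hypothesis, the predicted
#' clockwise interval and its mean direction — the package's analogue of a
#' predicted-ranges summary table.
#'
#' @param specs list of [path_spec()] objects.
#' @param condition_label condition whose admissible set to use; if `NULL`
#'   (default) every hypothesis admissible for each path's crossing class is
#'   tabulated.
#' @param experiment experiment number, passed to [admissible_set()].
#' @param n_samples,seed passed to [range_mean()].
#' @return data.frame with columns `path_id`, `hypothesis_id`, `from`, `to`,
#'   `width`, `mean`.
#' @export
prediction_table <- function(specs, condition_label = NULL, experiment = 1,
                             n_samples = 1000, seed = NULL) {
  stopifnot(is.list(specs))
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    set.seed(seed)
    on.exit(restore_rng(old), add = TRUE)
  }
  rows <- list()
  for (spec in specs) {
    geom <- build_path(spec)
    hyps <- if (is.null(condition_label)) {
      HYPOTHESIS_IDS[vapply(HYPOTHESIS_IDS, function(h)
        geom$crossing_class %in% hypothesis_classes(h), logical(1))]
    } else {
      admissible_set(condition_label, experiment)
    }
    for (h in hyps) {
      iv <- predict_range(h, geom)
      rows[[length(rows) + 1L]] <- data.frame(
        path_id = spec$path_id, hypothesis_id = h,
        from = iv$from_bearing, to = iv$to_bearing, width = iv$width,
        mean = range_mean(iv, n_samples = n_samples),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
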