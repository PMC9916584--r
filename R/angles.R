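# Angle arithmetic helpers.
#
# All public angles are in degrees. The canonical frame puts 0 at the walker's
# final heading, with positive angles measured clockwise (toward the start
# side of a canonical left-turn path). Wrapping maps onto (-180, 180], so the
# straight-back direction is +180, never -180.

#' Wrap angles into the canonical (-180, 180] range
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector with each element reduced modulo 360 into
#'   `(-180, 180]`.
#' @examples
#' wrap_signed(c(270, 540, -180))
#' @export
wrap_signed <- function(x) {
  stopifnot(is.numeric(x))
  y <- x %% 360
  ifelse(y > 180, y - 360, y)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Circular mean of angles in degrees; convention-free (works in any frame).
# Returns list(mean, r, n). mean is NA when the resultant is (numerically) zero.
circ_mean_rl <- function(x, zero_tol = 1e-9) {
  n <- length(x)
  th <- deg2rad(x)
  C <- sum(cos(th)) / n
  S <- sum(sin(th)) / n
  r <- sqrt(C^2 + S^2)
  m <- if (r <= zero_tol) NA_real_ else wrap_signed(rad2deg(atan2(S, C)))
  list(mean = m, r = r, n = n)
}
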