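# Descriptive and inferential circular statistics.
#
# Conventions: samples are vectors of angles in degrees (any frame); the mean
# direction is reported in (-180, 180]. The von Mises concentration kappa is
# estimated by maximum likelihood (inverting A1(kappa) = r with the
# Best-Fisher piecewise starting value refined by Newton iteration), with the
# standard small-sample correction below n = 16.

#' Descriptive circular statistics of a sample
#'
#' Computes the vector-sum mean direction, the mean resultant length
#' `r = |sum of unit vectors| / n`, the maximum-likelihood von Mises
#' concentration `kappa`, and a dispersion-based large-sample 95% confidence
#' interval for the mean direction (requires `n >= 3` and a non-degenerate
#' resultant; otherwise `NULL`).
#'
#' @param angles numeric vector of angles in degrees (`n >= 1`).
#' @return object of class `circ_descriptives`: a list with `n`,
#'   `mean_direction` (NA when the resultant is zero), `r`, `kappa`, `ci95`
#'   (an [angular_interval()] or `NULL`), and `mean_defined`.
#' @examples
#' circ_describe(c(10, 350, 5, -5))
#' @export
circ_describe <- function(angles) {
  stopifnot(is.numeric(angles), length(angles) >= 1, all(is.finite(angles)))
  n <- length(angles)
  m <- circ_mean_rl(angles)
  kappa <- kappa_ml(m$r, n)
  ci <- NULL
  if (n >= 3 && is.finite(m$mean) && m$r > 1e-9) {
    th <- deg2rad(angles - m$mean)
    rho2 <- sqrt(mean(cos(2 * th))^2 + mean(sin(2 * th))^2)
    disp <- (1 - rho2) / (2 * m$r^2)       # circular dispersion
    se <- sqrt(disp / n)
    arg <- stats::qnorm(0.975) * se
    half <- if (arg >= 1) 180 else rad2deg(asin(arg))
    if (half < 1e-9) {
      # all mass at one angle: degenerate zero-width interval at the mean
      ci <- structure(list(from_bearing = m$mean, to_bearing = m$mean,
                           width = 0), class = "angular_interval")
    } else if (half < 180) {
      ci <- angular_interval(wrap_signed(m$mean - half),
                             wrap_signed(m$mean + half))
    }
  }
  structure(list(n = n, mean_direction = m$mean, r = m$r, kappa = kappa,
                 ci95 = ci, mean_defined = is.finite(m$mean)),
            class = "circ_descriptives")
}

#' @export
print.circ_descriptives <- function(x, ...) {
  cat(sprintf(
    "<circ_descriptives> n = %d, mean = %s deg, r = %.4f, kappa = %.4f\n",
    x$n, if (x$mean_defined) sprintf("%.2f", x$mean_direction) else "undefined",
    x$r, x$kappa))
  invisible(x)
}

# A1(kappa) = I1(kappa) / I0(kappa), computed with scaled Bessel functions
A1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
}

# ML inversion of A1(kappa) = r: Best-Fisher piecewise start + Newton
# refinement; standard small-sample bias correction for n < 16.
kappa_ml <- function(r, n = Inf, tol = 1e-10) {
  stopifnot(r >= 0, r <= 1 + 1e-12)
  r <- min(r, 1)
  if (r < 1e-12) return(0)
  if (r > 1 - 1e-9) return(1e8)
  k <- if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
  for (i in 1:50) {
    a <- A1(k)
    deriv <- 1 - a / k - a^2          # d A1 / d kappa
    step <- (a - r) / deriv
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < tol * max(1, k)) { k <- k_new; break }
    k <- k_new
  }
  if (is.finite(n) && n < 16) {
    k <- if (k < 2) max(k - 2 / (n * k), 0) else k * (n - 1)^3 / (n^3 + n)
  }
  k
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that angles are uniformly distributed on the
#' circle against a unimodal alternative, using the statistic `z = n r^2` and
#' the standard series approximation for the p-value.
#'
#' @param angles numeric vector of angles in degrees, `n >= 5`.
#' @return a list of class `htest_circ` with `statistic` (z), `r`, `n`, and
#'   `p.value`.
#' @examples
#' rayleigh_test(c(10, 20, 15, 5, 0, 12, 18))
#' @export
rayleigh_test <- function(angles) {
  stopifnot(is.numeric(angles), all(is.finite(angles)))
  n <- length(angles)
  if (n < 5) stop("Rayleigh test requires n >= 5", call. = FALSE)
  r <- circ_mean_rl(angles)$r
  z <- n * r^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  p <- min(max(p, 0), 1)
  structure(list(method = "Rayleigh test of uniformity",
                 statistic = c(z = z), r = r, n = n, p.value = p),
            class = "htest_circ")
}

#' @export
print.htest_circ <- function(x, ...) {
  cat(sprintf("%s\n  %s = %.4f, p = %.4g\n", x$method,
              names(x$statistic)[1], x$statistic[1], x$p.value))
  invisible(x)
}

#' Mardia-Watson-Wheeler two-sample test
#'
#' Nonparametric uniform-scores test that two circular samples come from the
#' same distribution. Pooled observations are ranked on the circle, mapped to
#' uniform scores `beta = 2 pi rank / N`, and the statistic
#' `W = 2 * sum_j (C_j^2 + S_j^2) / n_j` is referred to a chi-square
#' distribution with 2 degrees of freedom. Ties are broken by midranks with a
#' warning.
#'
#' @param a,b numeric vectors of angles in degrees, each with `n >= 5`.
#' @return a list of class `htest_circ` with `statistic` (W), `df`, and
#'   `p.value`.
#' @export
mww_test <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b),
            all(is.finite(a)), all(is.finite(b)))
  if (length(a) < 5 || length(b) < 5) {
    stop("Mardia-Watson-Wheeler test requires n >= 5 in each sample",
         call. = FALSE)
  }
  pooled <- c(a, b) %% 360
  if (length(unique(pooled)) == 1) {
    stop("all values identical across both samples; test undefined",
         call. = FALSE)
  }
  if (anyDuplicated(pooled)) {
    warning("ties present; using midranks", call. = FALSE)
  }
  N <- length(pooled)
  beta <- 2 * pi * rank(pooled, ties.method = "average") / N
  idx <- rep(c(1L, 2L), c(length(a), length(b)))
  W <- 0
  for (j in 1:2) {
    bj <- beta[idx == j]
    W <- W + 2 * (sum(cos(bj))^2 + sum(sin(bj))^2) / length(bj)
  }
  structure(list(method = "Mardia-Watson-Wheeler uniform-scores test",
                 statistic = c(W = W), df = 2,
                 p.value = stats::pchisq(W, df = 2, lower.tail = FALSE)),
            class = "htest_circ")
}

#' Paired Hotelling test for circular samples
#'
#' Each angle is embedded as a unit vector `(cos, sin)`; the paired
#' differences of these vectors are tested for zero mean with Hotelling's
#' T-squared, referred to an `F(2, n - 2)` distribution.
#'
#' @param a,b paired numeric vectors of angles in degrees, equal length
#'   `n >= 3`.
#' @return a list of class `htest_circ` with `statistic` (F), `T2`, `df`, and
#'   `p.value`.
#' @export
hotelling_paired <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b),
            all(is.finite(a)), all(is.finite(b)))
  if (length(a) != length(b)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  n <- length(a)
  if (n < 3) stop("paired Hotelling test requires n >= 3", call. = FALSE)
  ra <- deg2rad(a); rb <- deg2rad(b)
  d <- cbind(cos(ra) - cos(rb), sin(ra) - sin(rb))
  dbar <- colMeans(d)
  if (max(abs(d)) < 1e-12) {
    T2 <- 0
  } else {
    S <- stats::cov(d)
    if (abs(det(S)) < 1e-300) {
      stop("degenerate covariance of paired differences", call. = FALSE)
    }
    T2 <- n * drop(t(dbar) %*% solve(S, dbar))
  }
  Fstat <- (n - 2) / (2 * (n - 1)) * T2
  structure(list(method = "Paired Hotelling test on unit-vector differences",
                 statistic = c(F = Fstat), T2 = T2, df = c(2, n - 2),
                 p.value = stats::pf(Fstat, 2, n - 2, lower.tail = FALSE)),
            class = "htest_circ")
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler (vectorized). `kappa = 0` gives the uniform
#' distribution on the circle.
#'
#' @param n number of draws.
#' @param mu mean direction in degrees.
#' @param kappa concentration parameter, `>= 0`.
#' @return numeric vector of angles in degrees in `(-180, 180]`.
#' @examples
#' set.seed(1); rvonmises(5, 90, 4)
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, is.finite(mu), kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-10) return(wrap_signed(stats::runif(n, 0, 360)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r0 <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    m <- length(need)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r0 * z) / (r0 + z)
    cc <- kappa * (r0 - f)
    accept <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3 - 0.5) * acos(f)
    out[need[accept]] <- th[accept]
    need <- need[!accept]
  }
  wrap_signed(mu + rad2deg(out))
}
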