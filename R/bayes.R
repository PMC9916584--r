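# Bayesian projected-normal mixed-effects estimation of pointing directions.
#
# Each observed angle theta_i is modeled as the direction of a latent
# bivariate normal vector with identity covariance:
#   r_i * u_i ~ N2(mu_i, I),  u_i = (cos theta_i, sin theta_i), r_i > 0,
#   mu_i = beta[cell_i, ] + b[subject_i, ]   (per component),
# with flat priors on the cell coefficients, subject random intercepts per
# component with inverse-gamma(0.001, 0.001) variances, and Gibbs updates
# throughout. The latent length r_i has the known univariate conditional
# density  f(r) proportional to r * phi(r - t_i),  t_i = mu_i . u_i,  which
# is sampled exactly by inverting its closed-form CDF with vectorized
# bisection. Per-cell posterior mean-direction draws are atan2 of the cell
# coefficients.

# Exact draw from f(r) ~ r * dnorm(r - t), r > 0, vectorized over t.
# CDF numerator: G(r) = phi(t) - phi(r - t) + t * (Phi(r - t) - Phi(-t)).
draw_latent_length <- function(t, steps = 30L) {
  Z <- stats::dnorm(t) + t * stats::pnorm(t)
  target <- stats::runif(length(t)) * Z
  phi_t <- stats::dnorm(t)
  pnorm_mt <- stats::pnorm(-t)
  lo <- rep(0, length(t))
  hi <- pmax(t, 0) + 8
  for (s in seq_len(steps)) {
    mid <- (lo + hi) / 2
    G <- phi_t - stats::dnorm(mid - t) + t * (stats::pnorm(mid - t) - pnorm_mt)
    below <- G < target
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

#' Fit a Bayesian projected-normal mixed-effects model to circular data
#'
#' Estimates a posterior mean pointing direction per cell (typically per
#' path) with optional subject random intercepts, by Gibbs sampling of the
#' latent-vector representation described above.
#'
#' @param angles numeric vector of canonical angles in degrees.
#' @param cell factor (or coercible) giving the fixed-effect cell of each
#'   observation, e.g. the path id.
#' @param subject optional factor giving the subject of each observation;
#'   `NULL` omits random effects. When supplied, at least 2 subjects are
#'   required.
#' @param n_iterations total MCMC iterations (default 1000).
#' @param burn_in iterations discarded from the front (default 200).
#' @param seed integer seed; fixed seed gives identical draws.
#' @return object of class `pn_fit`: `cells`, `direction_draws` (kept
#'   iterations x cells, degrees), `beta_draws` (kept x cells x 2),
#'   `tau2_draws`, `rhat` (split-half diagnostic per cell; a value above 1.1
#'   triggers a warning), `n_iterations`, `burn_in`, `seed`.
#' @examples
#' set.seed(1)
#' fit <- fit_projected_normal(rvonmises(60, 135, 4),
#'                             cell = rep("p1", 60),
#'                             n_iterations = 300, burn_in = 100, seed = 1)
#' circ_describe(fit$direction_draws[, 1])$mean_direction
#' @export
fit_projected_normal <- function(angles, cell, subject = NULL,
                                 n_iterations = 1000, burn_in = 200,
                                 seed = 1) {
  stopifnot(is.numeric(angles), all(is.finite(angles)))
  n <- length(angles)
  cell <- factor(cell)
  if (length(cell) != n) stop("cell must match angles in length",
                              call. = FALSE)
  has_re <- !is.null(subject)
  if (has_re) {
    subject <- factor(subject)
    if (length(subject) != n) stop("subject must match angles in length",
                                   call. = FALSE)
    if (nlevels(subject) < 2) {
      stop("random effects require at least 2 subjects", call. = FALSE)
    }
  }
  if (burn_in >= n_iterations) stop("burn_in must be below n_iterations",
                                    call. = FALSE)
  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit(restore_rng(old), add = TRUE)

  K <- nlevels(cell)
  ci <- as.integer(cell)
  n_cell <- tabulate(ci, K)
  th <- deg2rad(angles)
  u <- cbind(cos(th), sin(th))

  if (has_re) {
    J <- nlevels(subject)
    si <- as.integer(subject)
    n_subj <- tabulate(si, J)
  }

  # init at the per-cell resultant directions, unit length
  beta <- vapply(1:2, function(k)
    vapply(seq_len(K), function(p) mean(u[ci == p, k]), numeric(1)),
    numeric(K))
  beta <- matrix(beta, nrow = K)
  norms <- sqrt(rowSums(beta^2)); norms[norms < 1e-8] <- 1
  beta <- beta / norms
  b <- if (has_re) matrix(0, J, 2) else NULL
  tau2 <- c(1, 1)
  r <- rep(1, n)

  kept <- n_iterations - burn_in
  dir_draws <- matrix(NA_real_, kept, K,
                      dimnames = list(NULL, levels(cell)))
  beta_draws <- array(NA_real_, c(kept, K, 2),
                      dimnames = list(NULL, levels(cell), c("I", "II")))
  tau2_draws <- matrix(NA_real_, kept, 2)

  a0 <- 0.001; b0 <- 0.001
  for (it in seq_len(n_iterations)) {
    z <- r * u
    for (k in 1:2) {
      resid <- z[, k] - if (has_re) b[si, k] else 0
      m_p <- rowsum(resid, ci, reorder = TRUE)[, 1] / n_cell
      beta[, k] <- stats::rnorm(K, m_p, sqrt(1 / n_cell))
    }
    if (has_re) {
      for (k in 1:2) {
        resid <- z[, k] - beta[ci, k]
        s_j <- rowsum(resid, si, reorder = TRUE)[, 1]
        v <- 1 / (n_subj + 1 / tau2[k])
        b[, k] <- stats::rnorm(J, v * s_j, sqrt(v))
        tau2[k] <- 1 / stats::rgamma(1, a0 + J / 2, b0 + sum(b[, k]^2) / 2)
      }
    }
    mu <- beta[ci, , drop = FALSE] + if (has_re) b[si, , drop = FALSE] else 0
    t_i <- rowSums(mu * u)
    r <- draw_latent_length(t_i)

    if (it > burn_in) {
      kk <- it - burn_in
      dir_draws[kk, ] <- wrap_signed(rad2deg(atan2(beta[, 2], beta[, 1])))
      beta_draws[kk, , ] <- beta
      tau2_draws[kk, ] <- tau2
    }
  }

  rhat <- vapply(seq_len(K), function(p) split_half_rhat(dir_draws[, p]),
                 numeric(1))
  names(rhat) <- levels(cell)
  if (any(rhat > 1.1, na.rm = TRUE)) {
    warning("split-half diagnostic above 1.1 for cell(s): ",
            paste(names(rhat)[rhat > 1.1], collapse = ", "),
            "; posterior may not have converged", call. = FALSE)
  }

  structure(list(cells = levels(cell), direction_draws = dir_draws,
                 beta_draws = beta_draws, tau2_draws = tau2_draws,
                 rhat = rhat, n_iterations = n_iterations, burn_in = burn_in,
                 seed = seed, has_random = has_re),
            class = "pn_fit")
}

# crude split-half potential-scale-reduction on unwrapped direction draws
split_half_rhat <- function(d) {
  m <- circ_mean_rl(d)$mean
  if (!is.finite(m)) return(NA_real_)
  x <- wrap_signed(d - m)
  half <- length(x) %/% 2
  chains <- list(x[seq_len(half)], x[half + seq_len(half)])
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W < 1e-12) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' @export
print.pn_fit <- function(x, ...) {
  post <- vapply(seq_along(x$cells), function(p)
    circ_mean_rl(x$direction_draws[, p])$mean, numeric(1))
  cat(sprintf("<pn_fit> %d cells, %d kept draws%s\n", length(x$cells),
              nrow(x$direction_draws),
              if (x$has_random) ", subject random intercepts" else ""))
  for (p in seq_along(x$cells)) {
    cat(sprintf("  %s: posterior mean direction %.2f deg\n", x$cells[p],
                post[p]))
  }
  invisible(x)
}

#' Circular highest-posterior-density interval
#'
#' Shortest arc containing the requested posterior mass, computed by a
#' sliding window over draws unwrapped around their circular mean. Requires
#' concentrated draws (mean resultant length above 0.1); a circular HPD is
#' ill-defined for dispersed posteriors.
#'
#' @param draws numeric vector of angle draws in degrees, `>= 100`.
#' @param mass posterior mass to cover (default 0.95).
#' @return an [angular_interval()]; for numerically identical draws, a
#'   degenerate zero-width interval at the common value.
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  stopifnot(is.numeric(draws), all(is.finite(draws)),
            mass > 0, mass <= 1)
  n <- length(draws)
  if (n < 100) stop("HPD interval requires at least 100 draws", call. = FALSE)
  m <- circ_mean_rl(draws)
  if (m$r <= 0.1) {
    stop("draws too dispersed (resultant <= 0.1): circular HPD ill-defined",
         call. = FALSE)
  }
  x <- sort(wrap_signed(draws - m$mean))
  if (x[n] - x[1] < 1e-12) {
    lo <- wrap_signed(m$mean + x[1])
    return(structure(list(from_bearing = lo, to_bearing = lo, width = 0),
                     class = "angular_interval"))
  }
  w <- ceiling(mass * n)
  if (w >= n) {
    i <- 1L
    lo <- x[1]; hi <- x[n]
  } else {
    widths <- x[seq(w, n)] - x[seq(1, n - w + 1)]
    i <- which.min(widths)
    lo <- x[i]; hi <- x[i + w - 1]
  }
  angular_interval(wrap_signed(m$mean + lo), wrap_signed(m$mean + hi))
}

#' Overlap ratio between an HPD interval and a predicted range
#'
#' Arc length of the intersection divided by the arc length of the HPD
#' interval — the fraction of the posterior's credible arc lying inside the
#' hypothesis's predicted pointing range. 1 means the posterior is wholly
#' contained in the prediction; 0 means they are disjoint.
#'
#' @param hpd [angular_interval()] from [hpd_interval()] (zero-width
#'   degenerate intervals allowed).
#' @param predicted [angular_interval()] of the hypothesis.
#' @return ratio in `[0, 1]`.
#' @examples
#' overlap_ratio(angular_interval(80, 120), angular_interval(90, 180))
#' @export
overlap_ratio <- function(hpd, predicted) {
  stopifnot(inherits(hpd, "angular_interval"),
            inherits(predicted, "angular_interval"))
  if (hpd$width == 0) {
    return(as.numeric(interval_contains(predicted, hpd$from_bearing)))
  }
  min(1, interval_intersect_length(hpd, predicted) / hpd$width)
}

#' Compare representational hypotheses for one condition
#'
#' Fits the projected-normal mixed model (path cells, subject random
#' intercepts) to the per-participant per-path mean responses of one
#' condition, computes the 95% HPD interval of each path's posterior mean
#' direction, scores every admissible hypothesis by its overlap ratio on each
#' path, and ranks hypotheses by the mean ratio across paths.
#'
#' @param summaries a [summarize_trials()] table (degenerate cells are
#'   dropped).
#' @param condition_label condition to analyse.
#' @param specs list of [path_spec()]s covering the condition's paths.
#' @param experiment experiment number for [admissible_set()].
#' @param n_iterations,burn_in,seed passed to [fit_projected_normal()].
#' @param mass HPD mass (default 0.95).
#' @param arena_bound passed to [predict_range()].
#' @return object of class `fit_result`: `ratios` (hypothesis x path
#'   matrix), `mean_ratio` (named vector), `best_hypothesis` (character;
#'   length above 1 when the top ratios tie within 1e-6, with
#'   `ambiguous = TRUE`), `margin`, `hpd` (per path), `fit` (the `pn_fit`).
#' @export
compare_hypotheses <- function(summaries, condition_label, specs,
                               experiment = 1, n_iterations = 1000,
                               burn_in = 200, seed = 1, mass = 0.95,
                               arena_bound = 3.4) {
  hyps <- admissible_set(condition_label, experiment)
  rows <- summaries$condition_label == condition_label & !summaries$degenerate
  dat <- summaries[rows, , drop = FALSE]
  if (!nrow(dat)) stop(sprintf("no usable summaries for condition '%s'",
                               condition_label), call. = FALSE)
  if (length(unique(dat$participant_id)) < 2) {
    stop("at least 2 participants are required", call. = FALSE)
  }
  fit <- fit_projected_normal(dat$mean_response, cell = dat$path_id,
                              subject = dat$participant_id,
                              n_iterations = n_iterations, burn_in = burn_in,
                              seed = seed)
  score_fit(fit, hyps, specs, mass = mass, arena_bound = arena_bound)
}

#' Per-participant hypothesis comparison on individual trials
#'
#' Fits the projected-normal regression with path cells (no random effects)
#' to all of one participant's trials in a condition — no outlier exclusion —
#' and scores the admissible hypotheses as in [compare_hypotheses()].
#'
#' @param trials trial table (see [summarize_trials()] for the schema).
#' @param participant_id participant to analyse.
#' @param condition_label condition to analyse.
#' @param specs list of [path_spec()]s.
#' @param experiment experiment number.
#' @param min_trials minimum trial count required (default 16).
#' @param canonical_turn per-path canonical chirality (see
#'   [summarize_trials()]).
#' @param n_iterations,burn_in,seed,mass,arena_bound as in
#'   [compare_hypotheses()].
#' @return a `fit_result` (see [compare_hypotheses()]).
#' @export
compare_per_participant <- function(trials, participant_id, condition_label,
                                    specs, experiment = 1, min_trials = 16,
                                    canonical_turn = "left",
                                    n_iterations = 1000, burn_in = 200,
                                    seed = 1, mass = 0.95,
                                    arena_bound = 3.4) {
  rows <- trials$participant_id == participant_id &
    trials$condition_label == condition_label
  dat <- trials[rows, , drop = FALSE]
  if (nrow(dat) < min_trials) {
    stop(sprintf("participant '%s' has %d trials in '%s'; %d required",
                 participant_id, nrow(dat), condition_label, min_trials),
         call. = FALSE)
  }
  signed <- to_signed(dat$response_deg)
  canon <- canonicalize_response(signed, dat$turn_direction,
                                 canonical_turn = "left")
  ct <- vapply(dat$path_id, function(pid) {
    if (length(canonical_turn) == 1 && is.null(names(canonical_turn)))
      canonical_turn
    else if (is.null(canonical_turn[[pid]])) "left" else canonical_turn[[pid]]
  }, character(1))
  canon[ct != "left"] <- -canon[ct != "left"]
  canon <- wrap_signed(canon)

  fit <- fit_projected_normal(canon, cell = dat$path_id, subject = NULL,
                              n_iterations = n_iterations, burn_in = burn_in,
                              seed = seed)
  hyps <- admissible_set(condition_label, experiment)
  score_fit(fit, hyps, specs, mass = mass, arena_bound = arena_bound,
            canonical_turn = ct[match(fit$cells, dat$path_id)])
}

# shared scoring: per-path HPD -> overlap ratios -> best hypothesis
score_fit <- function(fit, hyps, specs, mass = 0.95, arena_bound = 3.4,
                      canonical_turn = NULL) {
  spec_ids <- vapply(specs, function(s) s$path_id, character(1))
  hpd <- lapply(seq_along(fit$cells), function(p)
    hpd_interval(fit$direction_draws[, p], mass = mass))
  names(hpd) <- fit$cells

  ratios <- matrix(NA_real_, length(hyps), length(fit$cells),
                   dimnames = list(hyps, fit$cells))
  for (pi in seq_along(fit$cells)) {
    pid <- fit$cells[pi]
    sp <- specs[[match(pid, spec_ids)]]
    if (is.na(match(pid, spec_ids))) {
      stop(sprintf("no path_spec for path '%s'", pid), call. = FALSE)
    }
    if (!is.null(canonical_turn)) sp$turn_direction <- canonical_turn[pi]
    geom <- suppressWarnings(build_path(sp))
    for (h in hyps) {
      ratios[h, pi] <- overlap_ratio(
        hpd[[pi]], predict_range(h, geom, arena_bound = arena_bound))
    }
  }
  mean_ratio <- rowMeans(ratios)
  top <- max(mean_ratio)
  best <- names(mean_ratio)[mean_ratio >= top - 1e-6]
  runner <- if (length(mean_ratio) > 1) {
    sort(mean_ratio, decreasing = TRUE)[2]
  } else NA_real_
  structure(list(ratios = ratios, mean_ratio = mean_ratio,
                 best_hypothesis = best, ambiguous = length(best) > 1,
                 margin = top - runner, hpd = hpd, fit = fit),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> mean overlap ratios across paths:\n")
  for (h in names(x$mean_ratio)) {
    cat(sprintf("  %-6s %.3f%s\n", h, x$mean_ratio[h],
                if (h %in% x$best_hypothesis) "  <- best" else ""))
  }
  if (x$ambiguous) cat("  (top ratios tie within 1e-6: ambiguous)\n")
  invisible(x)
}

#' Tabulate a fit result
#'
#' Long-format data.frame of per-path and mean overlap ratios, mirroring
#' hypothesis-comparison summary panels.
#'
#' @param result a `fit_result`.
#' @param condition optional condition label column.
#' @return data.frame with `condition`, `hypothesis`, `path_id`, `ratio`,
#'   `mean_ratio`, `best`.
#' @export
fit_result_table <- function(result, condition = "") {
  stopifnot(inherits(result, "fit_result"))
  long <- expand.grid(hypothesis = rownames(result$ratios),
                      path_id = colnames(result$ratios),
                      stringsAsFactors = FALSE)
  long$ratio <- result$ratios[cbind(long$hypothesis, long$path_id)]
  long$mean_ratio <- result$mean_ratio[long$hypothesis]
  long$best <- long$hypothesis %in% result$best_hypothesis
  cbind(condition = condition, long)
}
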