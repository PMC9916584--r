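# Synthetic experiment generator.
#
# Emulates the statistical structure the analysis assumes: von Mises
# pointing responses concentrated around hypothesis-predicted directions,
# subject-level random angular offsets, condition-dependent concentration, a
# small fraction of uniformly distributed discordant responses, and
# proportional underestimation of the pointing distance.

#' Construct the two path families used by the walking experiments
#'
#' Experiment-1 style: four crossed paths (`L3 < L1`, `L4 > L2`) and four
#' uncrossed paths with a short fourth leg (`L4 < L2`). Experiment-2/3
#' style: four crossed paths and four uncrossed long-third-leg partners
#' (`L3 > L1`, `L4 > L2`), where each cross/no-cross pair matches total path
#' length and Euclidean end-to-start distance exactly, and the mirrored
#' no-cross path has the same correct pointing angle as its crossed partner
#' (the no-cross endpoint is the reflection of the crossed endpoint across
#' the heading axis, with leg sums rebalanced in closed form). All legs stay
#' within the 3.4 m arena bound.
#'
#' @param experiment 1 or 2 (the Experiment-2 family also serves
#'   Experiments 3 and 4).
#' @param seed reserved for future randomized variants; the families are
#'   deterministic.
#' @return list of eight [path_spec()]s, ids `P1`-`P4` (crossed) and
#'   `P5`-`P8` (uncrossed).
#' @examples
#' vapply(make_experiment_paths(1), function(s)
#'   build_path(s)$crossing_class, character(1))
#' @export
make_experiment_paths <- function(experiment = 1, seed = NULL) {
  stopifnot(experiment %in% c(1, 2))
  crossed <- list(c(3.4, 1.7, 1.7, 3.4),
                  c(3.0, 1.5, 1.5, 2.9),
                  c(3.2, 2.0, 1.2, 3.1),
                  c(2.8, 1.4, 1.0, 2.7))
  tag <- paste0("exp", experiment)
  specs <- vector("list", 8)
  for (i in 1:4) {
    specs[[i]] <- path_spec(crossed[[i]], "left", path_id = paste0("P", i),
                            experiment_tag = tag)
  }
  if (experiment == 1) {
    uncrossed <- list(c(3.0, 2.0, 1.5, 1.0),
                      c(3.4, 2.4, 1.2, 1.4),
                      c(2.8, 1.8, 0.9, 1.2),
                      c(3.2, 2.2, 1.8, 1.6))
    for (i in 1:4) {
      specs[[4 + i]] <- path_spec(uncrossed[[i]], "left",
                                  path_id = paste0("P", 4 + i),
                                  experiment_tag = tag)
    }
  } else {
    bound <- 3.4
    for (i in 1:4) {
      a <- crossed[[i]]
      x <- a[4] - a[2]          # endpoint forward offset
      y <- a[1] - a[3]          # endpoint lateral offset (reflected)
      s <- a[1] + a[2] - y      # b1 + b2 must equal this for equal totals
      lo <- max(s - (bound - x), y * 0 + 1e-6)
      hi <- min(s - 1e-6, bound - y)
      if (lo > hi) {
        stop("infeasible matched no-cross partner for path ", i,
             call. = FALSE)
      }
      b1 <- min(max(s / 2, lo), hi)
      b <- c(b1, s - b1, b1 + y, s - b1 + x)
      specs[[4 + i]] <- path_spec(b, "left", path_id = paste0("P", 4 + i),
                                  experiment_tag = tag)
    }
  }
  specs
}

#' Configuration for a synthetic experiment
#'
#' Defaults reflect the walking studies the generator emulates: 32
#' participants, four trials per path shape (half of them on the mirrored
#' version), and mean proportional distance underestimation 0.29 (SD 0.20).
#' `condition_hypotheses` names the representational hypothesis that
#' actually generates each condition's responses; shapes are drawn from the
#' paths whose crossing class admits that hypothesis.
#'
#' @param paths list of [path_spec()]s (e.g. [make_experiment_paths()]).
#' @param condition_hypotheses named character vector, condition label ->
#'   generating hypothesis id.
#' @param n_subjects number of participants (default 32).
#' @param trials_per_path trials per path shape (default 4).
#' @param target_mode `"range_mean"` (trial target at the predicted range's
#'   mean direction) or `"uniform_in_range"` (fresh uniform draw inside the
#'   range per trial).
#' @param kappa_trial von Mises concentration of trial-level noise.
#' @param kappa_subject concentration of the subject-level angular offset
#'   (drawn once per subject and condition).
#' @param contamination_rate probability a response is replaced by a uniform
#'   draw on the circle.
#' @param distance_underestimation_mean,distance_underestimation_sd
#'   parameters of the truncated-normal proportional distance error.
#' @param seed integer seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(paths,
                         condition_hypotheses,
                         n_subjects = 32,
                         trials_per_path = 4,
                         target_mode = c("range_mean", "uniform_in_range"),
                         kappa_trial = 4,
                         kappa_subject = 8,
                         contamination_rate = 0.05,
                         distance_underestimation_mean = 0.29,
                         distance_underestimation_sd = 0.20,
                         seed = 1) {
  target_mode <- match.arg(target_mode)
  stopifnot(is.list(paths), length(paths) >= 1,
            all(vapply(paths, inherits, logical(1), "path_spec")))
  if (is.null(names(condition_hypotheses)) ||
      any(!nzchar(names(condition_hypotheses)))) {
    stop("condition_hypotheses must be a named vector (condition -> ",
         "hypothesis)", call. = FALSE)
  }
  if (any(!condition_hypotheses %in% HYPOTHESIS_IDS)) {
    stop("unknown hypothesis id in condition_hypotheses", call. = FALSE)
  }
  stopifnot(n_subjects >= 1, trials_per_path >= 1,
            kappa_trial >= 0, kappa_subject >= 0,
            contamination_rate >= 0, contamination_rate <= 1)
  structure(list(paths = paths,
                 condition_hypotheses = condition_hypotheses,
                 n_subjects = n_subjects,
                 trials_per_path = trials_per_path,
                 target_mode = target_mode,
                 kappa_trial = kappa_trial,
                 kappa_subject = kappa_subject,
                 contamination_rate = contamination_rate,
                 distance_underestimation_mean = distance_underestimation_mean,
                 distance_underestimation_sd = distance_underestimation_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

rtruncnorm_open <- function(n, mean, sd, lower = -1, upper = 1) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lower | out >= upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower | out[bad] >= upper]
  }
  out
}

# rotate a unit vector clockwise by `deg`
rotate_cw <- function(v, deg) {
  a <- deg2rad(deg)
  c(v[1] * cos(a) + v[2] * sin(a), -v[1] * sin(a) + v[2] * cos(a))
}

#' Generate a synthetic trial table
#'
#' For every subject and condition a random angular offset is drawn from
#' `vonMises(0, kappa_subject)`; each trial's target is the generating
#' hypothesis's predicted direction (range mean or a uniform draw within the
#' range), and the response is target + offset + `vonMises(0, kappa_trial)`
#' noise, replaced with probability `contamination_rate` by a uniform draw.
#' Half the trials of each shape use the mirrored (right-turn) path, and raw
#' responses are emitted in the pre-flip 0-360 convention of each trial's
#' own chirality. Landing coordinates place the response at the responded
#' distance `correct * (1 - p)`, `p` truncated-normal, along the responded
#' direction.
#'
#' @param config a [synth_config()].
#' @return data.frame with columns `participant_id`, `condition_label`,
#'   `path_id`, `trial_index`, `turn_direction`, `response_deg`,
#'   `landing_x`, `landing_y`; attribute `seed` records the generator seed.
#' @examples
#' cfg <- synth_config(make_experiment_paths(1),
#'                     c("HI-C" = "CtoN1", "NI-NC" = "NtoN1"),
#'                     n_subjects = 2, seed = 7)
#' nrow(generate_dataset(cfg))  # 2 subjects x 2 conditions x 4 paths x 4
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- globalenv()$.Random.seed
  set.seed(config$seed)
  on.exit(restore_rng(old), add = TRUE)

  spec_ids <- vapply(config$paths, function(s) s$path_id, character(1))
  geoms <- lapply(config$paths, function(s) suppressWarnings(build_path(s)))
  classes <- vapply(geoms, function(g) g$crossing_class, character(1))

  conds <- names(config$condition_hypotheses)
  rows <- vector("list", 0)
  for (cond in conds) {
    hyp <- config$condition_hypotheses[[cond]]
    ok <- classes %in% hypothesis_classes(hyp)
    if (!any(ok)) {
      stop(sprintf(
        "no path in config admits hypothesis %s (condition %s)", hyp, cond),
        call. = FALSE)
    }
    use <- which(ok)
    intervals <- lapply(use, function(i) predict_range(hyp, geoms[[i]]))
    targets <- vapply(intervals, interval_midpoint, numeric(1))

    for (s in seq_len(config$n_subjects)) {
      sid <- sprintf("S%02d", s)
      offset <- rvonmises(1, 0, config$kappa_subject)
      for (w in seq_along(use)) {
        i <- use[w]
        geom_l <- geoms[[i]]
        for (tr in seq_len(config$trials_per_path)) {
          turn <- if (tr %% 2 == 1) "left" else "right"
          target <- if (config$target_mode == "range_mean") {
            targets[w]
          } else {
            iv <- intervals[[w]]
            wrap_signed(iv$from_bearing + stats::runif(1, 0, iv$width))
          }
          canonical <- if (stats::runif(1) < config$contamination_rate) {
            wrap_signed(stats::runif(1, 0, 360))
          } else {
            wrap_signed(target + offset +
                          rvonmises(1, 0, config$kappa_trial))
          }
          # raw response in the trial's own chirality frame
          signed_trial <- if (turn == "left") canonical else -canonical
          raw <- signed_trial %% 360

          sp <- config$paths[[i]]
          sp$turn_direction <- turn
          g <- suppressWarnings(build_path(sp))
          p_err <- rtruncnorm_open(1, config$distance_underestimation_mean,
                                   config$distance_underestimation_sd)
          resp_d <- end_to_start_distance(g) * (1 - p_err)
          dir <- rotate_cw(g$final_heading, signed_trial)
          landing <- g$E + resp_d * dir

          rows[[length(rows) + 1L]] <- data.frame(
            participant_id = sid, condition_label = cond,
            path_id = spec_ids[i], trial_index = tr,
            turn_direction = turn, response_deg = raw,
            landing_x = landing[1], landing_y = landing[2],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- config$seed
  out
}
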