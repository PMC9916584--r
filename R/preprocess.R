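# Raw trial responses -> canonicalized per-participant, per-path circular
# summaries with signed angular errors.

#' Convert a 0-360 degree response to a signed canonical angle
#'
#' @param deg360 numeric vector of angles in `[0, 360)` (0 = facing
#'   direction).
#' @return angles in `(-180, 180]`; exactly 180 maps to +180.
#' @examples
#' to_signed(c(270, 0, 180))
#' @export
to_signed <- function(deg360) {
  stopifnot(is.numeric(deg360))
  if (any(!is.finite(deg360)) || any(deg360 < 0 | deg360 >= 360)) {
    stop("responses must lie in [0, 360)", call. = FALSE)
  }
  wrap_signed(deg360)
}

#' Canonicalize a signed response for a path's chirality
#'
#' Mirror-image paths produce mirror-image pointing distributions; to pool
#' them, responses from paths whose turn direction differs from the canonical
#' chirality have their sign flipped. With the default `canonical_turn =
#' "left"` this reproduces the convention of flipping right-turn trials;
#' supplying `"right"` for particular paths reproduces designs where the
#' left-turn versions are the mirrored ones.
#'
#' @param signed_deg numeric vector of signed responses in `(-180, 180]`.
#' @param turn_direction `"left"` or `"right"` per response (recycled).
#' @param canonical_turn chirality of the canonical frame (scalar).
#' @return canonicalized angles in `(-180, 180]`.
#' @examples
#' canonicalize_response(-160, "right")   # 160
#' @export
canonicalize_response <- function(signed_deg, turn_direction,
                                  canonical_turn = "left") {
  stopifnot(is.numeric(signed_deg))
  turn_direction <- rep_len(as.character(turn_direction), length(signed_deg))
  if (!all(turn_direction %in% c("left", "right"))) {
    stop("turn_direction must be 'left' or 'right'", call. = FALSE)
  }
  if (!canonical_turn %in% c("left", "right")) {
    stop("canonical_turn must be 'left' or 'right'", call. = FALSE)
  }
  flip <- turn_direction != canonical_turn
  wrap_signed(ifelse(flip, -signed_deg, signed_deg))
}

#' Circular mean of trial responses for one path
#'
#' Direction of the vector sum of the unit vectors. When the resultant is
#' numerically zero (for example two antipodal trials), the mean is undefined
#' and `NA` is returned with a warning; such cells are excluded downstream.
#'
#' @param angles numeric vector of canonical angles in degrees, `n >= 1`.
#' @return mean direction in degrees, or `NA` for a degenerate cell.
#' @examples
#' per_path_mean(c(10, 350, 20, 340))
#' @export
per_path_mean <- function(angles) {
  stopifnot(is.numeric(angles), length(angles) >= 1, all(is.finite(angles)))
  m <- circ_mean_rl(angles)
  if (!is.finite(m$mean)) {
    warning("zero resultant: circular mean undefined; cell flagged degenerate",
            call. = FALSE)
    return(NA_real_)
  }
  m$mean
}

#' Signed angular pointing error
#'
#' `response - correct`, wrapped to `(-180, 180]`. Positive errors are
#' clockwise of the correct direction in the canonical frame.
#'
#' @param response,correct canonical angles in degrees (vectorized).
#' @return wrapped signed differences.
#' @examples
#' angular_error(-170, 170)  # 20
#' @export
angular_error <- function(response, correct) {
  stopifnot(is.numeric(response), is.numeric(correct))
  wrap_signed(response - correct)
}

#' Proportional distance error
#'
#' `(correct - response) / correct`; positive values indicate
#' underestimation of the distance back to the start.
#'
#' @param correct_d correct Euclidean distance in meters, `> 0`.
#' @param response_d responded distance in meters, `>= 0`.
#' @return error proportion (vectorized).
#' @examples
#' distance_error_proportion(2, 1)  # 0.5
#' @export
distance_error_proportion <- function(correct_d, response_d) {
  stopifnot(is.numeric(correct_d), is.numeric(response_d))
  if (any(correct_d <= 0)) stop("correct distance must be positive",
                                call. = FALSE)
  if (any(response_d < 0)) stop("response distance must be non-negative",
                                call. = FALSE)
  (correct_d - response_d) / correct_d
}

#' Summarize a trial table into per-participant, per-path circular means
#'
#' For every participant x condition x path cell: signed responses are
#' canonicalized for chirality, circularly averaged across trials, and
#' compared with the geometrically correct pointing direction of the
#' canonical-chirality geometry to give the signed error `AE_G`. When landing
#' coordinates are present (columns `landing_x`, `landing_y`, in the frame of
#' the trial's own geometry), the pointing angle is recomputed from them for
#' trials missing `response_deg`; if both exist and disagree by more than
#' 0.1 degrees the explicit angle wins with a warning. Landing coordinates
#' also yield a per-cell mean proportional distance error.
#'
#' @param trials data.frame with columns `participant_id`, `condition_label`,
#'   `path_id`, `trial_index`, `turn_direction`, `response_deg`, optionally
#'   `landing_x`/`landing_y`.
#' @param specs list of [path_spec()] objects covering every `path_id`
#'   (chirality-free shape definitions; the trial's `turn_direction`
#'   determines the mirroring).
#' @param canonical_turn scalar or named character vector (by `path_id`)
#'   giving the canonical chirality per path; default `"left"` everywhere.
#' @return data.frame of class `subject_path_summary` with columns
#'   `participant_id`, `condition_label`, `path_id`, `mean_response`,
#'   `n_trials`, `AE_G`, `distance_error_proportion`, `degenerate`.
#' @export
summarize_trials <- function(trials, specs, canonical_turn = "left") {
  required <- c("participant_id", "condition_label", "path_id",
                "turn_direction", "response_deg")
  miss <- setdiff(required, names(trials))
  if (length(miss)) {
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  spec_ids <- vapply(specs, function(s) s$path_id, character(1))
  unknown <- setdiff(unique(trials$path_id), spec_ids)
  if (length(unknown)) {
    stop("unknown path_id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  canon_for <- function(pid) {
    if (length(canonical_turn) == 1 && is.null(names(canonical_turn))) {
      canonical_turn
    } else {
      ct <- canonical_turn[[pid]]
      if (is.null(ct)) "left" else ct
    }
  }
  has_landing <- all(c("landing_x", "landing_y") %in% names(trials))

  # geometry cache: path_id x turn
  geom_cache <- new.env(parent = emptyenv())
  get_geom <- function(pid, turn) {
    key <- paste(pid, turn)
    if (is.null(geom_cache[[key]])) {
      sp <- specs[[match(pid, spec_ids)]]
      sp$turn_direction <- turn
      geom_cache[[key]] <- suppressWarnings(build_path(sp))
    }
    geom_cache[[key]]
  }

  # resolve per-trial response angle (deg 0-360 convention -> signed)
  resp <- trials$response_deg
  if (has_landing) {
    from_landing <- rep(NA_real_, nrow(trials))
    ok <- is.finite(trials$landing_x) & is.finite(trials$landing_y)
    for (i in which(ok)) {
      g <- get_geom(trials$path_id[i], trials$turn_direction[i])
      from_landing[i] <- bearing(g$E, c(trials$landing_x[i],
                                        trials$landing_y[i]), g)
    }
    both <- ok & is.finite(resp)
    if (any(both)) {
      disagree <- abs(wrap_signed(wrap_signed(resp[both]) -
                                    from_landing[both])) > 0.1
      if (any(disagree)) {
        warning(sum(disagree), " trial(s) where the explicit response angle ",
                "and the landing-point bearing disagree by > 0.1 deg; ",
                "using the explicit angle", call. = FALSE)
      }
    }
    if (any(is.finite(resp) & (resp < 0 | resp >= 360))) {
      stop("responses must lie in [0, 360)", call. = FALSE)
    }
    signed <- ifelse(is.finite(resp), wrap_signed(resp), from_landing)
    if (any(!is.finite(signed))) {
      stop("trial(s) with neither a response angle nor landing coordinates",
           call. = FALSE)
    }
  } else {
    if (any(!is.finite(resp))) {
      stop("response_deg contains missing values and no landing coordinates ",
           "are available", call. = FALSE)
    }
    signed <- to_signed(resp)
  }

  canon <- vapply(trials$path_id, canon_for, character(1))
  canonical <- canonicalize_response(signed, trials$turn_direction,
                                     canonical_turn = "left")
  # per-path canonical chirality: flip relative to the path's declared frame
  flip2 <- canon != "left"
  canonical[flip2] <- -canonical[flip2]
  canonical <- wrap_signed(canonical)

  # per-trial distance errors from landing points
  dist_err <- rep(NA_real_, nrow(trials))
  if (has_landing) {
    ok <- is.finite(trials$landing_x) & is.finite(trials$landing_y)
    for (i in which(ok)) {
      g <- get_geom(trials$path_id[i], trials$turn_direction[i])
      resp_d <- sqrt(sum((c(trials$landing_x[i], trials$landing_y[i]) -
                            g$E)^2))
      dist_err[i] <- distance_error_proportion(end_to_start_distance(g),
                                               resp_d)
    }
  }

  key <- interaction(trials$participant_id, trials$condition_label,
                     trials$path_id, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(trials)), key), function(ii) {
    pid <- trials$path_id[ii[1]]
    g <- get_geom(pid, canon_for(pid))
    mr <- suppressWarnings(per_path_mean(canonical[ii]))
    data.frame(
      participant_id = trials$participant_id[ii[1]],
      condition_label = trials$condition_label[ii[1]],
      path_id = pid,
      mean_response = mr,
      n_trials = length(ii),
      AE_G = if (is.finite(mr)) angular_error(mr, correct_pointing(g))
             else NA_real_,
      distance_error_proportion =
        if (all(is.na(dist_err[ii]))) NA_real_
        else mean(dist_err[ii], na.rm = TRUE),
      degenerate = !is.finite(mr),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$degenerate)) {
    warning(sum(out$degenerate), " degenerate zero-resultant cell(s) flagged",
            call. = FALSE)
  }
  class(out) <- c("subject_path_summary", class(out))
  out
}
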