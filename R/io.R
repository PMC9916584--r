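# File formats and the end-to-end analysis pipeline.
#
# All tables are comma-separated UTF-8 text with a header row, "." decimals,
# angles in degrees and lengths in meters. Writers prepend comment lines
# ("# key: value") recording the package version, seed, and a configuration
# checksum; readers skip comment lines.

TRIAL_COLUMNS <- c("participant_id", "condition_label", "path_id",
                   "trial_index", "turn_direction", "response_deg")

config_checksum <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(txt)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

write_table_with_header <- function(df, file, meta = list()) {
  con <- file(file, "w", encoding = "UTF-8")
  on.exit(close(con))
  meta <- c(list(package = paste0("pathpoint ",
                                  as.character(utils::packageVersion(
                                    "pathpoint")))),
            meta)
  for (key in names(meta)) {
    writeLines(sprintf("# %s: %s", key, meta[[key]]), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}

#' Write / read a trial table
#'
#' @param trials data.frame with the trial-table schema (see
#'   [summarize_trials()]).
#' @param file path to a CSV file.
#' @param seed optional seed recorded in the file header.
#' @return `write_trial_table()` returns the path invisibly;
#'   `read_trial_table()` returns the data.frame.
#' @export
write_trial_table <- function(trials, file, seed = attr(trials, "seed")) {
  miss <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(miss)) {
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  meta <- list()
  if (!is.null(seed)) meta$seed <- seed
  write_table_with_header(trials, file, meta)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file, call. = FALSE)
  df <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(miss)) {
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write / read a path configuration table
#'
#' One record per path: `path_id`, `L1`..`L4` (meters), `turn_direction`,
#' `experiment_tag`.
#'
#' @param specs list of [path_spec()]s.
#' @param file path to a CSV file.
#' @return `write_path_config()` returns the path invisibly;
#'   `read_path_config()` returns a list of [path_spec()]s.
#' @export
write_path_config <- function(specs, file) {
  stopifnot(is.list(specs),
            all(vapply(specs, inherits, logical(1), "path_spec")))
  df <- do.call(rbind, lapply(specs, function(s) {
    data.frame(path_id = s$path_id, L1 = s$leg_lengths[1],
               L2 = s$leg_lengths[2], L3 = s$leg_lengths[3],
               L4 = s$leg_lengths[4], turn_direction = s$turn_direction,
               experiment_tag = s$experiment_tag, stringsAsFactors = FALSE)
  }))
  write_table_with_header(df, file)
}

#' @rdname write_path_config
#' @export
read_path_config <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file, call. = FALSE)
  df <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("path_id", "L1", "L2", "L3", "L4", "turn_direction")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("path config is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    suppressWarnings(path_spec(
      unlist(df[i, c("L1", "L2", "L3", "L4")], use.names = FALSE),
      turn_direction = df$turn_direction[i],
      path_id = df$path_id[i],
      experiment_tag = if ("experiment_tag" %in% names(df))
        df$experiment_tag[i] else ""))
  })
}

#' Write the derived landmark table for a set of paths
#'
#' Emits one row per path with vertices, crossing class, and every defined
#' landmark, as delimited text.
#'
#' @param specs list of [path_spec()]s.
#' @param file path to a CSV file.
#' @return the path, invisibly.
#' @export
write_landmark_table <- function(specs, file) {
  pt_cols <- function(p, name) {
    out <- list(if (is.null(p)) NA_real_ else p[1],
                if (is.null(p)) NA_real_ else p[2])
    names(out) <- paste0(name, c("_x", "_y"))
    out
  }
  df <- do.call(rbind, lapply(specs, function(s) {
    g <- suppressWarnings(build_path(s))
    as.data.frame(c(list(path_id = s$path_id,
                         crossing_class = g$crossing_class),
                    pt_cols(g$S, "S"), pt_cols(g$T1, "T1"),
                    pt_cols(g$T2, "T2"), pt_cols(g$T3, "T3"),
                    pt_cols(g$E, "E"), pt_cols(g$I, "I"),
                    pt_cols(g$I_prime, "I_prime"), pt_cols(g$F1, "F1"),
                    pt_cols(g$F2, "F2"), pt_cols(g$E_prime, "E_prime"),
                    pt_cols(g$E_prime_far, "E_prime_far")),
                  stringsAsFactors = FALSE)
  }))
  write_table_with_header(df, file)
}

#' Simulate a synthetic experiment, optionally writing its files
#'
#' Wraps [generate_dataset()]; when `out_dir` is given, writes `trials.csv`
#' and `paths.csv` there (headers carry the seed and a configuration
#' checksum), so a bundle can be reproduced bit-for-bit from the same
#' configuration.
#'
#' @param config a [synth_config()].
#' @param out_dir optional output directory (created if missing).
#' @return list with `trials`, `specs`, and (if written) `files`.
#' @export
simulate_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  trials <- generate_dataset(config)
  out <- list(trials = trials, specs = config$paths)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    tf <- file.path(out_dir, "trials.csv")
    pf <- file.path(out_dir, "paths.csv")
    meta <- list(seed = config$seed, config = config_checksum(config))
    write_table_with_header(trials, tf, meta)
    write_path_config(config$paths, pf)
    out$files <- c(trials = tf, paths = pf)
  }
  out
}

#' Run the full analysis pipeline for an experiment
#'
#' For each condition: summarize trials into per-participant per-path
#' circular means, run C-statistic outlier detection on the pooled signed
#' errors, compute circular descriptives and a Rayleigh test on the retained
#' errors, and compare the admissible representational hypotheses with the
#' projected-normal mixed model. Between-condition Mardia-Watson-Wheeler
#' tests on the retained errors are reported for every condition pair.
#'
#' @param trials trial table (see [summarize_trials()]).
#' @param specs list of [path_spec()]s.
#' @param conditions conditions to analyse (default: all in the table).
#' @param experiment experiment number for [admissible_set()].
#' @param canonical_turn per-path canonical chirality (see
#'   [summarize_trials()]).
#' @param n_sim_total,probability,reps outlier-detection parameters (see
#'   [detect_outliers()]); `n_sim_total = NULL` uses each condition's own
#'   pooled count.
#' @param n_iterations,burn_in MCMC parameters.
#' @param seed integer seed governing outlier simulation and MCMC.
#' @param out_dir optional directory for result tables and a run log.
#' @return list of class `pathpoint_analysis`: per-condition entries with
#'   `summaries`, `outliers`, `descriptives`, `rayleigh`, `fit`, plus
#'   `pairwise_mww`, `seed`, and `conditions`.
#' @export
analyze_experiment <- function(trials, specs,
                               conditions = NULL, experiment = 1,
                               canonical_turn = "left",
                               n_sim_total = NULL, probability = 0.90,
                               reps = 1000, n_iterations = 1000,
                               burn_in = 200, seed = 1, out_dir = NULL) {
  if (is.null(conditions)) conditions <- unique(trials$condition_label)
  unknown <- setdiff(conditions, unique(trials$condition_label))
  if (length(unknown)) {
    stop("condition(s) absent from the trial table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  summaries <- summarize_trials(trials, specs,
                                canonical_turn = canonical_turn)
  per_cond <- list()
  retained_err <- list()
  for (cond in conditions) {
    rows <- summaries$condition_label == cond & !summaries$degenerate
    sub <- summaries[rows, , drop = FALSE]
    rep_out <- detect_outliers(
      sub$AE_G,
      n_sim_total = if (is.null(n_sim_total)) nrow(sub) else n_sim_total,
      probability = probability, reps = reps, seed = seed)
    keep <- setdiff(seq_len(nrow(sub)), rep_out$excluded_indices)
    kept <- sub[keep, , drop = FALSE]
    retained_err[[cond]] <- kept$AE_G
    fit <- compare_hypotheses(kept, cond, specs, experiment = experiment,
                              n_iterations = n_iterations,
                              burn_in = burn_in, seed = seed)
    per_cond[[cond]] <- list(summaries = sub,
                             outliers = rep_out,
                             descriptives = circ_describe(kept$AE_G),
                             rayleigh = rayleigh_test(kept$AE_G),
                             fit = fit)
  }
  pairwise <- list()
  if (length(conditions) > 1) {
    combs <- utils::combn(conditions, 2, simplify = FALSE)
    for (pair in combs) {
      key <- paste(pair, collapse = " vs ")
      pairwise[[key]] <- mww_test(retained_err[[pair[1]]],
                                  retained_err[[pair[2]]])
    }
  }
  result <- structure(c(per_cond,
                        list(pairwise_mww = pairwise, seed = seed,
                             conditions = conditions)),
                      class = "pathpoint_analysis")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    meta <- list(seed = seed)
    ot <- do.call(rbind, lapply(conditions, function(cond)
      outlier_report_table(per_cond[[cond]]$outliers, cond)))
    write_table_with_header(ot, file.path(out_dir, "outliers.csv"), meta)
    ft <- do.call(rbind, lapply(conditions, function(cond)
      fit_result_table(per_cond[[cond]]$fit, cond)))
    write_table_with_header(ft, file.path(out_dir, "fit_ratios.csv"), meta)
    write_table_with_header(summaries,
                            file.path(out_dir, "summaries.csv"), meta)
    log_lines <- c(
      sprintf("pathpoint %s", as.character(utils::packageVersion(
        "pathpoint"))),
      sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
      sprintf("seed: %d", seed),
      sprintf("conditions: %s", paste(conditions, collapse = ", ")),
      sprintf("run at: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  result
}

#' @export
print.pathpoint_analysis <- function(x, ...) {
  cat("<pathpoint_analysis> conditions:",
      paste(x$conditions, collapse = ", "), "\n")
  for (cond in x$conditions) {
    e <- x[[cond]]
    cat(sprintf(
      "  %s: AE_G mean %.2f deg (r = %.2f, kappa = %.2f), best fit %s\n",
      cond, e$descriptives$mean_direction, e$descriptives$r,
      e$descriptives$kappa,
      paste(e$fit$best_hypothesis, collapse = "/")))
  }
  invisible(x)
}
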