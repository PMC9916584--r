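# Shared fixtures: canonical example paths of each crossing class.

crossed_spec <- function(turn = "left") {
  path_spec(c(3, 2, 1.5, 3), turn, path_id = "cross_ex")
}

short_l4_spec <- function(turn = "left") {
  path_spec(c(3, 2, 1.5, 1), turn, path_id = "short_ex")
}

long_l3_spec <- function(turn = "left") {
  suppressWarnings(path_spec(c(3, 2, 4, 3), turn, path_id = "long_ex"))
}

fixture_specs <- function() {
  c(make_experiment_paths(1), make_experiment_paths(2))
}

# independent brute-force circular mean / resultant length (plain loop)
brute_circ <- function(deg) {
  s <- 0; c <- 0
  for (a in deg) {
    s <- s + sin(a * pi / 180)
    c <- c + cos(a * pi / 180)
  }
  r <- sqrt(s^2 + c^2) / length(deg)
  # atan2 already yields (-pi, pi], i.e. (-180, 180] in degrees
  list(mean = atan2(s, c) * 180 / pi, r = r)
}

# brute-force leave-one-out C-statistics
brute_c_statistic <- function(deg) {
  n <- length(deg)
  r_all <- brute_circ(deg)$r
  vapply(seq_len(n), function(i) {
    (brute_circ(deg[-i])$r - r_all) / r_all
  }, numeric(1))
}
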