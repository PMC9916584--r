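test_that("crossing topology and landmark coordinates follow the leg lengths", {
  g <- build_path(crossed_spec())
  expect_equal(g$crossing_class, "cross")
  expect_equal(g$I, c(0, 1.5), tolerance = 1e-12)
  expect_equal(g$E, c(1, 1.5), tolerance = 1e-12)

  g2 <- build_path(long_l3_spec())
  expect_equal(g2$crossing_class, "no_cross_long_L3")
  expect_equal(g2$F2, c(0, -1), tolerance = 1e-12)
  expect_equal(g2$E_prime_far, c(1, 3), tolerance = 1e-12)

  g3 <- build_path(short_l4_spec())
  expect_equal(g3$crossing_class, "no_cross_short_L4")
  expect_equal(g3$I_prime, c(0, 1.5), tolerance = 1e-12)
  expect_equal(g3$E_prime, c(1, 1.5), tolerance = 1e-12)
})

test_that("degenerate and unsupported topologies are rejected", {
  expect_error(build_path(path_spec(c(3, 2, 3, 2.5), "left")),
               "boundary topology")
  expect_error(build_path(path_spec(c(3, 2, 1.5, 2), "left")),
               "boundary topology")
  expect_error(build_path(suppressWarnings(
    path_spec(c(2, 3, 3.2, 2.5), "left"))), "unsupported topology")
  expect_error(path_spec(c(3, 2, 1.5), "left"), "four")
  expect_error(path_spec(c(3, 2, -1, 3), "left"), "positive")
  expect_warning(path_spec(c(3, 2, 4, 3), "left"), "arena bound")
})

test_that("printed boundary bearings hold exactly on crossed paths", {
  for (spec in Filter(function(s) build_path(s)$crossing_class == "cross",
                      fixture_specs())) {
    g <- build_path(spec)
    expect_equal(bearing("E", "I", g), 180, tolerance = 1e-9)
    expect_equal(bearing("I", "S", g), 90, tolerance = 1e-9)
    expect_equal(bearing("T3", "I", g), 0, tolerance = 1e-9)
    expect_equal(bearing("I", "T1", g), -90, tolerance = 1e-9)
  }
})

test_that("I, I', F2 lie on leg 1's line in the canonical frame", {
  for (spec in fixture_specs()) {
    g <- build_path(spec)
    for (lm in c("I", "I_prime", "F2")) {
      if (!is.null(g[[lm]])) expect_equal(g[[lm]][1], 0, tolerance = 1e-9)
    }
  }
})

test_that("correct pointing is backward-oriented on crossed paths", {
  g <- build_path(crossed_spec())
  # independent derivation: E = (1, 1.5), so E->S makes 180 - atan(1.5/1)
  # clockwise of the +x heading
  expect_equal(correct_pointing(g), 180 - atan2(1.5, 1) * 180 / pi,
               tolerance = 1e-9)
  expect_equal(correct_pointing(g), 123.69, tolerance = 1e-2)
  for (spec in fixture_specs()) {
    gg <- build_path(spec)
    if (gg$crossing_class == "cross") {
      expect_gt(abs(correct_pointing(gg)), 90)
    }
  }
  expect_error(bearing(g$E, g$E, g), "zero-length")
})

test_that("mirrored specs produce the reflected geometry and flipped bearings", {
  for (legs in list(c(3, 2, 1.5, 3), c(3, 2, 1.5, 1), c(3.4, 1.7, 1.7, 3.4))) {
    l <- build_path(path_spec(legs, "left"))
    r <- build_path(path_spec(legs, "right"))
    expect_equal(r$E, c(-l$E[1], l$E[2]), tolerance = 1e-12)
    expect_equal(r$crossing_class, l$crossing_class)
    expect_equal(correct_pointing(r), -correct_pointing(l),
                 tolerance = 1e-9)
    expect_equal(bearing(r$E, r$T1, r), -bearing(l$E, l$T1, l),
                 tolerance = 1e-9)
  }
})

test_that("bearings are invariant to translation and global rotation", {
  g <- build_path(crossed_spec())
  rot <- function(p, a) {
    c(p[1] * cos(a) - p[2] * sin(a), p[1] * sin(a) + p[2] * cos(a))
  }
  shift <- c(2.3, -4.1); a <- 0.7
  g2 <- g
  for (nm in c("S", "T1", "T2", "T3", "E", "I")) {
    g2[[nm]] <- rot(g[[nm]], a) + shift
  }
  g2$final_heading <- rot(g$final_heading, a)
  expect_equal(bearing(g2$E, g2$I, g2), bearing(g$E, g$I, g),
               tolerance = 1e-9)
  expect_equal(bearing(g2$E, g2$S, g2), bearing(g$E, g$S, g),
               tolerance = 1e-9)
})

test_that("crossing predicate matches a brute-force segment intersection test", {
  # orientation/CCW method on the canonical left-turn coordinates
  ccw <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  segments_cross <- function(p1, p2, p3, p4) {
    d1 <- ccw(p3, p4, p1); d2 <- ccw(p3, p4, p2)
    d3 <- ccw(p1, p2, p3); d4 <- ccw(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  set.seed(20240601)
  n_checked <- 0
  while (n_checked < 1000) {
    L <- round(runif(4, 0.5, 3.4), 3)
    # skip boundary-adjacent and the unsupported corner
    if (abs(L[3] - L[1]) < 0.05 || abs(L[4] - L[2]) < 0.05) next
    if (L[3] > L[1] && L[4] < L[2]) next
    g <- build_path(path_spec(L, "left"))
    S <- c(0, 0); T1 <- c(0, L[1]); T3 <- c(-L[2], L[1] - L[3])
    E <- c(-L[2] + L[4], L[1] - L[3])
    expect_identical(g$crossing_class == "cross",
                     segments_cross(S, T1, T3, E))
    n_checked <- n_checked + 1
  }
})

test_that("extended leg 4 doubles the remaining gap", {
  g <- build_path(short_l4_spec())
  expect_equal(extended_leg4_length(g), 3, tolerance = 1e-12)
  # identity 2*L2 - L4 across a family, incl. one reaching the printed
  # 4.25 m extension
  for (legs in list(c(3, 2.55, 1.5, 0.85), c(3.4, 2.4, 1.2, 1.4),
                    c(2.8, 1.8, 0.9, 1.2))) {
    gg <- build_path(path_spec(legs, "left"))
    expect_equal(extended_leg4_length(gg), 2 * legs[2] - legs[4],
                 tolerance = 1e-12)
  }
  expect_equal(extended_leg4_length(build_path(
    path_spec(c(3, 2.55, 1.5, 0.85), "left"))), 4.25, tolerance = 1e-12)
  expect_error(extended_leg4_length(build_path(crossed_spec())),
               "no_cross_short_L4")
})
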