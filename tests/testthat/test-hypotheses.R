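test_that("angular intervals are wrap-safe", {
  iv <- angular_interval(90, 180)
  expect_equal(interval_width(iv), 90)
  expect_equal(interval_midpoint(iv), 135)
  expect_true(interval_contains(iv, 90))    # closed boundaries
  expect_true(interval_contains(iv, 180))
  expect_false(interval_contains(iv, 89.9))

  wrap <- angular_interval(160, -160)       # crosses the +/-180 cut
  expect_equal(interval_width(wrap), 40)
  expect_equal(interval_midpoint(wrap), 180)
  expect_true(all(interval_contains(wrap, c(170, 180, -170))))
  expect_false(any(interval_contains(wrap, c(150, 0, -150))))

  expect_error(angular_interval(10, 10), "width")
  expect_equal(interval_intersect_length(angular_interval(0, 90),
                                         angular_interval(45, 180)), 45)
  expect_equal(interval_intersect_length(angular_interval(160, -160),
                                         angular_interval(170, 0)), 30)
  expect_equal(interval_intersect_length(angular_interval(0, 40),
                                         angular_interval(50, 90)), 0)
})

test_that("crossed-path predicted ranges reproduce the printed boundaries", {
  g <- build_path(crossed_spec())
  ctoc <- predict_range("CtoC", g)
  expect_equal(c(ctoc$from_bearing, ctoc$to_bearing), c(90, 180))
  cton3 <- predict_range("CtoN3", g)
  expect_equal(c(cton3$from_bearing, cton3$to_bearing), c(-90, 0))
  # derived boundaries: E = (1, 1.5), T1 = (0, 3), T3 = (-2, 1.5)
  cton1 <- predict_range("CtoN1", g)
  expect_equal(cton1$from_bearing, 180)
  expect_equal(cton1$to_bearing, -atan2(1.5, -1) * 180 / pi,
               tolerance = 1e-9) # bearing(E, T1): T1 - E = (-1, 1.5)
  expect_equal(cton1$to_bearing, -123.69, tolerance = 1e-2)
  cton2 <- predict_range("CtoN2", g)
  expect_equal(cton2$from_bearing, atan2(1.5, 2) * 180 / pi,
               tolerance = 1e-9) # bearing(T3, S): S - T3 = (2, -1.5)
  expect_equal(cton2$to_bearing, 90)
})

test_that("uncrossed-path predicted ranges reproduce the landmark boundaries", {
  g3 <- build_path(short_l4_spec())   # E = (-1, 1.5), I' = (0, 1.5)
  nton1 <- predict_range("NtoN1", g3)
  expect_equal(nton1$from_bearing, -atan2(1.5, 1) * 180 / pi,
               tolerance = 1e-9)     # bearing(E, T1): T1 - E = (1, 1.5)
  expect_equal(nton1$to_bearing, 0)
  nton2 <- predict_range("NtoN2", g3)
  expect_equal(nton2$to_bearing, 90) # bearing(I', S)
  ntoc1 <- predict_range("NtoC1", g3)
  expect_equal(ntoc1$from_bearing, 90)
  expect_equal(ntoc1$to_bearing, 180 - atan2(1.5, 1) * 180 / pi,
               tolerance = 1e-9)     # bearing(E', S), E' = (1, 1.5)

  g2 <- build_path(long_l3_spec())   # T3 = (-2, -1), F2 = (0, -1)
  ntoc3 <- predict_range("NtoC3", g2)
  expect_equal(ntoc3$from_bearing, -90)
  expect_equal(ntoc3$to_bearing, -atan2(1, 2) * 180 / pi, tolerance = 1e-9)
  expect_equal(ntoc3$to_bearing, -26.57, tolerance = 1e-2)
  ntoc2 <- predict_range("NtoC2", g2) # E'_far = (1, 3)
  expect_equal(ntoc2$to_bearing, 180)
  expect_equal(ntoc2$from_bearing, 180 - atan2(3, 1) * 180 / pi,
               tolerance = 1e-9)
})

test_that("inadmissible hypothesis-path pairings are rejected with the set", {
  g <- build_path(crossed_spec())
  expect_error(predict_range("NtoC3", g), "admissible")
  expect_error(predict_range("CtoC", build_path(short_l4_spec())),
               "admissible")
})

test_that("admissible sets follow condition and experiment", {
  expect_setequal(admissible_set("HI-C"), c("CtoC", "CtoN1", "CtoN2", "CtoN3"))
  expect_setequal(admissible_set("PG-C"), admissible_set("HI-C"))
  expect_setequal(admissible_set("TI-C", 2), admissible_set("HI-C"))
  expect_setequal(admissible_set("NI-NC", 1), c("NtoN1", "NtoN2", "NtoC1"))
  expect_setequal(admissible_set("NI-NC", 2), c("NtoN1", "NtoC2", "NtoC3"))
  expect_setequal(admissible_set("FI-NC", 2), c("NtoN1", "NtoC2", "NtoC3"))
  expect_error(admissible_set("FI-NC", 1), "Experiments 2-4")
  expect_error(admissible_set("unknown"), "unknown condition")
})

test_that("admissible predicted ranges have pairwise disjoint interiors", {
  for (spec in fixture_specs()) {
    for (turn in c("left", "right")) {
      sp <- spec; sp$turn_direction <- turn
      g <- build_path(sp)
      exp_n <- if (g$spec$experiment_tag == "exp2") 2 else 1
      cond <- switch(g$crossing_class,
                     cross = "HI-C",
                     no_cross_short_L4 = "NI-NC",
                     no_cross_long_L3 = "FI-NC")
      hyps <- admissible_set(cond, exp_n)
      ivs <- lapply(hyps, predict_range, geom = g)
      for (i in seq_along(ivs)) {
        expect_lt(interval_width(ivs[[i]]), 360)
        expect_gt(interval_width(ivs[[i]]), 0)
        for (j in seq_along(ivs)) {
          if (i < j) {
            expect_lt(interval_intersect_length(ivs[[i]], ivs[[j]]), 1e-6)
          }
        }
      }
    }
  }
})

test_that("hypotheses that keep the walked topology contain the correct direction", {
  for (spec in fixture_specs()) {
    g <- build_path(spec)
    cp <- correct_pointing(g)
    if (g$crossing_class == "cross") {
      expect_true(interval_contains(predict_range("CtoC", g), cp))
    } else if (g$crossing_class == "no_cross_short_L4") {
      expect_true(interval_contains(predict_range("NtoN2", g), cp))
    } else {
      # the represented-L1 sweep passes through the true start
      expect_true(interval_contains(predict_range("NtoN1", g), cp))
    }
  }
})

test_that("mirrored specs yield mirrored predicted ranges", {
  for (legs in list(c(3, 2, 1.5, 3), c(3, 2, 1.5, 1))) {
    gl <- build_path(path_spec(legs, "left"))
    gr <- build_path(path_spec(legs, "right"))
    hyps <- if (gl$crossing_class == "cross") {
      c("CtoC", "CtoN1", "CtoN2", "CtoN3")
    } else {
      c("NtoN1", "NtoN2", "NtoC1")
    }
    for (h in hyps) {
      il <- predict_range(h, gl)
      ir <- predict_range(h, gr)
      expect_equal(interval_width(ir), interval_width(il), tolerance = 1e-9)
      expect_equal(ir$from_bearing, wrap_signed(-il$to_bearing),
                   tolerance = 1e-9)
      expect_equal(ir$to_bearing, wrap_signed(-il$from_bearing),
                   tolerance = 1e-9)
    }
  }
})

test_that("range means are reproducible and converge to the arc midpoint", {
  iv <- angular_interval(90, 180)
  expect_equal(range_mean(iv, seed = 5), range_mean(iv, seed = 5))
  expect_equal(range_mean(iv, seed = 5), 135, tolerance = 2)
  expect_equal(range_mean(angular_interval(-90, 0), seed = 5), -45,
               tolerance = 2)
  expect_error(range_mean(iv, n_samples = 0), "at least 1")
  # convergence at n = 100,000 for a wrap-crossing interval (compare on the
  # circle: the midpoint is the +/-180 cut itself)
  expect_lt(abs(wrap_signed(range_mean(angular_interval(160, -160),
                                       n_samples = 1e5, seed = 6) - 180)),
            0.5)
})

test_that("prediction tables cover every admissible hypothesis per path", {
  tab <- prediction_table(make_experiment_paths(1), seed = 3)
  expect_true(all(c("path_id", "hypothesis_id", "from", "to", "mean") %in%
                    names(tab)))
  # 4 hypotheses per crossed path, 3 per uncrossed short-L4 path
  expect_equal(nrow(tab), 4 * 4 + 4 * 3)
  counts <- table(tab$path_id)
  expect_setequal(as.integer(counts), c(4, 3))
})
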