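cfg <- kinematics_config()

test_that("movement threshold reproduces the 90-degree chord geometry", {
  # independent check: rotate the head point (L/2, 0) by 90 degrees about
  # the body midpoint at the origin and measure the chord
  chord_by_rotation <- function(L) {
    head0 <- c(L / 2, 0)
    head1 <- c(L / 2 * cos(pi / 2), L / 2 * sin(pi / 2))
    sqrt(sum((head1 - head0)^2))
  }
  for (L in c(2.0, 3.25, 5.7)) {
    expect_equal(movement_threshold(L), chord_by_rotation(L),
                 tolerance = 1e-12)
  }
  expect_equal(movement_threshold(2.0), sqrt(2), tolerance = 1e-12)
  expect_identical(movement_threshold(0), 0)
  expect_error(movement_threshold(-1), "non-negative")
})

test_that("derived config threshold matches L * sin(45 deg) and guards bounds", {
  expect_equal(cfg$movement_threshold_mm, 3.25 * sin(pi / 4),
               tolerance = 1e-9)
  expect_error(kinematics_config(min_vector_mm = 3), "min_vector_mm")
  expect_error(kinematics_config(turn_threshold_deg = 190))
})

test_that("tracking vectors are per-sample displacements with direction flags", {
  tr <- trajectory("L1", 0:2, c(0, 1, 1), c(0, 0, 1))
  v <- tracking_vectors(tr, cfg)
  expect_equal(v$dx_mm, c(1, 0))
  expect_equal(v$dy_mm, c(0, 1))
  expect_true(all(v$direction_defined))

  still <- trajectory("L2", 0:5, rep(0, 6), rep(0, 6))
  expect_true(all(!tracking_vectors(still, cfg)$direction_defined))

  two <- trajectory("L3", 0:1, c(0, 1), c(0, 0))
  expect_equal(nrow(tracking_vectors(two, cfg)), 1)
  expect_error(count_turns(two, cfg), "at least 3 points")
})

test_that("turn scoring is strict at the 45-degree threshold", {
  collinear <- trajectory("L1", 0:3, c(0, 1, 2, 3), rep(0, 4))
  expect_equal(count_turns(collinear, cfg), 0)

  right <- trajectory("L2", 0:2, c(0, 1, 1), c(0, 0, 1))
  expect_equal(count_turns(right, cfg), 1)

  # second vector at exactly 45 degrees to the first: not a turn
  exact45 <- trajectory("L3", 0:2, c(0, 1, 2), c(0, 0, 1))
  expect_equal(count_turns(exact45, cfg), 0)

  just_over <- trajectory("L4", 0:2,
                          c(0, 1, 1 + cos(46 * pi / 180)),
                          c(0, 0, sin(46 * pi / 180)))
  expect_equal(count_turns(just_over, cfg), 1)
})

test_that("pairs flanking a direction-undefined vector are skipped", {
  # move right, stall (0.05 mm < min_vector), move up: the 90-degree angle
  # across the stall must not be evaluated
  tr <- trajectory("L1", 0:3, c(0, 1, 1.05, 1.05), c(0, 0, 0, 1))
  expect_equal(count_turns(tr, cfg), 0)
})

test_that("movement scoring is strict at the derived threshold", {
  thr <- cfg$movement_threshold_mm
  tr <- trajectory("L1", 0:3, c(0, 2.5, 2.5, 2.5 + thr), c(0, 0, 0, 0))
  # displacements: 2.5 (> thr), 0, exactly thr (not counted)
  expect_equal(count_movements(tr, cfg), 1)
  expect_equal(count_movements(trajectory("L2", 0:9, rep(0, 10), rep(0, 10)),
                               cfg), 0)
})

test_that("average velocity is path length over duration", {
  expect_equal(average_velocity(trajectory("L1", 0:1, c(0, 3), c(0, 4))), 5)
  expect_equal(average_velocity(
    trajectory("L2", c(0, 300), c(0, 0), c(0, 0))), 0)
  set.seed(11)
  tr <- random_trajectory(100)
  p <- tr$points
  manual <- sum(sqrt(diff(p$x_mm)^2 + diff(p$y_mm)^2)) / diff(range(p$t_s))
  expect_equal(average_velocity(tr), manual, tolerance = 1e-12)
})

test_that("resting time complements movements on uniform sampling", {
  still <- trajectory("L1", 0:300, rep(0, 301), rep(0, 301))
  expect_equal(resting_time(still, cfg), 300)
  runner <- trajectory("L2", 0:10, seq(0, 30, by = 3), rep(0, 11))
  expect_equal(resting_time(runner, cfg), 0)

  set.seed(12)
  for (i in 1:20) {
    tr <- random_trajectory(150)
    dur <- diff(range(tr$points$t_s))
    expect_equal(
      resting_time(tr, cfg) + count_movements(tr, cfg) * cfg$sample_interval_s,
      dur, tolerance = 1e-9)
  }
})

test_that("scorers match the brute-force oracle on random trajectories", {
  set.seed(13)
  for (i in 1:200) {
    tr <- random_trajectory(100)
    o <- oracle_score(tr, cfg)
    s <- summarize_trajectory(tr, cfg)
    expect_identical(s$n_turns, o$n_turns)
    expect_identical(s$n_movements, o$n_movements)
    expect_equal(s$avg_velocity_mm_s, o$avg_velocity_mm_s, tolerance = 1e-12)
    expect_equal(s$resting_time_s, o$resting_time_s, tolerance = 1e-12)
  }
})

test_that("all four metrics are invariant under rotation, translation, reflection", {
  set.seed(14)
  transform_traj <- function(tr, theta, shift, reflect = FALSE) {
    p <- tr$points
    x <- p$x_mm
    y <- if (reflect) -p$y_mm else p$y_mm
    trajectory(tr$larva_id, p$t_s,
               x = cos(theta) * x - sin(theta) * y + shift[1],
               y = sin(theta) * x + cos(theta) * y + shift[2])
  }
  for (i in 1:25) {
    tr <- random_trajectory(120)
    tr2 <- transform_traj(tr, runif(1, 0, 2 * pi), rnorm(2, sd = 50),
                          reflect = i %% 2 == 0)
    a <- summarize_trajectory(tr, cfg)
    b <- summarize_trajectory(tr2, cfg)
    expect_identical(a$n_turns, b$n_turns)
    expect_identical(a$n_movements, b$n_movements)
    expect_equal(a$avg_velocity_mm_s, b$avg_velocity_mm_s, tolerance = 1e-9)
    expect_equal(a$resting_time_s, b$resting_time_s, tolerance = 1e-9)
  }
})

test_that("scaling coordinates and body length together preserves counts", {
  set.seed(15)
  for (i in 1:25) {
    tr <- random_trajectory(120)
    s <- runif(1, 0.2, 5)
    tr2 <- trajectory(tr$larva_id, tr$points$t_s,
                      s * tr$points$x_mm, s * tr$points$y_mm)
    cfg2 <- kinematics_config(body_length_mm = s * cfg$body_length_mm,
                              min_vector_mm = s * cfg$min_vector_mm)
    expect_identical(count_turns(tr2, cfg2), count_turns(tr, cfg))
    expect_identical(count_movements(tr2, cfg2), count_movements(tr, cfg))
  }
})

test_that("raising a threshold never increases its count", {
  set.seed(16)
  for (i in 1:15) {
    tr <- random_trajectory(120)
    turn_thresholds <- c(20, 45, 90, 130)
    turns <- vapply(turn_thresholds, function(th) {
      count_turns(tr, kinematics_config(turn_threshold_deg = th))
    }, numeric(1))
    expect_true(all(diff(turns) <= 0))
    move_thresholds <- c(0.5, 1.5, 2.3, 4)
    moves <- vapply(move_thresholds, function(th) {
      count_movements(tr, kinematics_config(movement_threshold_mm = th))
    }, numeric(1))
    expect_true(all(diff(moves) <= 0))
  }
})

test_that("summarize_trajectory agrees with its component scorers", {
  tr <- trajectory("L1", 0:3, c(0, 3, 6, 6), c(0, 0, 0, 3))
  s <- summarize_trajectory(tr, cfg)
  expect_identical(s$n_turns, count_turns(tr, cfg))
  expect_identical(s$n_movements, count_movements(tr, cfg))
  expect_equal(s$avg_velocity_mm_s, average_velocity(tr))
  expect_equal(s$resting_time_s, resting_time(tr, cfg))
  expect_equal(s$n_turns, 1)       # one 90-degree turn
  expect_equal(s$n_movements, 3)   # all 3-mm steps exceed ~2.3 mm
  expect_equal(s$avg_velocity_mm_s, 3)
  expect_equal(s$resting_time_s, 0)
  expect_error(summarize_trajectory(
    trajectory("tiny", 0:1, c(0, 1), c(0, 0)), cfg), "tiny")
})

test_that("collinear constant-speed track scores as pure translation", {
  tr <- trajectory("L1", 0:10, seq(0, 30, by = 3), rep(0, 11))
  s <- summarize_trajectory(tr, cfg)
  expect_equal(s$n_turns, 0)
  expect_equal(s$n_movements, 10)
  expect_equal(s$avg_velocity_mm_s, 3)
  expect_equal(s$resting_time_s, 0)
})
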