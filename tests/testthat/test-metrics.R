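test_that("target error reads the endpoint at the first slow sample", {
  expect_equal(target_error(straight_trajectory()), 0, tolerance = 1e-9)

  # trajectory coming to rest at (44.3, 150) mm
  tr <- shift_x(straight_trajectory(), 0)
  tr$x_m <- 0.0443 * tr$y_m / 0.15
  expect_equal(target_error(tr), 44.3, tolerance = 0.2)

  # speed first drops below threshold at (-12, 140) mm, then drifts on
  tr2 <- straight_trajectory(reach_mm = 140)
  tr2$x_m <- -0.012 * tr2$y_m / 0.14
  n <- nrow(tr2)
  drift <- data.frame(t_s = tr2$t_s[n] + (1:10) * 0.01,
                      x_m = tr2$x_m[n] + cumsum(rep(1e-4, 10)),
                      y_m = tr2$y_m[n], vx_ms = 0.01, vy_ms = 0)
  expect_equal(target_error(rbind(tr2, drift)), -12, tolerance = 0.2)
})

test_that("a never-stopping trajectory is flagged and read at its last sample", {
  tr <- straight_trajectory()
  tr$vy_ms <- pmax(tr$vy_ms, 0.05)   # never below 20 mm/s after onset
  te <- target_error(tr)
  expect_true(isTRUE(attr(te, "flagged")))
})

test_that("lateral deviation interpolates the first mid-line crossing", {
  expect_equal(lateral_deviation(straight_trajectory()), 0, tolerance = 1e-9)
  expect_equal(lateral_deviation(parabolic_trajectory(c_mm = 20)), 5.0,
               tolerance = 0.02)
  short <- straight_trajectory(reach_mm = 60)
  expect_true(is.na(lateral_deviation(short)))
  expect_false(trial_metrics(short)$valid)
})

test_that("y-grid resampling matches the closed-form lateral profile", {
  tr <- parabolic_trajectory(c_mm = 20)
  xs <- resample_x_at_y(tr)
  expect_length(xs, 16L)
  expect_equal(unname(xs["y7.5"]), 20 * 7.5 * 142.5 / 150^2, tolerance = 0.02)
  expect_equal(unname(resample_x_at_y(tr, y_grid_mm = 75)), 5.0,
               tolerance = 0.02)
  expect_equal(unname(resample_x_at_y(straight_trajectory(),
                                      y_grid_mm = 150)), 0, tolerance = 1e-6)
  expect_true(all(abs(resample_x_at_y(straight_trajectory())) < 1e-6))
})

test_that("resampling at the mid-line equals the lateral deviation", {
  for (c_mm in c(-15, 5, 30)) {
    tr <- parabolic_trajectory(c_mm)
    expect_equal(unname(resample_x_at_y(tr, 75)), lateral_deviation(tr),
                 tolerance = 1e-9)
  }
})

test_that("TE and LD are translation-equivariant in x", {
  tr <- parabolic_trajectory(c_mm = 12)
  for (delta in c(-20, 7)) {
    sh <- shift_x(tr, delta)
    expect_equal(target_error(sh), as.numeric(target_error(tr)) + delta,
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(lateral_deviation(sh), lateral_deviation(tr) + delta,
                 tolerance = 1e-9)
  }
})

test_that("epoch means follow their windows", {
  expect_equal(unname(epoch_summary(rep(5, 200), list(a = 1L, b = 3:5))),
               c(5, 5))
  expect_equal(unname(epoch_summary(seq_len(200), list(mid = 3:5))), 4)
  expect_equal(unname(epoch_summary(c(9, 1, 1), list(first = 1L))), 9)
  expect_error(epoch_summary(1:10, list(bad = 9:12)))
})

test_that("baseline subtraction shifts by the last-20 baseline mean", {
  expect_equal(baseline_subtract(rep(3, 10), 3), rep(0, 10))
  expect_equal(baseline_subtract(1:5, 2), -1:3)
  ramp <- seq(0.1, 5, length.out = 50)
  bl <- mean(utils::tail(ramp, 20))
  expect_equal(mean(utils::tail(baseline_subtract(ramp, bl), 20)), 0)
})

test_that("participant screening is strict at the 4.5 mm bound", {
  expect_true(screen_participant(rep(4.4, 30)))
  expect_false(screen_participant(rep(4.5, 30)))
  expect_true(screen_participant(rep(0, 30)))
  expect_true(screen_participant(rep(-4.4, 30)))   # magnitude rule
  expect_false(screen_participant(rep(-5, 30)))
})

test_that("unstable-participant rule needs three jumps AND an outlying mean", {
  group <- c(rep(0.5, 14))
  smooth <- 30 * 0.9^(seq_len(120))
  expect_false(flag_unstable_participant(smooth, c(group, mean(tail(smooth, 20)))))

  jumpy <- rep(0.5, 120)
  jumpy[c(30, 50, 70)] <- 30
  jumpy[c(31, 51, 71)] <- -30
  jumpy[101:120] <- 25            # outlying last-20 mean
  expect_true(flag_unstable_participant(jumpy, c(group, mean(tail(jumpy, 20)))))

  # a single up-down excursion yields exactly two sign-crossing jumps
  two <- rep(0.5, 120)
  two[30] <- 30
  two[31] <- -30
  two[101:120] <- 25
  expect_false(flag_unstable_participant(two, c(group, mean(tail(two, 20)))))

  # three jumps but unremarkable mean
  jumps_only <- rep(0.5, 120)
  jumps_only[c(30, 50, 70)] <- 30
  jumps_only[c(31, 51, 71)] <- -30
  expect_false(flag_unstable_participant(
    jumps_only, c(group, mean(tail(jumps_only, 20)))))
})

test_that("exclusion removes exactly the short reaches", {
  rec <- data.frame(id = 1:5, reach_mm = c(150, 60, 74.9, 75, 149))
  kept <- exclude_short_reaches(rec)
  expect_equal(kept$id, c(1L, 4L, 5L))
})
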