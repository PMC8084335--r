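test_that("noiseless generation follows the deterministic recursion", {
  cfg <- gen_config(n_participants = 1, te1_sd = 0, noise_sd = 0,
                    n_baseline = 0, n_adapt = 60, n_deadapt = 0)
  s <- gen_te_series(cfg, seed = 1)
  # replay the recursion by hand
  D <- -112.6; dx <- 0; te <- numeric(60); active <- FALSE
  for (i in 1:60) {
    te[i] <- D + dx
    failed <- abs(te[i]) > 7.5
    if (failed) active <- TRUE
    if (active) dx <- if (failed) 0.95 * dx - 0.45 * te[i] else 0.95 * dx
  }
  expect_equal(s$TE_mm, te, tolerance = 1e-10)
  # geometric relaxation toward the recursion's fixed point
  fp <- (1 - 0.95) * D / (1 - 0.95 + 0.45)
  expect_equal(tail(s$TE_mm, 1), fp, tolerance = 0.5)

  # no sensitivity, no learning: TE stays at the drive
  cfg0 <- gen_config(n_participants = 1, te1_sd = 0, noise_sd = 0, r = 0,
                     n_baseline = 0, n_adapt = 20, n_deadapt = 0)
  s0 <- gen_te_series(cfg0, seed = 1)
  expect_true(all(s0$TE_mm == s0$TE_mm[1]))
})

test_that("seeded generation is bit-identical across runs", {
  cfg <- gen_config(n_participants = 3, n_baseline = 5, n_adapt = 20,
                    n_deadapt = 10)
  a <- gen_te_series(cfg, seed = 99)
  b <- gen_te_series(cfg, seed = 99)
  expect_identical(a, b)
  d1 <- gen_trajectory_dataset(cfg, seed = 99)
  d2 <- gen_trajectory_dataset(cfg, seed = 99)
  expect_identical(d1$trajectories, d2$trajectories)
})

test_that("first-trial TE distribution matches the configured moments", {
  cfg <- gen_config(n_participants = 4000, n_baseline = 0, n_adapt = 1,
                    n_deadapt = 0)
  s <- gen_te_series(cfg, seed = 5)
  te1 <- -s$TE_mm[s$trial == 1]
  se <- sqrt(cfg$te1_sd^2 + cfg$noise_sd^2) / sqrt(length(te1))
  expect_lt(abs(mean(te1) - cfg$te1_mean), 2 * se)
})

test_that("the dataset exercises exclusion and screening rules on demand", {
  # a single outlier can only exceed 3 group s.d. when the group is large
  # enough ((n-1)/sqrt(n) > 3), as in the reported n = 14 group
  cfg <- gen_config(n_participants = 14, te1_sd = 10, n_baseline = 5,
                    n_adapt = 10, n_deadapt = 110, noise_sd = 1)
  ds <- gen_trajectory_dataset(cfg, seed = 17, short_trials = c(12, 30),
                               unstable_participant = 2)
  an <- analyze_trajectories(ds$trajectories)
  expect_equal(sum(!an$trials$valid), 2L)
  expect_equal(nrow(exclude_short_reaches(an$trials)),
               nrow(an$trials) - 2L)

  de <- an$trials[an$trials$phase == "de_adaptation", ]
  means <- tapply(de$LD_mm[de$trial > 90], de$participant[de$trial > 90],
                  mean)
  flags <- vapply(1:14, function(p)
    flag_unstable_participant(de$LD_mm[de$participant == p], means),
    logical(1))
  expect_identical(which(flags), 2L)
})

test_that("measured trial metrics reproduce the generated series", {
  cfg <- gen_config(n_participants = 2, n_baseline = 2, n_adapt = 10,
                    n_deadapt = 5)
  ds <- gen_trajectory_dataset(cfg, seed = 3)
  an <- analyze_trajectories(ds$trajectories)
  merged <- merge(an$trials, ds$series,
                  by = c("participant", "phase", "trial"))
  expect_gt(nrow(merged), 30)
  expect_lt(max(abs(merged$TE_mm.x - merged$TE_mm.y)), 1.5)
  expect_lt(max(abs(merged$LD_mm.x - merged$LD_mm.y)), 1.5)
})

test_that("update-rule recovery is exact without noise and flags degeneracy", {
  te <- rep(-10, 151); dx <- numeric(151)
  for (i in 1:150) dx[i + 1] <- 0.95 * dx[i] - 0.45 * te[i]
  fit <- fit_update_rule(te[1:150], dx[1:150])
  expect_equal(coef(fit), c(b = 0.95, r = 0.45), tolerance = 1e-10)

  flat <- fit_update_rule(rep(0, 50), rep(0, 50))
  expect_false(flat$identifiable)
  expect_true(is.na(coef(flat)["b"]))
})

test_that("recovery stays accurate under trial noise", {
  set.seed(55)
  errs_b <- errs_r <- numeric(100)
  for (k in 1:100) {
    te <- numeric(151); dx <- numeric(151)
    te[1] <- -112.6
    for (i in 1:150) {
      dx[i + 1] <- 0.95 * dx[i] - 0.45 * te[i] + rnorm(1, 0, 1)
      te[i + 1] <- -112.6 + dx[i + 1] + rnorm(1, 0, 1)
    }
    f <- fit_update_rule(te[1:150], dx[1:150])
    errs_b[k] <- abs(f$b - 0.95); errs_r[k] <- abs(f$r - 0.45)
  }
  expect_lt(mean(errs_b), 0.02)
  expect_lt(mean(errs_r), 0.02)
})
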