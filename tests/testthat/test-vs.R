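test_that("muscle-space error and its filtered form follow the definitions", {
  nt <- 100; dt <- 0.001
  lam0 <- matrix(0, nt, 6)
  expect_true(all(muscle_error(lam0, lam0, g_d = 0.1, dt = dt)$eps == 0))

  delta <- matrix(rep(c(1, -2, 3, 0.5, -1, 2) * 1e-3, each = nt), nt, 6)
  me <- muscle_error(lam0 + delta, lam0, g_d = 0.2, dt = dt)
  expect_equal(me$E, delta)
  expect_equal(me$eps, delta)                      # constant offset: Edot = 0

  ramp <- matrix(seq(0, by = dt, length.out = nt), nt, 6)
  mr <- muscle_error(ramp, 0 * ramp, g_d = 0.1, dt = dt)
  expect_equal(mr$eps[2:(nt - 1), 1], ramp[2:(nt - 1), 1] + 0.1,
               tolerance = 1e-9)

  expect_error(muscle_error(lam0, lam0[1:10, ], g_d = 0.1, dt = dt),
               "mismatch")
})

test_that("the V-shaped update has the printed gains and rectification", {
  cfg <- vs_config(alpha_l = 0.5, beta_l = 0.25, gamma_l = 0.1)
  nt <- 300
  u <- matrix(1, nt, 6)
  ones <- matrix(1, nt, 6)
  up <- vshape_update(u, ones, cfg)                # eps = +1 everywhere
  mid <- 150:160                                   # away from edge effects
  expect_equal(up[mid, ], u[mid, ] + 0.4, tolerance = 1e-9)   # 0.5 - 0.1

  dn <- vshape_update(u, -ones, cfg)               # eps = -1 everywhere
  expect_equal(dn[mid, ], u[mid, ] + 0.15, tolerance = 1e-9)  # 0.25 - 0.1

  z <- vshape_update(matrix(0, nt, 6), matrix(0, nt, 6), cfg)
  expect_true(all(z == 0))                         # deactivation rectified

  # commands never go negative whatever the errors
  set.seed(41)
  ru <- matrix(runif(nt * 6, 0, 0.2), nt, 6)
  reps <- matrix(rnorm(nt * 6, 0, 2), nt, 6)
  expect_true(all(vshape_update(ru, reps, cfg) >= 0))
})

test_that("deflection updates share the bias law's structure and gate", {
  d <- deflection_state()
  d1 <- update_deflection(d, te_m = 0.10, failed = TRUE, motor_cost = 400)
  expect_equal(d1$dx, -0.045)                      # -0.45 * 0.10
  expect_true(d1$active)

  d1$dx <- 0.05
  d2 <- update_deflection(d1, te_m = 0, failed = FALSE, motor_cost = 400)
  expect_equal(d2$dx, 0.0475)                      # 0.95 * 0.05

  d2$dx <- 0.05
  d3 <- update_deflection(d2, te_m = 0, failed = FALSE, motor_cost = 300)
  expect_equal(d3$dx, 0.05)                        # frozen below the gate
  expect_true(d3$frozen)
})

test_that("constant-error deflection converges to the closed-form fixed point", {
  st <- deflection_state(b = 0.95, r = 0.45, dx_max = 10)
  te <- -0.01
  for (i in 1:600)
    st <- update_deflection(st, te, failed = TRUE, motor_cost = 400)
  expect_equal(st$dx, -st$r / (1 - st$b) * te, tolerance = 1e-6)
})

test_that("desired trajectories pass through the via and aim with it", {
  cfg <- vs_config()
  d0 <- vs_desired(cfg, 0)
  expect_lt(max(abs(d0$hand[, 1])), 1e-9)          # straight plan
  expect_equal(d0$hand[nrow(d0$hand), 2], 0.150, tolerance = 1e-9)

  d <- vs_desired(cfg, 0.02)
  iv <- which.min(abs(d$hand[, 2] - cfg$via_y))
  expect_equal(d$hand[iv, 1], 0.02, tolerance = 1e-3)
  expect_equal(d$hand[nrow(d$hand), 1], 0.02, tolerance = 1e-9)
  # joint-space image is kinematically consistent
  p <- hmadapt:::vs_fk(cfg, d$q[iv, ]) - cfg$start
  expect_equal(p, unname(d$hand[iv, ]), tolerance = 1e-9)
})

test_that("the arm tracks a converged command and V-shape learning is stable", {
  cfg <- vs_config()
  des <- vs_desired(cfg, 0)
  u <- vs_feedforward_init(cfg, des)
  tr <- vs_simulate_reach(u, des, cfg)
  ep <- attr(tr, "endpoint")
  expect_lt(sqrt(sum((ep - (cfg$target - cfg$start))^2)), cfg$target_radius)
  expect_true(all(attr(tr, "tension") >= 0))

  # start from a strongly degraded command; updates shrink the error
  u2 <- 0.2 * u
  errs <- numeric(8)
  for (i in 1:8) {
    t2 <- vs_simulate_reach(u2, des, cfg)
    errs[i] <- max(abs(attr(t2, "E")))
    u2 <- vshape_update(u2, attr(t2, "eps"), cfg)
    expect_true(all(u2 >= 0))
  }
  expect_lt(errs[8], errs[1])
  expect_lt(errs[8], 2e-3)                         # converged tolerance
})

test_that("naive reaches fail under the end-loaded field, clamp rescues them", {
  cfg <- vs_config()
  des <- vs_desired(cfg, 0)
  u <- vs_feedforward_init(cfg, des)
  tl <- vs_simulate_reach(u, des, cfg,
                          field = field_spec("LIPF", k1 = cfg$lipf_k1))
  expect_lt(target_error(tl), -7.5)

  tv <- vs_simulate_reach(u, des, cfg,
                          field = field_spec("VDCF", b1 = cfg$vdcf_b1))
  expect_lt(abs(target_error(tv)), 7.5)
  expect_gt(abs(lateral_deviation(tv)), 7.5)

  pec <- channel_spec(cfg$pec_stiffness, cfg$pec_damping)
  tc <- vs_simulate_reach(u, des, cfg,
                          field = field_spec("LIPF", k1 = cfg$lipf_k1),
                          clamp = pec)
  expect_lt(abs(target_error(tc)), abs(target_error(tl)) / 3)
})
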