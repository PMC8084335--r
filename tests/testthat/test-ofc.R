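test_that("internal-model schedule has the printed endpoints and shape", {
  expect_equal(alpha_schedule(1), 0)
  expect_equal(alpha_schedule(155), 0.8)
  expect_equal(alpha_schedule(156), 0.8)   # full after-effect at switch
  expect_equal(alpha_schedule(185), 0)
  expect_equal(alpha_schedule(200), 0)
  expect_equal(alpha_schedule(305), 0)
  a <- alpha_schedule(1:155)
  expect_true(all(diff(a) > 0))            # monotone rise
  d <- alpha_schedule(156:185)
  expect_true(all(diff(d) < 0))            # monotone fall
})

test_that("directional-bias matrix is the perpendicular projector", {
  expect_equal(bias_cost_matrix(0), matrix(c(1, 0, 0, 0), 2, 2))
  expect_equal(bias_cost_matrix(90), matrix(c(0, 0, 0, 1), 2, 2),
               tolerance = 1e-12)
  for (phi in c(-70, -13, 22, 45, 160)) {
    Qd <- bias_cost_matrix(phi)
    a <- phi * pi / 180
    d <- c(sin(a), cos(a))
    expect_lt(max(abs(Qd %*% d)), 1e-12)          # aimed direction is free
    expect_equal(Qd, t(Qd))
    expect_gte(min(eigen(Qd, only.values = TRUE)$values), -1e-12)
  }
  # Eq-6 arithmetic: phi = 0, p = (0.01, 0.1), k_p = 0.5 at t = 0
  p <- c(0.01, 0.1)
  expect_equal(0.5 * drop(p %*% bias_cost_matrix(0) %*% p), 5e-5)
  # motion along the plan is free
  v <- c(0, 0.5)
  expect_equal(drop(v %*% bias_cost_matrix(0) %*% v), 0)
})

test_that("linear fields and their state matrices agree", {
  set.seed(31)
  for (kind in c("NULL", "VDCF", "LIPF", "CPVF")) {
    f <- field_spec(kind, b1 = 7, k1 = 120)
    M <- hmadapt:::field_state_matrix(f)
    for (i in 1:10) {
      st <- random_hand_state()
      x <- c(st$pos, st$vel, 0, 0, 1)
      expect_equal(as.numeric(M %*% x), field_force(f, st$pos, st$vel),
                   info = kind)
    }
  }
})

test_that("the nominal null-field reach is straight, timely and on target", {
  cfg <- ofc_config()
  pol <- ofc_policy(cfg)
  tr <- ofc_simulate_reach(pol)
  expect_lt(max(abs(tr$x_m)), 1e-3)                 # straight
  ep <- attr(tr, "endpoint")
  expect_lt(sqrt(sum((ep - cfg$target)^2)), cfg$target_radius)
  expect_true(attr(tr, "lock_engaged"))
  # movement is essentially complete near the 400 ms horizon
  i400 <- which.min(abs(tr$t_s - 0.4))
  expect_gt(tr$y_m[i400], 0.135)
  expect_lt(attr(tr, "motor_cost"), cfg$cost_threshold)
})

test_that("full knowledge of the curl field restores the null trajectory", {
  cfg <- ofc_config()
  nullpol <- ofc_policy(cfg)
  base <- ofc_simulate_reach(nullpol)
  f <- field_spec("VDCF", b1 = cfg$vdcf_b1)
  comp <- ofc_simulate_reach(ofc_policy(cfg, f, alpha = 1), true_field = f)
  n <- min(nrow(base), nrow(comp))
  dev <- pmax(abs(base$x_m[1:n] - comp$x_m[1:n]),
              abs(base$y_m[1:n] - comp$y_m[1:n]))
  expect_lt(max(dev), 0.002)
})

test_that("naive reaches fail in the end-loaded field but not the curl", {
  cfg <- ofc_config()
  pol <- ofc_policy(cfg)
  lipf <- field_spec("LIPF", k1 = cfg$lipf_k1)
  tl <- ofc_simulate_reach(pol, true_field = lipf)
  expect_lt(target_error(tl), -7.5)                 # failure toward -x
  # the perturbing force is largest near the end of the movement
  n_mv <- round(cfg$T / cfg$dt)
  f_along <- abs(vapply(seq_len(n_mv), function(i)
    field_force(lipf, c(tl$x_m[i], tl$y_m[i]))[1L], numeric(1)))
  expect_gt(which.max(f_along), 0.8 * n_mv)

  tv <- ofc_simulate_reach(pol, true_field = field_spec("VDCF",
                                                        b1 = cfg$vdcf_b1))
  expect_lt(abs(target_error(tv)), 7.5)
  expect_gt(abs(lateral_deviation(tv)), 7.5)        # perturbed mid-reach
})

test_that("perturbing the planned gains never beats the planned policy", {
  cfg <- ofc_config()
  pol <- ofc_policy(cfg)                            # model == plant (null)
  j0 <- attr(ofc_simulate_reach(pol), "motor_cost")
  for (s in c(0.95, 1.05)) {
    pert <- pol
    pert$L <- lapply(pol$L, function(L) s * L)
    pert$L_hold <- s * pol$L_hold
    js <- attr(ofc_simulate_reach(pert), "motor_cost")
    expect_gte(js, j0 - 1e-12)
  }
})

test_that("aim-bias updates follow the retention/sensitivity law and gate", {
  b <- bias_state()
  b1 <- update_bias(b, theta_deg = 20, failed = TRUE, motor_cost = 1)
  expect_equal(b1$phi, -17)                         # 0.95*0 - 0.85*20
  expect_true(b1$active)

  b1$phi <- -17
  b2 <- update_bias(b1, theta_deg = 0, failed = FALSE, motor_cost = 0.5)
  expect_equal(b2$phi, -16.15)                      # 0.95 * (-17)
  expect_false(b2$frozen)

  b2$phi <- -17
  b3 <- update_bias(b2, theta_deg = 0, failed = FALSE, motor_cost = 0.005)
  expect_equal(b3$phi, -17)                         # frozen: b treated as 1
  expect_true(b3$frozen)
  # freeze is permanent even if cost rises again
  b4 <- update_bias(b3, theta_deg = 0, failed = FALSE, motor_cost = 5)
  expect_equal(b4$phi, -17)

  # never-activated bias stays at zero
  b0 <- update_bias(bias_state(), theta_deg = 0, failed = FALSE,
                    motor_cost = 0.001)
  expect_equal(b0$phi, 0)
  expect_false(b0$active)
})

test_that("the PEC suppresses endpoint error of an adapted-but-wrong policy", {
  cfg <- ofc_config()
  lipf <- field_spec("LIPF", k1 = cfg$lipf_k1)
  pol <- ofc_policy(cfg, lipf, alpha = 0.8)         # after-effect state
  clamped <- ofc_simulate_reach(pol, true_field = field_spec("NULL"),
                                clamp = channel_spec(cfg$pec_stiffness,
                                                     cfg$pec_damping))
  free <- ofc_simulate_reach(pol, true_field = field_spec("NULL"))
  expect_lt(abs(target_error(clamped)), 7.5)     # clamped trial succeeds
  expect_gt(abs(target_error(free)), 7.5)        # unclamped trial fails
  expect_lt(abs(target_error(clamped)), abs(target_error(free)) / 3)
})
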