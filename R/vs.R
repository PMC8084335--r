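#' @title V-shaped (feedback-error) learning model
#'
#' @description A two-joint, six-muscle planar arm tracks a desired
#' trajectory; the feedforward command of each muscle is corrected across
#' trials by a V-shaped function of the muscle-space error (stretch and
#' shortening both increase activation, minus a constant deactivation), a
#' form of feedback-error learning. The flat variant keeps the desired
#' trajectory fixed at the straight start-to-target line; the hierarchical
#' variant deflects the via-point of a minimum-jerk desired trajectory
#' laterally by `dx` (at 120 mm from the start), updated trial-by-trial by
#' the target error and gated by motor cost (average muscle tension).
#' Noise-free throughout.
#' @name vs-model
NULL

#' Configuration of the V-shaped learning model
#'
#' The arm (shoulder at the origin) reaches from (0, 350) to (0, 500) mm.
#' Link parameters are standard human-arm values; the six muscles
#' (shoulder flexor/extensor, elbow flexor/extensor, biarticular pair) have
#' constant moment arms, muscle lengths linear in joint angles, intrinsic
#' (instantaneous) viscoelasticity and a delayed stretch reflex. Learning
#' gains satisfy `alpha_l > beta_l > 0`, `gamma_l > 0`. The co-activation
#' baseline `t_coact` sets the tension scale so the converged null reach has
#' an average muscle tension just below the 350 gate used by the
#' via-point-deflection decay.
#'
#' @param dt Output sample step, s.
#' @param dt_inner Integration step, s.
#' @param T Movement duration, s.
#' @param T_sim Total simulated time per trial, s (movement + settle).
#' @param l1,l2 Upper-arm and forearm lengths, m.
#' @param m1,m2 Segment masses, kg.
#' @param lc1,lc2 Segment center-of-mass distances, m.
#' @param i1,i2 Segment moments of inertia about their COM, kg m^2.
#' @param b_joint Joint viscous damping, N m s/rad.
#' @param moment_arms 6 x 2 moment-arm matrix, m (rows = muscles,
#'   columns = shoulder, elbow; flexors positive).
#' @param k_int,b_int Intrinsic (undelayed) muscle stiffness N/m and
#'   viscosity N s/m at baseline drive; the effective viscoelastic and
#'   reflex gains of each muscle scale with its drive
#'   `(u + t_coact)/t_coact`, so co-contraction raises impedance.
#' @param g_ref_p,g_ref_v Delayed stretch-reflex gains, N/m and N s/m.
#' @param co_reflex Co-contracting reflex gain, N/m: raises tension in every
#'   muscle in proportion to the mean absolute (delayed) muscle error, the
#'   within-trial analog of the V-shaped law; it makes average tension a
#'   faithful effort signal when fighting a perturbation.
#' @param delay Reflex feedback delay, s (also the learning phase advance).
#' @param alpha_l,beta_l,gamma_l V-shaped learning gains: stretch-error
#'   gain, shortening-error gain (N per m of error) and constant
#'   deactivation (N); `alpha_l > beta_l > 0`, `gamma_l > 0`.
#' @param g_d Velocity-error weight in the filtered error
#'   `eps = E + g_d dE/dt`, s.
#' @param t_coact Baseline co-activation tension per muscle, N.
#' @param start,target Hand start and target in shoulder coordinates, m.
#' @param target_radius Target radius, m.
#' @param via_y Forward distance of the desired-trajectory via-point from
#'   the start, m.
#' @param defl_b,defl_r Retention and sensitivity of the via-point
#'   deflection update.
#' @param dx_max Saturation bound on the planned deflection, m (keeps the
#'   plan within reach).
#' @param cost_threshold Motor-cost gate (average muscle tension) under
#'   which deflection decay stops.
#' @param vdcf_b1,lipf_k1,cpvf_b1,cpvf_k1,pspf_k2 Simulation field gains.
#' @param pec_stiffness,pec_damping Simulation error-clamp channel.
#' @return List of class `"vs_config"`.
#' @export
vs_config <- function(dt = 0.010, dt_inner = 0.001, T = 0.400, T_sim = 0.70,
                      l1 = 0.30, l2 = 0.33, m1 = 1.4, m2 = 1.1,
                      lc1 = 0.11, lc2 = 0.16, i1 = 0.025, i2 = 0.045,
                      b_joint = 0.30,
                      moment_arms = matrix(c(
                         0.040,  0.000,
                        -0.040,  0.000,
                         0.000,  0.025,
                         0.000, -0.025,
                         0.030,  0.030,
                        -0.030, -0.030), nrow = 6L, byrow = TRUE),
                      k_int = 7000, b_int = 650,
                      g_ref_p = 400, g_ref_v = 40, co_reflex = 55000,
                      delay = 0.060,
                      alpha_l = 7000, beta_l = 100, gamma_l = 3.5,
                      g_d = 0.08, t_coact = 327,
                      start = c(0, 0.350), target = c(0, 0.500),
                      target_radius = 0.0075, via_y = 0.120,
                      defl_b = 0.95, defl_r = 0.45, dx_max = 0.024,
                      cost_threshold = 350,
                      vdcf_b1 = 20, lipf_k1 = 120,
                      cpvf_b1 = 20, cpvf_k1 = 120, pspf_k2 = 20868,
                      pec_stiffness = 2500, pec_damping = 1000) {
  stopifnot(alpha_l > beta_l, beta_l > 0, gamma_l > 0, g_d > 0,
            nrow(moment_arms) == 6L, ncol(moment_arms) == 2L,
            qr(moment_arms)$rank == 2L)
  structure(as.list(environment()), class = "vs_config")
}

# ---- arm kinematics and dynamics ------------------------------------------

vs_fk <- function(cfg, q) {
  c(cfg$l1 * cos(q[1L]) + cfg$l2 * cos(q[1L] + q[2L]),
    cfg$l1 * sin(q[1L]) + cfg$l2 * sin(q[1L] + q[2L]))
}

vs_jacobian <- function(cfg, q) {
  s1 <- sin(q[1L]); c1 <- cos(q[1L])
  s12 <- sin(q[1L] + q[2L]); c12 <- cos(q[1L] + q[2L])
  matrix(c(-cfg$l1 * s1 - cfg$l2 * s12, -cfg$l2 * s12,
            cfg$l1 * c1 + cfg$l2 * c12,  cfg$l2 * c12),
         2L, 2L, byrow = TRUE)
}

# elbow-flexed (q2 > 0) inverse kinematics branch, fixed throughout
vs_ik <- function(cfg, p) {
  d2 <- sum(p^2)
  c2 <- (d2 - cfg$l1^2 - cfg$l2^2) / (2 * cfg$l1 * cfg$l2)
  if (c2 > 1 || c2 < -1) stop("hand position out of reach")
  q2 <- acos(c2)
  q1 <- atan2(p[2L], p[1L]) -
    atan2(cfg$l2 * sin(q2), cfg$l1 + cfg$l2 * cos(q2))
  c(q1, q2)
}

vs_inertia <- function(cfg, q2) {
  c2 <- cos(q2)
  m11 <- cfg$i1 + cfg$i2 + cfg$m1 * cfg$lc1^2 +
    cfg$m2 * (cfg$l1^2 + cfg$lc2^2 + 2 * cfg$l1 * cfg$lc2 * c2)
  m12 <- cfg$i2 + cfg$m2 * (cfg$lc2^2 + cfg$l1 * cfg$lc2 * c2)
  m22 <- cfg$i2 + cfg$m2 * cfg$lc2^2
  matrix(c(m11, m12, m12, m22), 2L, 2L)
}

vs_coriolis_torque <- function(cfg, q2, qd) {
  h <- cfg$m2 * cfg$l1 * cfg$lc2 * sin(q2)
  c(-h * qd[2L] * (2 * qd[1L] + qd[2L]), h * qd[1L]^2)
}

# ---- desired trajectories and muscle space --------------------------------

#' Desired trajectory with a deflected via-point
#'
#' Minimum-jerk desired hand path through the via-point `(dx, via_y)` (task
#' frame, relative to the start), extended by a stationary hold, together
#' with its joint-space image and desired muscle lengths
#' `lambda0 = -A q_des` (lengths are linear in joint angles with constant
#' moment arms; the rest-length offset cancels from all errors). The
#' deflection is a change of the planned movement direction: the plan's
#' endpoint is shifted laterally by the same `dx`, so a deflected plan
#' aims, not merely bulges.
#'
#' @param cfg A [vs_config()].
#' @param dx Lateral via-point deflection, m (0 gives the straight plan).
#' @return List with `t` (s), `hand` (task-frame positions, nt x 2),
#'   `q`, `qd` (joint angles/velocities), `lambda0`, `lambda0_d`
#'   (desired muscle lengths and their rates, nt x 6).
#' @export
vs_desired <- function(cfg, dx = 0) {
  tt <- seq(0, cfg$T_sim, by = cfg$dt_inner)
  nt <- length(tt)
  goal <- cfg$target - cfg$start
  if (abs(dx) < 1e-12) {
    mj <- minjerk_straight(c(0, 0), goal, cfg$T, cfg$dt_inner)
  } else {
    goal <- goal + c(dx, 0)
    mj <- minjerk_viapoint(c(0, 0), c(dx, cfg$via_y), goal, cfg$T,
                           cfg$dt_inner)
  }
  hand <- matrix(rep(goal, each = nt), nt, 2L)
  n_mv <- nrow(mj)
  hand[seq_len(n_mv), ] <- cbind(mj$x_m, mj$y_m)
  q <- t(apply(hand, 1L, function(p) vs_ik(cfg, p + cfg$start)))
  qd <- rbind(diff(q) / cfg$dt_inner, c(0, 0))
  lambda0 <- -q %*% t(cfg$moment_arms)
  lambda0_d <- -qd %*% t(cfg$moment_arms)
  list(t = tt, hand = hand, q = q, qd = qd,
       lambda0 = lambda0, lambda0_d = lambda0_d, dx = dx)
}

#' Muscle-space movement error
#'
#' The per-muscle error `E = lambda - lambda0` (actual minus desired muscle
#' length; stretch positive) and the filtered error
#' `eps = E + g_d dE/dt` used by the V-shaped update.
#'
#' @param lambda_actual,lambda_desired Muscle-length series (nt x 6
#'   matrices, m), aligned in time.
#' @param g_d Velocity-error weight, s.
#' @param dt Sample step of the series, s.
#' @return List with matrices `E` and `eps`.
#' @export
muscle_error <- function(lambda_actual, lambda_desired, g_d, dt) {
  if (!all(dim(lambda_actual) == dim(lambda_desired)))
    stop("muscle-length series have mismatched dimensions")
  E <- lambda_actual - lambda_desired
  Ed <- rbind(diff(E) / dt, rep(0, ncol(E)))
  list(E = E, eps = E + g_d * Ed)
}

#' V-shaped trial-to-trial update of the feedforward command
#'
#' `u'(t) = [u(t) + Delta_u(t + phase_advance)]_+` with
#' `Delta_u = alpha_l [eps]_+ + beta_l [-eps]_+ - gamma_l`: both stretch and
#' shortening errors increase activation (with different gains), while the
#' constant deactivation slowly removes wasteful co-contraction. The phase
#' advance compensates the feedback delay; commands stay non-negative.
#'
#' @param u Feedforward command matrix (nt x 6), N, non-negative.
#' @param eps Filtered muscle error matrix (nt x 6), m.
#' @param cfg A [vs_config()] (supplies `alpha_l`, `beta_l`, `gamma_l`,
#'   `delay`).
#' @param dt Sample step of the series, s.
#' @return Updated non-negative command matrix.
#' @export
vshape_update <- function(u, eps, cfg, dt = cfg$dt_inner) {
  stopifnot(all(u >= 0), all(dim(u) == dim(eps)))
  du <- cfg$alpha_l * pmax(eps, 0) + cfg$beta_l * pmax(-eps, 0) - cfg$gamma_l
  adv <- round(cfg$delay / dt)
  nt <- nrow(du)
  if (adv > 0L) {
    du <- rbind(du[(adv + 1L):nt, , drop = FALSE],
                matrix(rep(du[nt, ], each = adv), adv, ncol(du)))
  }
  # muscle activation is band-limited: smooth the increment (~50 ms) so the
  # update cannot build oscillatory temporal fine structure
  win <- round(0.100 / dt)
  if (win > 1L) {
    kern <- rep(1 / win, win)
    du <- apply(du, 2L, function(col)
      stats::filter(c(rep(col[1L], win), col, rep(col[nt], win)), kern,
                    sides = 2L)[(win + 1L):(win + nt)])
  }
  pmax(u + du, 0)
}

#' Via-point deflection state
#'
#' @param b Retention per trial.
#' @param r Sensitivity to target error (dimensionless; TE in m maps to a
#'   deflection in m).
#' @param cost_threshold Average-muscle-tension gate under which decay
#'   stops.
#' @return List of class `"deflection_state"` with `dx = 0`.
#' @export
deflection_state <- function(b = 0.95, r = 0.45, cost_threshold = 350,
                             dx_max = 0.060) {
  structure(list(dx = 0, b = b, r = r, cost_threshold = cost_threshold,
                 dx_max = dx_max, active = FALSE, frozen = FALSE),
            class = "deflection_state")
}

#' Trial-by-trial update of the via-point deflection
#'
#' Identical gating structure to [update_bias()]: on failure the deflection
#' becomes (and stays) active and moves opposite the target error,
#' `dx' = b dx - r TE`; on success it decays (`dx' = b dx`) until the motor
#' cost (average muscle tension) falls below the gate, after which `b` is
#' treated as 1 permanently and the current plan persists.
#'
#' @param state A [deflection_state()].
#' @param te_m Signed target error, m.
#' @param failed Logical: |TE| beyond the target radius?
#' @param motor_cost Average muscle tension of the trial, N.
#' @return Updated `deflection_state`.
#' @export
update_deflection <- function(state, te_m, failed, motor_cost) {
  stopifnot(inherits(state, "deflection_state"))
  if (state$active && !state$frozen && motor_cost < state$cost_threshold)
    state$frozen <- TRUE
  b_eff <- if (state$frozen) 1 else state$b
  if (failed) {
    state$active <- TRUE
    state$dx <- b_eff * state$dx - state$r * te_m
  } else if (state$active) {
    state$dx <- b_eff * state$dx
  }
  state$dx <- max(-state$dx_max, min(state$dx_max, state$dx))
  state
}

# non-negative tension distribution of a joint-torque series: each joint
# torque is carried by the corresponding antagonist pair (flexor for
# positive, extensor for negative); the biarticular pair carries none of
# the feedforward drive and contributes through feedback and learning
tension_distribution <- function(cfg, tau) {
  A <- cfg$moment_arms
  Tm <- matrix(0, nrow(tau), 6L)
  Tm[, 1L] <- pmax(tau[, 1L], 0) / A[1L, 1L]
  Tm[, 2L] <- pmax(-tau[, 1L], 0) / -A[2L, 1L]
  Tm[, 3L] <- pmax(tau[, 2L], 0) / A[3L, 2L]
  Tm[, 4L] <- pmax(-tau[, 2L], 0) / -A[4L, 2L]
  Tm
}

#' Feedforward command from inverse dynamics of a desired trajectory
#'
#' The converged starting point of learning: joint torques from the rigid
#' two-link inverse dynamics of the desired motion, distributed across the
#' six muscles by rectified antagonist-pair distribution. The tonic
#' co-activation
#' `t_coact` is not part of the learned command; it is added at execution
#' time, so the deactivation term of the learning law cannot erode it.
#'
#' @param cfg A [vs_config()].
#' @param desired A [vs_desired()] trajectory.
#' @return Feedforward tension matrix (nt x 6), N, non-negative.
#' @export
vs_feedforward_init <- function(cfg, desired) {
  nt <- length(desired$t)
  qdd <- rbind(diff(desired$qd) / cfg$dt_inner, c(0, 0))
  tau <- matrix(0, nt, 2L)
  for (i in seq_len(nt)) {
    M <- vs_inertia(cfg, desired$q[i, 2L])
    tau[i, ] <- M %*% qdd[i, ] +
      vs_coriolis_torque(cfg, desired$q[i, 2L], desired$qd[i, ]) +
      cfg$b_joint * desired$qd[i, ]
  }
  tension_distribution(cfg, tau)
}

vs_sim_field <- function(cfg, condition) {
  switch(condition,
    VDCF = field_spec("VDCF", b1 = cfg$vdcf_b1),
    LIPF_NULL = , LIPF_PEC = field_spec("LIPF", k1 = cfg$lipf_k1),
    PSPF = field_spec("PSPF", k2 = cfg$pspf_k2),
    CPVF = field_spec("CPVF", b1 = cfg$cpvf_b1, k1 = cfg$cpvf_k1))
}

#' Simulate one arm reach under feedforward + reflex control
#'
#' Forward dynamics of the two-link arm driven by the feedforward muscle
#' command plus intrinsic viscoelasticity and the delayed stretch reflex
#' (both computed from the muscle-length error to the desired motion);
#' the force field, optional error-clamp channel and endpoint lock act on
#' the hand. Muscle tensions are rectified. The motor cost is the average
#' tension across the six muscles over the movement (up to endpoint-lock
#' engagement).
#'
#' @param u Feedforward tension matrix (nt x 6) on the inner time grid.
#' @param desired A [vs_desired()] trajectory.
#' @param cfg A [vs_config()].
#' @param field True [field_spec()] applied by the environment.
#' @param clamp Optional [channel_spec()].
#' @param lock An [endpoint_lock_spec()] or `NULL`.
#' @return Trajectory data frame on the `dt` output grid (task-frame
#'   columns as elsewhere) with attributes `motor_cost` (avg tension, N),
#'   `endpoint`, `E`, `eps` (muscle-error series on the inner grid),
#'   `tension` (nt x 6) and `diverged`.
#' @export
vs_simulate_reach <- function(u, desired, cfg, field = field_spec("NULL"),
                              clamp = NULL, lock = endpoint_lock_spec()) {
  tt <- desired$t
  nt <- length(tt)
  stopifnot(nrow(u) == nt)
  A <- cfg$moment_arms
  a1 <- A[, 1L]; a2 <- A[, 2L]
  nd <- round(cfg$delay / cfg$dt_inner)
  l1 <- cfg$l1; l2 <- cfg$l2; dti <- cfg$dt_inner
  mi1 <- cfg$i1 + cfg$i2 + cfg$m1 * cfg$lc1^2 + cfg$m2 * (l1^2 + cfg$lc2^2)
  mi2 <- cfg$m2 * l1 * cfg$lc2                 # cos-coupling coefficient
  m22 <- cfg$i2 + cfg$m2 * cfg$lc2^2
  m12c <- cfg$i2 + cfg$m2 * cfg$lc2^2          # + mi2 * cos(q2)
  q1 <- desired$q[1L, 1L]; q2 <- desired$q[1L, 2L]
  qd1 <- 0; qd2 <- 0
  sx <- cfg$start[1L]; sy <- cfg$start[2L]
  E <- matrix(0, nt, 6L); Ed <- matrix(0, nt, 6L)
  Tension <- matrix(0, nt, 6L)
  hand <- matrix(NA_real_, nt, 2L); handv <- matrix(0, nt, 2L)
  onset <- FALSE; lock_on_at <- NA_integer_; diverged <- FALSE
  endpoint <- NULL
  lock_engaged <- FALSE; anchor_x <- 0; anchor_y <- 0
  lock_k <- if (is.null(lock)) 0 else lock$stiffness
  lock_c <- if (is.null(lock)) 0 else lock$damping
  lock_thr <- if (is.null(lock)) 0 else lock$speed_threshold
  for (i in seq_len(nt)) {
    s1 <- sin(q1); c1 <- cos(q1)
    s12 <- sin(q1 + q2); c12 <- cos(q1 + q2)
    # Jacobian entries
    j11 <- -l1 * s1 - l2 * s12; j12 <- -l2 * s12
    j21 <-  l1 * c1 + l2 * c12; j22 <-  l2 * c12
    px <- l1 * c1 + l2 * c12 - sx
    py <- l1 * s1 + l2 * s12 - sy
    vx <- j11 * qd1 + j12 * qd2
    vy <- j21 * qd1 + j22 * qd2
    hand[i, 1L] <- px; hand[i, 2L] <- py
    handv[i, 1L] <- vx; handv[i, 2L] <- vy
    e1 <- desired$q[i, 1L] - q1; e2 <- desired$q[i, 2L] - q2
    ed1 <- desired$qd[i, 1L] - qd1; ed2 <- desired$qd[i, 2L] - qd2
    E[i, ] <- a1 * e1 + a2 * e2
    Ed[i, ] <- a1 * ed1 + a2 * ed2
    idel <- if (i > nd) i - nd else 1L
    # muscle viscoelasticity scales with drive: co-contraction buys
    # impedance, which is what lets the deactivation term prune it back
    drv <- (u[i, ] + cfg$t_coact) / cfg$t_coact
    Tm <- u[i, ] + cfg$t_coact +
      drv * (cfg$k_int * E[i, ] + cfg$b_int * Ed[i, ]) +
      drv * (cfg$g_ref_p * E[idel, ] + cfg$g_ref_v * Ed[idel, ]) +
      cfg$co_reflex * mean(abs(E[idel, ]))
    Tm[Tm < 0] <- 0
    Tension[i, ] <- Tm
    f_ext <- field_force(field, c(px, py), c(vx, vy))
    if (!is.null(clamp) && py > clamp$activation_y)
      f_ext[1L] <- f_ext[1L] - clamp$stiffness * px - clamp$damping * vx
    sp <- sqrt(vx * vx + vy * vy)
    if (!onset && sp >= SPEED_STOP_MS) onset <- TRUE
    if (lock_k > 0 && onset) {
      if (!lock_engaged && sp < lock_thr) {
        lock_engaged <- TRUE; anchor_x <- px; anchor_y <- py
        lock_on_at <- i; endpoint <- c(px, py)
      }
      if (lock_engaged) {
        f_ext[1L] <- f_ext[1L] - lock_k * (px - anchor_x) - lock_c * vx
        f_ext[2L] <- f_ext[2L] - lock_k * (py - anchor_y) - lock_c * vy
      }
    }
    tau_m1 <- sum(a1 * Tm); tau_m2 <- sum(a2 * Tm)
    h <- mi2 * sin(q2)
    tau1 <- tau_m1 + j11 * f_ext[1L] + j21 * f_ext[2L] -
      cfg$b_joint * qd1 + h * qd2 * (2 * qd1 + qd2)
    tau2 <- tau_m2 + j12 * f_ext[1L] + j22 * f_ext[2L] -
      cfg$b_joint * qd2 - h * qd1 * qd1
    cm <- mi2 * cos(q2)
    M11 <- mi1 + 2 * cm; M12 <- m12c + cm
    det <- M11 * m22 - M12 * M12
    qdd1 <- ( m22 * tau1 - M12 * tau2) / det
    qdd2 <- (-M12 * tau1 + M11 * tau2) / det
    qd1 <- qd1 + dti * qdd1; qd2 <- qd2 + dti * qdd2
    q1 <- q1 + dti * qd1; q2 <- q2 + dti * qd2    # semi-implicit Euler
    if (!is.finite(q1) || !is.finite(q2) ||
        abs(px) > 0.6 || abs(py) > 0.6) {
      diverged <- TRUE
      break
    }
  }
  keep <- seq(1L, nt, by = round(cfg$dt / cfg$dt_inner))
  traj <- data.frame(t_s = tt[keep], x_m = hand[keep, 1L],
                     y_m = hand[keep, 2L],
                     vx_ms = handv[keep, 1L], vy_ms = handv[keep, 2L])
  mv <- if (is.na(lock_on_at)) seq_len(nt) else seq_len(lock_on_at)
  if (is.null(endpoint)) {
    last <- max(which(stats::complete.cases(hand)))
    endpoint <- hand[last, ]
  }
  attr(traj, "motor_cost") <- mean(Tension[mv, ])
  attr(traj, "endpoint") <- endpoint
  attr(traj, "E") <- E
  attr(traj, "eps") <- E + cfg$g_d * Ed
  attr(traj, "tension") <- Tension
  attr(traj, "diverged") <- diverged
  if (diverged) warning("arm trajectory diverged")
  traj
}

run_condition_vs <- function(variant, condition, cfg, keep_trajectories) {
  trained <- vs_sim_field(cfg, condition)
  null_f <- field_spec("NULL")
  pec <- if (condition == "LIPF_PEC")
    channel_spec(cfg$pec_stiffness, cfg$pec_damping) else NULL
  n_adapt <- 155L; n_deadapt <- 150L; n_total <- n_adapt + n_deadapt
  defl <- deflection_state(b = cfg$defl_b, r = cfg$defl_r,
                           cost_threshold = cfg$cost_threshold,
                           dx_max = cfg$dx_max)
  desired <- vs_desired(cfg, 0)
  u <- vs_feedforward_init(cfg, desired)
  rows <- vector("list", n_total)
  trajs <- if (keep_trajectories) vector("list", n_total) else NULL
  dx_cur <- 0
  for (i in seq_len(n_total)) {
    adapt <- i <= n_adapt
    if (variant == "hierarchical" && abs(defl$dx - dx_cur) > 1e-9) {
      desired <- vs_desired(cfg, defl$dx)
      dx_cur <- defl$dx
    }
    traj <- vs_simulate_reach(u, desired, cfg,
                              field = if (adapt) trained else null_f,
                              clamp = if (adapt) NULL else pec)
    if (isTRUE(attr(traj, "diverged"))) {
      ep <- attr(traj, "endpoint")
      mt <- list(TE_mm = ep[1L] * 1000, LD_mm = NA_real_,
                 reach_mm = ep[2L] * 1000, valid = FALSE, flagged = TRUE)
    } else mt <- trial_metrics(traj)
    cost <- attr(traj, "motor_cost")
    u <- vshape_update(u, attr(traj, "eps"), cfg)
    if (variant == "hierarchical") {
      failed <- abs(mt$TE_mm) > TARGET_RADIUS_MM
      defl <- update_deflection(defl, mt$TE_mm / 1000, failed, cost)
    }
    rows[[i]] <- data.frame(
      trial = i,
      phase = if (adapt) "adaptation" else "de_adaptation",
      trial_in_phase = if (adapt) i else i - n_adapt,
      TE_mm = mt$TE_mm, LD_mm = mt$LD_mm,
      plan = dx_cur * 1000, alpha = NA_real_, cost = cost,
      valid = mt$valid)
    if (keep_trajectories) trajs[[i]] <- traj
  }
  new_condition_result("vs", variant, condition,
                       do.call(rbind, rows), cfg, trajs)
}
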