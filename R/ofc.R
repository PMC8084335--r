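#' @title Optimal-feedback-control reaching model
#'
#' @description A point-mass arm under discrete-time finite-horizon LQR
#' control. The controller's internal model of the external force is
#' `alpha * D` where `D` is the true force matrix of the trained field and
#' `alpha in [0, 1]` is internal-model knowledge, so mismatch between the
#' assumed and true dynamics drives trajectory errors. Simulations are
#' noise-free with a certainty-equivalent (full, noiseless observation)
#' estimator. The hierarchical variant adds a failure-driven aim-direction
#' bias `phi` to the cost (penalizing motion perpendicular to the biased
#' direction), updated trial-by-trial by the signed endpoint direction error
#' and gated by motor cost.
#' @name ofc-model
NULL

#' Configuration of the OFC reaching model
#'
#' State is (position, velocity, actuated force, 1): the actuated force is a
#' first-order lag on the motor command (time constant `tau_f`), and the
#' trailing constant carries target and feedforward terms. Cost weights are
#' calibrated once so the null-field reach is straight, 150 mm, completes in
#' ~400 ms and ends inside the 7.5 mm target; the motor cost of that nominal
#' reach then sits just below the 0.01 gate used by the bias decay.
#'
#' @param dt Time step, s.
#' @param T Movement time, s.
#' @param T_hold Post-movement hold, s.
#' @param mass Point mass, kg.
#' @param tau_f Muscle (force-lag) time constant, s.
#' @param w_pos,w_vel,w_force Per-stage state-cost weights applied at and
#'   after `T` (position error to target, velocity, actuated force).
#' @param w_path,w_path_v Running (every-stage) weights penalizing position
#'   and velocity perpendicular to the planned direction `d(phi)` — the
#'   controller's path regularization, standing in for intrinsic arm
#'   impedance. With `phi = 0` this is a straight-line lateral penalty.
#' @param r_control Control-cost weight (scalar; `R = r_control * I`).
#' @param k_p,k_v Directional-bias weights on position and velocity.
#' @param tau Bias-term decay time constant, s.
#' @param target Target position, m.
#' @param target_radius Target radius, m; |TE| above it is a failure.
#' @param bias_b Bias retention (forgetting) rate per trial.
#' @param bias_r Bias sensitivity to the endpoint direction error.
#' @param cost_threshold Motor-cost gate; when the trial's motor cost
#'   (sum of u' R u) falls below it, bias decay stops (b treated as 1).
#' @param vdcf_b1,lipf_k1,cpvf_b1,cpvf_k1,pspf_k2 Simulation field gains.
#' @param pec_stiffness,pec_damping Simulation error-clamp channel.
#' @param extend_T Extra simulated time past the policy horizon, s, during
#'   which the final feedback gain is held (lets slow perturbed reaches come
#'   to rest so the endpoint lock can engage).
#' @return List of class `"ofc_config"`.
#' @export
ofc_config <- function(dt = 0.010, T = 0.400, T_hold = 0.050,
                       mass = 1, tau_f = 0.040,
                       w_pos = 150, w_vel = 0.05, w_force = 1e-4,
                       w_path = 2, w_path_v = 0.01,
                       r_control = 1e-5,
                       k_p = 0.5, k_v = 0.5, tau = 0.130,
                       target = c(0, 0.150), target_radius = 0.0075,
                       bias_b = 0.95, bias_r = 0.85, cost_threshold = 0.01,
                       vdcf_b1 = 7, lipf_k1 = 120,
                       cpvf_b1 = 7, cpvf_k1 = 120, pspf_k2 = 20868,
                       pec_stiffness = 1500, pec_damping = 100,
                       extend_T = 0.60) {
  stopifnot(dt > 0, T > 0, T_hold >= 0,
            abs(T / dt - round(T / dt)) < 1e-9,
            abs(T_hold / dt - round(T_hold / dt)) < 1e-9,
            w_pos >= 0, w_vel >= 0, w_force >= 0, r_control >= 0)
  structure(as.list(environment()), class = "ofc_config")
}

#' Internal-model learning schedule
#'
#' Knowledge `alpha` of the trained force field across the 305-trial
#' schedule: rises 0 to 0.8 over the 155 adaptation trials as
#' `0.8 log(log(i) + 1) / log(log(155) + 1)` (natural logs), falls back from
#' 0.8 to 0 over the first 30 de-adaptation trials (de-adaptation is much
#' faster than adaptation; the decreasing mirror
#' `0.8 (1 - log(log(i - 155) + 1) / log(log(30) + 1))` is used), and is 0
#' from trial 186 on.
#'
#' @param i Trial index (1..305), vectorized.
#' @param n_adapt Number of adaptation trials.
#' @param n_decay Number of de-adaptation trials over which alpha returns
#'   to 0.
#' @param n_total Schedule length.
#' @param alpha_max Asymptotic knowledge reached at the end of adaptation.
#' @return `alpha` values in `[0, alpha_max]`.
#' @export
alpha_schedule <- function(i, n_adapt = 155L, n_decay = 30L, n_total = 305L,
                           alpha_max = 0.8) {
  stopifnot(all(i >= 1), all(i <= n_total), all(i == round(i)))
  up <- alpha_max * log(log(pmax(i, 1)) + 1) / log(log(n_adapt) + 1)
  j <- i - n_adapt
  down <- alpha_max * (1 - log(log(pmax(j, 1)) + 1) / log(log(n_decay) + 1))
  out <- ifelse(i <= n_adapt, up,
                ifelse(j <= n_decay, pmax(down, 0), 0))
  out
}

#' Directional-bias cost matrix
#'
#' Rank-1 projector penalizing the state component perpendicular to the
#' aimed direction `d(phi)` (unit vector at angle `phi` clockwise from
#' straight-to-target): `Q_d = [[dy^2, -dx dy], [-dx dy, dx^2]]`, so
#' `Q_d d = 0`.
#'
#' @param phi_deg Aim bias, degrees, clockwise positive from +y.
#' @return Symmetric positive-semidefinite 2x2 matrix.
#' @export
bias_cost_matrix <- function(phi_deg) {
  stopifnot(is.finite(phi_deg))
  a <- phi_deg * pi / 180
  d <- c(sin(a), cos(a))  # clockwise from +y
  matrix(c(d[2L]^2, -d[1L] * d[2L], -d[1L] * d[2L], d[1L]^2), 2L, 2L)
}

# ---- internal LQR machinery ------------------------------------------------

# state x = (px, py, vx, vy, fx, fy, 1)
OFC_NSTATE <- 7L

# 2 x 7 matrix mapping state to field force for the linear fields;
# NULL for fields without a linear state representation (PSPF).
field_state_matrix <- function(field) {
  M <- matrix(0, 2L, OFC_NSTATE)
  switch(field$kind,
    "NULL" = M,
    VDCF = { M[1L, 4L] <- -field$b1; M[2L, 3L] <- field$b1; M },
    LIPF = { M[1L, 2L] <- -field$k1; M },
    CPVF = { M[1L, 2L] <- -field$k1
             M[1L, 4L] <- field$b1; M[2L, 3L] <- -field$b1; M },
    PSPF = NULL)
}

# base (null-field) dynamics
ofc_dynamics <- function(cfg) {
  n <- OFC_NSTATE
  A <- diag(n)
  A[1L, 3L] <- A[2L, 4L] <- cfg$dt
  A[3L, 5L] <- A[4L, 6L] <- cfg$dt / cfg$mass
  A[5L, 5L] <- A[6L, 6L] <- 1 - cfg$dt / cfg$tau_f
  B <- matrix(0, n, 2L)
  B[5L, 1L] <- B[6L, 2L] <- cfg$dt / cfg$tau_f
  list(A = A, B = B)
}

#' Per-stage quadratic state costs
#'
#' Builds the stage cost matrices of the reaching cost: accuracy terms
#' (position error to target, velocity, actuated force) at and after the
#' movement time `T`, and — in the hierarchical variant — the
#' exponentially decaying directional-bias term
#' `exp(-t/tau) (k_p p' Q_d p + k_v v' Q_d v)` at every stage. At `phi = 0`
#' the bias term vanishes for motion along the straight line x = 0.
#'
#' @param cfg An [ofc_config()].
#' @param phi_deg Aim bias, degrees; use 0 for the flat variant.
#' @return List of `N + 1` state-cost matrices (stages `0..N`,
#'   `N = (T + T_hold)/dt`) plus the control cost matrix `R`.
#' @export
assemble_stage_costs <- function(cfg, phi_deg = 0) {
  n_move <- round(cfg$T / cfg$dt)
  N <- n_move + round(cfg$T_hold / cfg$dt)
  Qd <- bias_cost_matrix(phi_deg)
  # the kinematic plan aims the reach: the accuracy term centers on the
  # target rotated clockwise by phi about the start, and the bias term
  # penalizes motion perpendicular to that aimed direction
  a <- phi_deg * pi / 180
  tgt <- sqrt(sum(cfg$target^2)) * c(sin(a), cos(a))
  Qs <- vector("list", N + 1L)
  for (k in 0:N) {
    Q <- matrix(0, OFC_NSTATE, OFC_NSTATE)
    tk <- k * cfg$dt
    w <- exp(-tk / cfg$tau)
    Q[1:2, 1:2] <- Q[1:2, 1:2] + (cfg$w_path + w * cfg$k_p) * Qd
    Q[3:4, 3:4] <- Q[3:4, 3:4] + (cfg$w_path_v + w * cfg$k_v) * Qd
    if (k >= n_move) {
      Q[1:2, 1:2] <- Q[1:2, 1:2] + cfg$w_pos * diag(2L)
      Q[1:2, 7L] <- Q[1:2, 7L] - cfg$w_pos * tgt
      Q[7L, 1:2] <- Q[7L, 1:2] - cfg$w_pos * tgt
      Q[7L, 7L] <- Q[7L, 7L] + cfg$w_pos * sum(tgt^2)
      Q[3:4, 3:4] <- Q[3:4, 3:4] + cfg$w_vel * diag(2L)
      Q[5:6, 5:6] <- Q[5:6, 5:6] + cfg$w_force * diag(2L)
    }
    Qs[[k + 1L]] <- Q
  }
  list(Q = Qs, R = cfg$r_control * diag(2L), N = N, n_move = n_move)
}

# nominal forward positions for the PSPF feedforward linearization
pspf_feedforward <- function(cfg, field, N) {
  tk <- (0:(N - 1L)) * cfg$dt
  s <- pmin(tk / cfg$T, 1)
  y <- cfg$target[2L] * (10 * s^3 - 15 * s^4 + 6 * s^5)
  vapply(y, function(yy) field_force(field, c(0, yy), c(0, 0))[1L],
         numeric(1L))
}

#' Plan the time-varying LQR feedback policy
#'
#' Solves the finite-horizon discrete LQR backward recursion for the
#' internal-model dynamics: the null-field point mass augmented with the
#' predicted force `alpha * D x` for fields linear in the state, or with a
#' time-varying feedforward force along the nominal straight reach for the
#' skew (PSPF) field. Deterministic given its inputs.
#'
#' @param cfg An [ofc_config()].
#' @param field The trained [field_spec()] the internal model refers to
#'   (gains as in the simulation, not the experiment).
#' @param alpha Internal-model knowledge in `[0, 1]`.
#' @param phi_deg Aim bias, degrees (0 for the flat variant).
#' @return List of class `"ofc_policy"` with per-stage gain matrices `L` and
#'   the assumed dynamics.
#' @export
ofc_policy <- function(cfg, field = field_spec("NULL"), alpha = 0,
                       phi_deg = 0) {
  stopifnot(alpha >= 0, alpha <= 1)
  costs <- assemble_stage_costs(cfg, phi_deg)
  dyn <- ofc_dynamics(cfg)
  N <- costs$N
  Dmat <- field_state_matrix(field)
  ff <- if (is.null(Dmat)) pspf_feedforward(cfg, field, N) else NULL
  A_at <- function(k) {  # stage index 0-based
    A <- dyn$A
    if (!is.null(Dmat)) {
      A[3:4, ] <- A[3:4, ] + (cfg$dt / cfg$mass) * alpha * Dmat
    } else {
      A[3L, 7L] <- A[3L, 7L] + (cfg$dt / cfg$mass) * alpha * ff[k + 1L]
    }
    A
  }
  L <- vector("list", N)
  S <- costs$Q[[N + 1L]]
  for (k in (N - 1L):0L) {
    A <- A_at(k)
    G <- costs$R + t(dyn$B) %*% S %*% dyn$B
    if (rcond(G) < 1e-14) stop("non-convergent Riccati recursion: invalid cost weights")
    Lk <- solve(G, t(dyn$B) %*% S %*% A)
    S <- costs$Q[[k + 1L]] + t(A) %*% S %*% (A - dyn$B %*% Lk)
    S <- (S + t(S)) / 2
    L[[k + 1L]] <- Lk
  }
  # stationary hold regulator used past the horizon: keeps the hand at the
  # target until the endpoint lock takes over
  A_hold <- A_at(N - 1L)
  Q_hold <- costs$Q[[N + 1L]]
  Sh <- Q_hold
  L_hold <- NULL
  for (it in seq_len(500L)) {
    G <- costs$R + t(dyn$B) %*% Sh %*% dyn$B
    Lh <- solve(G, t(dyn$B) %*% Sh %*% A_hold)
    Sh2 <- Q_hold + t(A_hold) %*% Sh %*% (A_hold - dyn$B %*% Lh)
    Sh2 <- (Sh2 + t(Sh2)) / 2
    done <- !is.null(L_hold) && max(abs(Lh - L_hold)) < 1e-10
    Sh <- Sh2; L_hold <- Lh
    if (done) break
  }
  structure(list(L = L, L_hold = L_hold, N = N, cfg = cfg, field = field,
                 alpha = alpha, phi_deg = phi_deg, R = costs$R, B = dyn$B,
                 Q = costs$Q),
            class = "ofc_policy")
}

#' Simulate one reach under a policy and the true environment
#'
#' Forward-simulates the point mass under the TRUE field (and optional
#' error-clamp channel and endpoint lock) while the controller applies the
#' feedback law planned for its internal model; model-plant mismatch drives
#' the trajectory errors. Noise-free. Past the policy horizon the last
#' feedback gain is held (up to `extend_T`) so slow perturbed reaches come
#' to rest. Motor cost is the summed `u' R u` up to endpoint-lock
#' engagement.
#'
#' @param policy An [ofc_policy()].
#' @param true_field [field_spec()] actually applied by the environment.
#' @param clamp Optional [channel_spec()].
#' @param lock An [endpoint_lock_spec()]; pass `NULL` to disable.
#' @return Trajectory data frame (`t_s`, `x_m`, `y_m`, `vx_ms`, `vy_ms`,
#'   `fx_N`, `fy_N`, `ux`, `uy`) with attributes `motor_cost`, `endpoint`
#'   (m), `lock_engaged`, `diverged`.
#' @export
ofc_simulate_reach <- function(policy, true_field = field_spec("NULL"),
                               clamp = NULL, lock = endpoint_lock_spec()) {
  cfg <- policy$cfg
  n_ext <- round(cfg$extend_T / cfg$dt)
  n_steps <- policy$N + n_ext
  x <- c(0, 0, 0, 0, 0, 0, 1)
  B <- policy$B
  out <- matrix(NA_real_, n_steps + 1L, 9L)
  onset <- FALSE
  motor_cost <- 0
  lock_on_at <- NA_integer_
  diverged <- FALSE
  endpoint <- NULL
  for (k in 0:n_steps) {
    pos <- x[1:2]; vel <- x[3:4]
    f_ext <- field_force(true_field, pos, vel)
    if (!is.null(clamp)) f_ext <- f_ext + channel_force(clamp, pos, vel)
    sp <- sqrt(sum(vel^2))
    if (!onset && sp >= SPEED_STOP_MS) onset <- TRUE
    if (!is.null(lock) && onset) {
      st <- endpoint_lock_step(lock, pos, vel)
      if (!lock$engaged && st$spec$engaged) {
        lock_on_at <- k
        endpoint <- pos
      }
      lock <- st$spec
      f_ext <- f_ext + st$force
    }
    u <- if (k < policy$N) -policy$L[[k + 1L]] %*% x
         else -policy$L_hold %*% x
    u <- as.numeric(u)
    out[k + 1L, ] <- c(k * cfg$dt, pos, vel, x[5:6], u)
    if (k <= policy$N) motor_cost <- motor_cost +
        sum(x * (policy$Q[[min(k + 1L, policy$N + 1L)]] %*% x))
    if (is.na(lock_on_at)) motor_cost <- motor_cost +
        sum(u * (policy$R %*% u))
    # Euler step
    xn <- x
    xn[1:2] <- pos + cfg$dt * vel
    xn[3:4] <- vel + cfg$dt * (x[5:6] + f_ext) / cfg$mass
    xn[5:6] <- x[5:6] + cfg$dt * (u - x[5:6]) / cfg$tau_f
    x <- xn
    if (sqrt(sum(x[1:2]^2)) > 1) { diverged <- TRUE; break }
    # once locked and settled there is nothing left to read out
    if (!is.na(lock_on_at) && k > lock_on_at + 10L) break
  }
  out <- out[!is.na(out[, 1L]), , drop = FALSE]
  traj <- data.frame(t_s = out[, 1L], x_m = out[, 2L], y_m = out[, 3L],
                     vx_ms = out[, 4L], vy_ms = out[, 5L],
                     fx_N = out[, 6L], fy_N = out[, 7L],
                     ux = out[, 8L], uy = out[, 9L])
  if (is.null(endpoint)) endpoint <- c(traj$x_m[nrow(traj)],
                                       traj$y_m[nrow(traj)])
  attr(traj, "motor_cost") <- motor_cost
  attr(traj, "endpoint") <- endpoint
  attr(traj, "lock_engaged") <- !is.na(lock_on_at)
  attr(traj, "diverged") <- diverged
  if (diverged) warning("trajectory diverged (>1 m from start)")
  traj
}

# ---- failure-driven aim-direction bias ------------------------------------

#' Aim-direction bias state
#'
#' @param b Retention (forgetting) rate per trial.
#' @param r Sensitivity to the endpoint direction error.
#' @param cost_threshold Motor-cost gate under which decay stops.
#' @return List of class `"bias_state"` with `phi = 0`, inactive, unfrozen.
#' @export
bias_state <- function(b = 0.95, r = 0.85, cost_threshold = 0.01) {
  structure(list(phi = 0, b = b, r = r, cost_threshold = cost_threshold,
                 active = FALSE, frozen = FALSE),
            class = "bias_state")
}

#' Trial-by-trial update of the aim-direction bias
#'
#' On a failed trial (|TE| beyond the target radius) the bias becomes (and
#' stays) active and is updated opposite the signed endpoint direction
#' error: `phi' = b phi - r theta`. On successful trials an active bias
#' decays, `phi' = b phi`, except that once the trial's motor cost falls
#' below the gate the decay stops permanently (`b` treated as 1), which is
#' what leaves a persistent curved null trajectory. An inactive bias stays
#' at zero.
#'
#' @param bias A [bias_state()].
#' @param theta_deg Signed endpoint direction error, degrees, clockwise
#'   positive (same sign as TE for this geometry).
#' @param failed Logical: was |TE| greater than the target radius?
#' @param motor_cost The trial's motor cost (sum of `u' R u`).
#' @return Updated `bias_state`.
#' @export
update_bias <- function(bias, theta_deg, failed, motor_cost) {
  stopifnot(inherits(bias, "bias_state"))
  if (bias$active && !bias$frozen && motor_cost < bias$cost_threshold)
    bias$frozen <- TRUE
  b_eff <- if (bias$frozen) 1 else bias$b
  if (failed) {
    bias$active <- TRUE
    bias$phi <- b_eff * bias$phi - bias$r * theta_deg
  } else if (bias$active) {
    bias$phi <- b_eff * bias$phi
  }
  bias
}

# signed endpoint direction error, degrees, clockwise positive
endpoint_theta_deg <- function(endpoint_m) {
  atan2(endpoint_m[1L], endpoint_m[2L]) * 180 / pi
}
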