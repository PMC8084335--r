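# trajectory with a parabolic lateral profile x = c * y * (150 - y) / 150^2
# (c in mm), sampled on a minimum-jerk forward profile over 150 mm / 400 ms
parabolic_trajectory <- function(c_mm = 20, reach_mm = 150, dt = 0.01,
                                 dur = 0.4) {
  tt <- seq(0, dur * 1.5, by = dt)
  s <- pmin(tt / dur, 1)
  y <- reach_mm / 1000 * (10 * s^3 - 15 * s^4 + 6 * s^5)
  y_mm <- 1000 * y
  x <- (c_mm * y_mm * (150 - y_mm) / 150^2) / 1000
  data.frame(t_s = tt, x_m = x, y_m = y,
             vx_ms = c(diff(x) / dt, 0), vy_ms = c(diff(y) / dt, 0))
}

straight_trajectory <- function(reach_mm = 150, dt = 0.01, dur = 0.4) {
  parabolic_trajectory(c_mm = 0, reach_mm = reach_mm, dt = dt, dur = dur)
}

# shift a trajectory laterally by delta_mm
shift_x <- function(traj, delta_mm) {
  traj$x_m <- traj$x_m + delta_mm / 1000
  traj
}

random_hand_state <- function() {
  list(pos = stats::runif(2, -0.05, 0.15), vel = stats::runif(2, -0.8, 0.8))
}

# brute-force one-way repeated-measures decomposition by explicit loops,
# with the definitional Box epsilon from the covariance matrix
rm_anova_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_cond <- 0
  for (j in 1:k) ss_cond <- ss_cond + n * (mean(m[, j]) - grand)^2
  ss_subj <- 0
  for (i in 1:n) ss_subj <- ss_subj + k * (mean(m[i, ]) - grand)^2
  ss_tot <- 0
  for (i in 1:n) for (j in 1:k) ss_tot <- ss_tot + (m[i, j] - grand)^2
  ss_err <- ss_tot - ss_cond - ss_subj
  f <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  # definitional Box epsilon: (sum lambda)^2 / ((k-1) sum lambda^2) on the
  # double-centered covariance
  S <- stats::cov(m)
  C <- diag(k) - matrix(1 / k, k, k)
  Sc <- C %*% S %*% C
  lam <- Re(eigen(Sc, only.values = TRUE)$values)
  eps <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  list(F = f, eps = eps, etap2 = ss_cond / (ss_cond + ss_err))
}
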